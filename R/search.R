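# The query pipeline: exact shared-7-mer counting against the triple store,
# filtering and ranking, optional Smith-Waterman refinement with bit scores,
# and six-frame handling of DNA / short-read queries.

#' Search options
#'
#' @param min_kmatch minimum number of distinct query 7-mers that must be
#'   found in a target for it to be reported (default 10, the engine's
#'   standard sensitivity mode; set 1 for the most sensitive mode).
#' @param min_ratio minimum shared-7-mer ratio in `[0, 1]` (default 0). The
#'   ratio is `shared_kmers / (number of distinct canonical 7-mers in the
#'   query)`, computed per translated segment for DNA/read queries.
#' @param align refine every reported hit with a Smith-Waterman local
#'   alignment against the stored target sequence and re-rank by bit score
#'   (default `FALSE`). Alignment never adds or removes candidates: the
#'   result set is exactly the alignment-free one.
#' @param matrix substitution matrix name (any matrix shipped with
#'   Biostrings: BLOSUM45/50/62/80/100, PAM30/40/70/120/250; default
#'   `"BLOSUM62"`).
#' @param gap_open cost of opening a gap (first gap column; default 11).
#' @param gap_extend cost of each further gap column (default 1).
#' @param max_results maximum reported hits per query (default 10; `Inf` for
#'   unlimited).
#' @param lambda,K Karlin-Altschul parameters for the bit-score
#'   normalization (defaults 0.267 and 0.041, the standard gapped BLOSUM62
#'   values).
#' @return list of class `aakmer_opts`.
#' @export
search_options <- function(min_kmatch = 10L, min_ratio = 0, align = FALSE,
                           matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, max_results = 10L,
                           lambda = 0.267, K = 0.041) {
  min_kmatch <- as.integer(min_kmatch)
  stopifnot(length(min_kmatch) == 1L, min_kmatch >= 1L,
            length(min_ratio) == 1L, min_ratio >= 0, min_ratio <= 1,
            is.logical(align), length(align) == 1L,
            gap_open >= 1, gap_extend >= 1, gap_extend <= gap_open,
            max_results >= 1)
  structure(list(min_kmatch = min_kmatch, min_ratio = min_ratio,
                 align = align, matrix = matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_results = max_results, lambda = lambda, K = K),
            class = "aakmer_opts")
}

.as_opts <- function(opts) {
  if (is.null(opts)) return(search_options())
  if (inherits(opts, "aakmer_opts")) return(opts)
  do.call(search_options, opts)
}

.empty_hits <- function(align = FALSE, dna = FALSE) {
  df <- data.frame(query = character(0), target_pid = integer(0),
                   target_name = character(0), shared_kmers = integer(0),
                   ratio = numeric(0), target_length = integer(0),
                   stringsAsFactors = FALSE)
  if (dna)
    df <- cbind(df, data.frame(frame = integer(0), segment = integer(0),
                               dna_start = integer(0), dna_end = integer(0)))
  if (align)
    df <- cbind(df, data.frame(raw_score = integer(0), bit_score = numeric(0),
                               pct_identity = numeric(0), q_start = integer(0),
                               q_end = integer(0), t_start = integer(0),
                               t_end = integer(0)))
  df
}

#' Alignment-free k-mer matching of one protein query
#'
#' Counts, for every database protein, the number of *distinct* canonical
#' 7-mers of the query that occur in that protein (set semantics, matching
#' the store design: a 7-mer maps to a protein set without multiplicities).
#' Targets passing the `min_kmatch` and `min_ratio` filters are ranked by
#' shared-7-mer count descending, ties broken by ratio descending then pid
#' ascending, and truncated to `max_results`.
#'
#' @param db opened database.
#' @param query_id query name carried into the result.
#' @param query_seq amino-acid string.
#' @param opts [search_options()].
#' @return data.frame of hits with columns `query`, `target_pid`,
#'   `target_name`, `shared_kmers`, `ratio`, `target_length`. A query with
#'   zero canonical 7-mers yields an empty result carrying
#'   `attr(, "unqueryable") = TRUE`.
#' @export
kmer_match <- function(db, query_id, query_seq, opts = search_options()) {
  stopifnot(inherits(db, "aakmer_db"))
  opts <- .as_opts(opts)
  qcodes <- .distinct_codes(query_seq)
  nq <- length(qcodes)
  if (nq == 0L) {
    out <- .empty_hits()
    attr(out, "unqueryable") <- TRUE
    return(out)
  }
  pos <- match(qcodes, db$kmer_codes)
  pos <- pos[!is.na(pos)]
  nprot <- nrow(db$proteins)
  shared <- integer(nprot)
  if (length(pos) > 0L) {
    pids <- unlist(db$combos[db$kmer_combo[pos]], use.names = FALSE)
    shared <- tabulate(pids + 1L, nbins = nprot)
  }
  ratio <- shared / nq
  keep <- which(shared >= opts$min_kmatch & ratio >= opts$min_ratio)
  if (length(keep) == 0L) return(.empty_hits())
  ord <- keep[order(-shared[keep], -ratio[keep], keep)]
  if (is.finite(opts$max_results) && length(ord) > opts$max_results)
    ord <- ord[seq_len(opts$max_results)]
  data.frame(
    query = query_id, target_pid = ord - 1L,
    target_name = db$proteins$name[ord],
    shared_kmers = shared[ord], ratio = ratio[ord],
    target_length = db$proteins$length[ord],
    stringsAsFactors = FALSE
  )
}

.matrix_cache <- new.env(parent = emptyenv())

.get_matrix <- function(name) {
  m <- get0(name, envir = .matrix_cache)
  if (!is.null(m)) return(m)
  ok <- tryCatch({
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- get(name, envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !is.matrix(m))
    stop("unknown substitution matrix: ", name, call. = FALSE)
  storage.mode(m) <- "integer"
  assign(name, m, envir = .matrix_cache)
  m
}

# residue -> 0-based row index of the matrix; residues absent from the
# matrix fall back to the ambiguity row X
.matrix_indices <- function(sequence, mat) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  i <- match(chars, rownames(mat))
  i[is.na(i)] <- match("X", rownames(mat))
  i - 1L
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment with affine gap penalties: a gap of length `L`
#' costs `gap_open + (L - 1) * gap_extend`. Exact dynamic programming (no
#' banding or heuristics) with full traceback of one optimal alignment.
#'
#' @param query,target non-empty amino-acid strings.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend gap penalties (defaults 11 and 1).
#' @return list with `raw_score`, `pct_identity` (identities / alignment
#'   columns x 100), and 1-based inclusive aligned spans `q_start`, `q_end`,
#'   `t_start`, `t_end`. When no cell scores above zero the score is 0 and
#'   the span fields are `NA` (empty alignment).
#' @examples
#' smith_waterman("AAAA", "AAAA")  # raw score 16 under BLOSUM62
#' @export
smith_waterman <- function(query, target, matrix = "BLOSUM62",
                           gap_open = 11L, gap_extend = 1L) {
  stopifnot(is.character(query), nchar(query) > 0L,
            is.character(target), nchar(target) > 0L,
            gap_open >= 1, gap_extend >= 1)
  mat <- .get_matrix(matrix)
  res <- .sw_align(.matrix_indices(query, mat), .matrix_indices(target, mat),
                   mat, as.integer(gap_open), as.integer(gap_extend))
  list(
    raw_score = res$score,
    pct_identity = if (res$aln_length > 0L)
      100 * res$identities / res$aln_length else NA_real_,
    q_start = res$q_start, q_end = res$q_end,
    t_start = res$t_start, t_end = res$t_end
  )
}

#' Bit-score normalization of a raw alignment score
#'
#' Standard Karlin-Altschul normalization
#' `(lambda * S - ln K) / ln 2`, making raw scores comparable across
#' scoring systems. Defaults are the standard gapped BLOSUM62 parameters.
#'
#' @param raw_score non-negative raw Smith-Waterman score (vectorized).
#' @param lambda positive scale parameter (default 0.267).
#' @param K positive parameter in `(0, 1)` (default 0.041).
#' @return numeric vector of scores in bits.
#' @export
bit_score <- function(raw_score, lambda = 0.267, K = 0.041) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive number", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K >= 1)
    stop("K must lie in (0, 1)", call. = FALSE)
  if (any(raw_score < 0)) stop("raw_score must be >= 0", call. = FALSE)
  (lambda * raw_score - log(K)) / log(2)
}

# Smith-Waterman refinement of an existing hit set (never changes the set
# of (query, target) pairs), plus bit-score re-ranking
.align_hits <- function(db, query_seq, hits, opts) {
  n <- nrow(hits)
  cols <- list(raw_score = integer(n), bit_score = numeric(n),
               pct_identity = numeric(n), q_start = integer(n),
               q_end = integer(n), t_start = integer(n), t_end = integer(n))
  for (i in seq_len(n)) {
    tseq <- db$proteins$sequence[hits$target_pid[i] + 1L]
    a <- smith_waterman(query_seq, tseq, matrix = opts$matrix,
                        gap_open = opts$gap_open,
                        gap_extend = opts$gap_extend)
    cols$raw_score[i] <- a$raw_score
    cols$bit_score[i] <- bit_score(a$raw_score, opts$lambda, opts$K)
    cols$pct_identity[i] <- a$pct_identity
    cols$q_start[i] <- a$q_start; cols$q_end[i] <- a$q_end
    cols$t_start[i] <- a$t_start; cols$t_end[i] <- a$t_end
  }
  hits <- cbind(hits, as.data.frame(cols))
  hits[order(-hits$bit_score, hits$target_pid), , drop = FALSE]
}

.read_queries <- function(path, query_type) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  if (!grepl("\\S", txt))
    return(data.frame(id = character(0), desc = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  if (query_type == "reads") read_fastq(path) else read_fasta(path)
}

#' Search a database
#'
#' The full query pipeline. Protein queries are matched directly with
#' [kmer_match()]. DNA and short-read queries are translated in six frames;
#' every stop-free segment of length >= 7 is searched independently, and its
#' hits carry the frame, the segment index and 1-based forward-strand DNA
#' coordinates (the whole segment span in alignment-free mode, narrowed to
#' the aligned query region in alignment mode).
#'
#' With `opts$align = TRUE` every reported hit is refined with a
#' Smith-Waterman alignment against the stored target sequence and hits are
#' re-ranked by bit score; the set of reported (query, target) pairs is
#' exactly the alignment-free result set under the same filters.
#'
#' @param db opened database.
#' @param queries a query file path, or a data.frame with columns `id` and
#'   `sequence` (an empty data.frame/file yields an empty result).
#' @param query_type `"protein"`, `"dna"` or `"reads"` (reads are FASTQ).
#' @param opts [search_options()].
#' @param annotation_fields character vector of database annotation fields
#'   to attach as extra hit columns (default none; `"all"` attaches every
#'   field).
#' @return data.frame of ranked hits for all queries.
#' @export
search <- function(db, queries, query_type = c("protein", "dna", "reads"),
                   opts = search_options(), annotation_fields = NULL) {
  stopifnot(inherits(db, "aakmer_db"))
  query_type <- match.arg(query_type)
  opts <- .as_opts(opts)
  if (opts$align && !isTRUE(db$meta$store_sequences))
    stop("alignment mode requires a database built with stored sequences",
         call. = FALSE)
  if (is.character(queries) && length(queries) == 1L)
    queries <- .read_queries(queries, query_type)
  stopifnot(is.data.frame(queries), all(c("id", "sequence") %in% names(queries)))

  dna <- query_type != "protein"
  res <- list()
  for (qi in seq_len(nrow(queries))) {
    qid <- queries$id[qi]
    qseq <- queries$sequence[qi]
    if (!dna) {
      hits <- kmer_match(db, qid, qseq, opts)
      if (opts$align)
        hits <- if (nrow(hits) > 0L) .align_hits(db, qseq, hits, opts)
                else .empty_hits(align = TRUE)
      res[[length(res) + 1L]] <- hits
    } else {
      segs <- translate_six_frames(qseq, source_id = qid)
      segs <- segs[nchar(segs$peptide) >= KMER_K, , drop = FALSE]
      for (si in seq_len(nrow(segs))) {
        hits <- kmer_match(db, qid, segs$peptide[si], opts)
        if (nrow(hits) == 0L) next
        hits$frame <- segs$frame[si]
        hits$segment <- segs$segment[si]
        hits$dna_start <- segs$dna_start[si]
        hits$dna_end <- segs$dna_end[si]
        if (opts$align) {
          hits <- .align_hits(db, segs$peptide[si], hits, opts)
          sp <- .segment_dna_span(segs$frame[si], segs$dna_start[si],
                                  segs$dna_end[si], hits$q_start, hits$q_end)
          hits$dna_start <- sp$start
          hits$dna_end <- sp$end
        }
        res[[length(res) + 1L]] <- hits
      }
    }
  }
  if (length(res) == 0L)
    return(.attach_annotations(db, .empty_hits(opts$align, dna),
                               annotation_fields))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  .attach_annotations(db, out, annotation_fields)
}

# forward-strand DNA span of query residues q_start..q_end of a translated
# segment located at (seg_start, seg_end) in frame `frame`
.segment_dna_span <- function(frame, seg_start, seg_end, q_start, q_end) {
  if (frame > 0L) {
    list(start = seg_start + 3L * (q_start - 1L),
         end = seg_start + 3L * q_end - 1L)
  } else {
    list(start = seg_end - 3L * q_end + 1L,
         end = seg_end - 3L * (q_start - 1L))
  }
}

.attach_annotations <- function(db, hits, fields) {
  if (is.null(fields) || length(fields) == 0L) return(hits)
  avail <- unlist(db$meta$annotation_fields)
  if (identical(fields, "all")) fields <- avail
  missing <- setdiff(fields, avail)
  if (length(missing) > 0L)
    stop("unknown annotation field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (f in fields)
    hits[[f]] <- db$proteins[[f]][hits$target_pid + 1L]
  hits
}
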