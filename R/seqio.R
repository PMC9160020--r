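# Sequence input/output: FASTA and FASTQ readers, six-frame translation of
# DNA queries, tabular result writing.
#
# Coordinate convention: everything user-facing is 1-based inclusive on the
# forward strand (the GFF convention); negative-frame segments carry
# forward-strand coordinates with the strand recorded via the frame sign.

#' Read a FASTA file
#'
#' Records may be line-wrapped; CRLF line endings are tolerated. The record
#' identifier is the header up to the first whitespace; any remaining header
#' text is kept as the description. Sequences are uppercased.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `desc`, `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA file contains no records: ", path, call. = FALSE)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("FASTA record with empty sequence: ",
         sub("\\s.*", "", headers[nchar(seqs) == 0L][1L]), call. = FALSE)
  data.frame(
    id = sub("\\s.*", "", headers),
    desc = ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), ""),
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
}

#' Read a FASTQ file
#'
#' Expects strict 4-line records (`@header`, sequence, `+`, quality). The
#' quality line is length-checked and then discarded: search results are, by
#' contract, independent of quality strings. Structural problems are
#' reported with the 1-based index of the offending record.
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `desc`, `sequence` (DNA, uppercased).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (length(lines) > 0L && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) == 0L)
    stop("FASTQ file contains no records: ", path, call. = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record ", length(lines) %/% 4L + 1L, " in ", path,
         call. = FALSE)
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0L)
    stop("malformed FASTQ record ", bad[1L],
         " (expected '@' header and '+' separator)", call. = FALSE)
  badq <- which(nchar(qual) != nchar(seq))
  if (length(badq) > 0L)
    stop("FASTQ record ", badq[1L],
         ": quality length differs from sequence length", call. = FALSE)
  hdr <- substring(hdr, 2L)
  data.frame(
    id = sub("\\s.*", "", hdr),
    desc = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
    sequence = toupper(seq),
    stringsAsFactors = FALSE
  )
}

#' Read an annotation TSV
#'
#' Tab-delimited, UTF-8, header row required; the first column holds FASTA
#' identifiers and every remaining column is a named annotation field.
#'
#' @param path TSV file.
#' @return data.frame of character columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ann <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         colClasses = "character",
                                         na.strings = NULL))
  if (ncol(ann) < 2L)
    stop("annotation TSV needs an identifier column plus at least one field: ",
         path, call. = FALSE)
  ann
}

#' Translate a DNA sequence in all six reading frames
#'
#' Translates with the standard genetic code (translation table 1) in frames
#' +1, +2, +3 on the forward strand and -1, -2, -3 on the reverse
#' complement, then splits each frame's translation at stop codons into
#' maximal stop-free peptide segments. `N`-containing codons translate to
#' `X` (which the 7-mer codec later skips). Segment coordinates are 1-based
#' inclusive on the forward strand, so for a negative frame `dna_start` is
#' the forward-strand position of the segment's last translated base.
#'
#' @param dna single DNA string over `ACGTN` (case-insensitive).
#' @param source_id identifier carried into the output (default `"query"`).
#' @return data.frame with columns `source_id`, `frame` (integer in
#'   `+1..+3, -1..-3`), `segment` (1-based index of the segment within its
#'   frame), `peptide`, `dna_start`, `dna_end`. Segment length times 3 always
#'   equals `dna_end - dna_start + 1`.
#' @examples
#' translate_six_frames("ATGGCT")
#' @export
translate_six_frames <- function(dna, source_id = "query") {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna))
    stop("DNA sequence contains characters outside ACGTN", call. = FALSE)
  L <- nchar(dna)
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)

  out <- list()
  for (f in 1:3) {
    for (strand in c(1L, -1L)) {
      s <- if (strand == 1L) fwd else rev
      ncodon <- (L - f + 1L) %/% 3L
      if (ncodon < 1L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(s, start = f, width = 3L * ncodon),
        if.fuzzy.codon = "X"
      ))
      segs <- .split_at_stops(aa)
      if (nrow(segs) == 0L) next
      if (strand == 1L) {
        dna_start <- f + 3L * (segs$from - 1L)
        dna_end <- f + 3L * segs$to - 1L
      } else {
        dna_start <- L - f - 3L * segs$to + 2L
        dna_end <- L - f - 3L * (segs$from - 1L) + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        source_id = source_id, frame = strand * f,
        segment = seq_len(nrow(segs)), peptide = segs$peptide,
        dna_start = dna_start, dna_end = dna_end,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L)
    return(data.frame(source_id = character(0), frame = integer(0),
                      segment = integer(0), peptide = character(0),
                      dna_start = integer(0), dna_end = integer(0)))
  do.call(rbind, out)
}

# maximal stop-free runs of a translated frame; from/to are codon indices
.split_at_stops <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
  keep <- chars != "*"
  if (!any(keep))
    return(data.frame(from = integer(0), to = integer(0),
                      peptide = character(0)))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  data.frame(
    from = starts[i], to = ends[i],
    peptide = vapply(i, function(j) paste(chars[starts[j]:ends[j]],
                                          collapse = ""), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write search hits as TSV
#'
#' Fixed column order: `query`, `target_name`, `shared_kmers`, `ratio`, then
#' (when alignment columns are present) `raw_score`, `bit_score`,
#' `pct_identity`, `q_start`, `q_end`, `t_start`, `t_end`, then one column
#' per annotation field attached to the hits. Translated-query hits
#' additionally carry `frame`, `segment`, `dna_start`, `dna_end` directly
#' after `ratio`. Ratios and percent identities are written with 4 decimals.
#'
#' @param hits hits data.frame from [search()] or [kmer_match()].
#' @param path output file path or an open connection (e.g. `stdout()`).
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  core <- c("query", "target_name", "shared_kmers", "ratio")
  dna_cols <- intersect(c("frame", "segment", "dna_start", "dna_end"),
                        names(hits))
  aln_cols <- intersect(c("raw_score", "bit_score", "pct_identity",
                          "q_start", "q_end", "t_start", "t_end"),
                        names(hits))
  known <- c(core, dna_cols, aln_cols, "target_pid", "target_length")
  ann_cols <- setdiff(names(hits), known)
  cols <- c(core, dna_cols, aln_cols, ann_cols)

  out <- hits[, cols, drop = FALSE]
  for (cc in intersect(c("ratio", "pct_identity"), cols))
    out[[cc]] <- sprintf("%.4f", out[[cc]])
  if ("bit_score" %in% cols) out$bit_score <- sprintf("%.2f", out$bit_score)

  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, "w")
    on.exit(close(con))
  }
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0L) {
    body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
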