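# Synthetic protein families and the homology-group ROC protocol.
#
# The generator emulates the structure of a domain database classified into
# homology groups: each family descends from one random ancestral sequence,
# and members diverge by independent per-residue substitutions. The
# evaluation sweeps a score threshold over all-vs-all search hits and counts
# true/false positives by group co-membership, crediting every subject
# protein at most once, so the maximum attainable number of true positives
# equals the database size.

#' Generate synthetic protein families
#'
#' Draws one random ancestral sequence per family (residues uniform over the
#' 20 canonical amino acids), then derives each member by substituting every
#' residue independently with probability `sub_rate` (replacement drawn
#' uniformly from the 19 other residues). Deterministic for a given seed.
#'
#' @param n_families number of families (>= 2).
#' @param members_per_family members per family (>= 2).
#' @param length sequence length in residues.
#' @param sub_rate per-residue substitution probability in `[0, 1)`.
#' @param seed integer random seed (required; the generator is
#'   self-contained and restores the caller's RNG state).
#' @return list with `records` (data.frame `id`, `sequence`; ids are
#'   `fam<i>_mem<j>`) and `groups` (data.frame `name`, `group`).
#' @export
generate_families <- function(n_families, members_per_family, length,
                              sub_rate, seed) {
  stopifnot(n_families >= 2, members_per_family >= 2, length >= 1,
            sub_rate >= 0, sub_rate < 1, !missing(seed))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  ids <- character(0)
  seqs <- character(0)
  groups <- character(0)
  for (f in seq_len(n_families)) {
    anc <- sample(AA_ALPHABET, length, replace = TRUE)
    fam <- sprintf("fam%02d", f)
    for (m in seq_len(members_per_family)) {
      member <- anc
      mut <- which(stats::runif(length) < sub_rate)
      if (base::length(mut) > 0L) {
        # uniform over the 19 residues other than the current one
        member[mut] <- vapply(member[mut], function(a)
          sample(setdiff(AA_ALPHABET, a), 1L), character(1))
      }
      ids <- c(ids, sprintf("%s_mem%02d", fam, m))
      seqs <- c(seqs, paste(member, collapse = ""))
      groups <- c(groups, fam)
    }
  }
  list(
    records = data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE),
    groups = data.frame(name = ids, group = groups, stringsAsFactors = FALSE)
  )
}

#' Write family FASTA and group map
#'
#' @param families result of [generate_families()].
#' @param fasta_path,groups_path output files (FASTA; name/group TSV).
#' @return invisibly, a list of the two paths.
#' @export
write_families <- function(families, fasta_path, groups_path) {
  con <- file(fasta_path, "w")
  writeLines(paste0(">", families$records$id, "\n",
                    families$records$sequence), con)
  close(con)
  utils::write.table(families$groups, groups_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, groups = groups_path))
}

#' Homology-group ROC / precision-recall evaluation
#'
#' Implements the homology benchmark protocol: a detected pair is a true
#' positive when query and subject belong to the same homology group and a
#' false positive otherwise; self-pairs are discarded; each subject protein
#' is credited at most once, to its highest-scoring pair (ties broken by
#' query name ascending), so the maximum number of true positives equals the
#' database size. The ROC curve is traced by sweeping the score threshold
#' from high to low and counting the credited true and false positives with
#' score >= threshold.
#'
#' @param hits data.frame with columns `query`, `subject`, `score` (all hits
#'   of an all-vs-all search; self-hits allowed, they are ignored).
#' @param groups data.frame with columns `name`, `group` mapping every
#'   protein to its homology group; also defines the database size.
#' @return data.frame with one row per distinct credited score, highest
#'   first: `threshold`, `tp`, `fp` (cumulative counts at `score >=
#'   threshold`), `precision` (`tp / (tp + fp)`), `recall`
#'   (`tp / database size`).
#' @export
evaluate_homology <- function(hits, groups) {
  stopifnot(is.data.frame(hits),
            all(c("query", "subject", "score") %in% names(hits)),
            is.data.frame(groups), all(c("name", "group") %in% names(groups)))
  db_size <- nrow(groups)
  missing <- setdiff(unique(c(hits$query, hits$subject)), groups$name)
  if (length(missing) > 0L)
    stop("protein(s) missing from the group map: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)

  h <- hits[hits$query != hits$subject, , drop = FALSE]  # drop self-pairs
  if (nrow(h) == 0L)
    return(data.frame(threshold = numeric(0), tp = integer(0),
                      fp = integer(0), precision = numeric(0),
                      recall = numeric(0)))

  # credit each subject once: best score, ties by query name ascending
  ord <- order(h$subject, -h$score, h$query)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(h$subject), , drop = FALSE]

  qg <- groups$group[match(h$query, groups$name)]
  sg <- groups$group[match(h$subject, groups$name)]
  is_tp <- qg == sg

  ord <- order(-h$score)
  score <- h$score[ord]
  is_tp <- is_tp[ord]
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  last <- !duplicated(score, fromLast = TRUE)  # one point per distinct score
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  data.frame(
    threshold = score[last], tp = tp, fp = fp,
    precision = tp / (tp + fp), recall = tp / db_size
  )
}

#' All-vs-all self-search of a database
#'
#' Convenience driver for the benchmark: queries every database protein
#' against the database and returns `(query, subject, score)` rows ready for
#' [evaluate_homology()], with the score taken from the shared-7-mer count
#' or, in alignment mode, the bit score.
#'
#' @param db opened database (built with the evaluated proteins).
#' @param opts [search_options()]; use `max_results = Inf` so crediting sees
#'   every qualifying pair, and `align = TRUE` to score by bits.
#' @return data.frame `query`, `subject`, `score`.
#' @export
all_vs_all_hits <- function(db, opts = search_options(min_kmatch = 1L,
                                                      max_results = Inf)) {
  opts <- .as_opts(opts)
  queries <- data.frame(id = db$proteins$name,
                        sequence = db$proteins$sequence,
                        stringsAsFactors = FALSE)
  hits <- search(db, queries, "protein", opts)
  data.frame(
    query = hits$query, subject = hits$target_name,
    score = if (opts$align) hits$bit_score else hits$shared_kmers,
    stringsAsFactors = FALSE
  )
}
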