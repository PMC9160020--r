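# Downstream use-case outputs: GFF3 genome annotation from translated-DNA
# hits, a per-gene antimicrobial-resistance report, and annotation-feature
# profiles (presence/abundance).

#' Write a GFF3 genome annotation from DNA-query hits
#'
#' Turns the hits of a six-frame translated genome search into GFF3
#' `protein_match` features: one feature per hit passing the identity and
#' ratio thresholds, with 1-based inclusive forward-strand coordinates, the
#' strand taken from the frame sign, and the bit score (falling back to the
#' shared-7-mer ratio for alignment-free hits) in the score column. Output
#' is byte-deterministic: features are sorted by seqid, then start, then
#' target name.
#'
#' @param dna_hits hits from a `"dna"`-type [search()]; alignment columns
#'   are required whenever `min_identity > 0`.
#' @param out_path output GFF3 file.
#' @param min_identity minimum percent identity (0-100; default 0).
#' @param min_ratio minimum shared-7-mer ratio (default 0).
#' @return `out_path`, invisibly.
#' @export
annotate_genome_gff <- function(dna_hits, out_path, min_identity = 0,
                                min_ratio = 0) {
  stopifnot(is.data.frame(dna_hits))
  need <- c("query", "target_name", "shared_kmers", "ratio", "frame",
            "dna_start", "dna_end")
  if (!all(need %in% names(dna_hits)))
    stop("dna_hits must come from a dna-type search (missing: ",
         paste(setdiff(need, names(dna_hits)), collapse = ", "), ")",
         call. = FALSE)
  has_aln <- "pct_identity" %in% names(dna_hits)
  if (min_identity > 0 && !has_aln)
    stop("min_identity > 0 requires alignment-mode hits (pct_identity)",
         call. = FALSE)

  keep <- dna_hits$ratio >= min_ratio
  if (has_aln && min_identity > 0)
    keep <- keep & !is.na(dna_hits$pct_identity) &
      dna_hits$pct_identity >= min_identity
  h <- dna_hits[keep, , drop = FALSE]
  h <- h[order(h$query, h$dna_start, h$target_name), , drop = FALSE]

  if (nrow(h) == 0L) {
    writeLines("##gff-version 3", out_path)
    return(invisible(out_path))
  }
  score <- if ("bit_score" %in% names(h)) sprintf("%.2f", h$bit_score)
           else sprintf("%.4f", h$ratio)
  attrs <- paste0(
    "Target=", h$target_name,
    if (has_aln) paste0(";identity=", sprintf("%.2f", h$pct_identity))
    else "",
    ";shared_kmers=", h$shared_kmers
  )
  lines <- paste(h$query, "aakmer", "protein_match", h$dna_start, h$dna_end,
                 score, ifelse(h$frame > 0L, "+", "-"), ".", attrs,
                 sep = "\t")
  con <- file(out_path, "w")
  on.exit(close(con))
  writeLines(c("##gff-version 3", lines), con)
  invisible(out_path)
}

#' Per-gene antimicrobial-resistance report
#'
#' Counts, for each resistance gene, the number of distinct query loci (one
#' locus = one translated segment of one source sequence) with a qualifying
#' hit, so tandem gene copies in a genome count separately. Requires the
#' database annotations to carry `gene` and `class` fields (attach them with
#' `search(..., annotation_fields = c("gene", "class"))`). Coverage is the
#' aligned target span divided by the target length.
#'
#' @param hits alignment-mode hits from a `"dna"`-type search carrying
#'   `gene` and `class` columns.
#' @param min_identity minimum percent identity (default 90).
#' @param min_coverage minimum target coverage in `[0, 1]` (default 0.8).
#' @return data.frame `gene`, `class`, `count`, sorted by class then gene.
#' @export
arg_report <- function(hits, min_identity = 90, min_coverage = 0.8) {
  stopifnot(is.data.frame(hits))
  for (f in c("gene", "class"))
    if (!f %in% names(hits))
      stop("hits lack the annotation field '", f,
           "'; search with annotation_fields = c(\"gene\", \"class\")",
           call. = FALSE)
  need <- c("pct_identity", "t_start", "t_end", "target_length",
            "query", "frame", "segment")
  if (!all(need %in% names(hits)))
    stop("arg_report needs alignment-mode dna hits (missing: ",
         paste(setdiff(need, names(hits)), collapse = ", "), ")",
         call. = FALSE)

  empty <- data.frame(gene = character(0), class = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  coverage <- (hits$t_end - hits$t_start + 1L) / hits$target_length
  keep <- !is.na(hits$pct_identity) & hits$pct_identity >= min_identity &
    !is.na(coverage) & coverage >= min_coverage
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)

  locus <- paste(h$query, h$frame, h$segment, sep = "\r")
  key <- paste(h$gene, h$class, sep = "\r")
  tab <- tapply(locus, key, function(x) length(unique(x)))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, character(1), 1L),
    class = vapply(parts, `[`, character(1), 2L),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$class, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Presence/abundance profile of annotation features
#'
#' Summarizes, per annotation field, how often each feature value occurs in
#' a hit set: `presence` is the number of distinct hit targets carrying the
#' value, `abundance` the total number of hits to such targets.
#' Comma-separated multi-valued fields credit each value once per target
#' or hit.
#'
#' @param hits hits carrying the named annotation columns (see
#'   `annotation_fields` in [search()]).
#' @param feature_fields character vector of annotation field names.
#' @return data.frame `field`, `value`, `presence`, `abundance`, sorted by
#'   field, then abundance descending, then value.
#' @export
profile_features <- function(hits, feature_fields) {
  stopifnot(is.data.frame(hits), is.character(feature_fields),
            length(feature_fields) >= 1L)
  missing <- setdiff(feature_fields, names(hits))
  if (length(missing) > 0L)
    stop("unknown annotation field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  empty <- data.frame(field = character(0), value = character(0),
                      presence = integer(0), abundance = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)

  out <- list()
  for (f in feature_fields) {
    vals <- strsplit(as.character(hits[[f]]), ",", fixed = TRUE)
    vals <- lapply(vals, function(v) unique(trimws(v)))
    long <- data.frame(
      target = rep(hits$target_pid, lengths(vals)),
      value = unlist(vals),
      stringsAsFactors = FALSE
    )
    long <- long[nzchar(long$value), , drop = FALSE]
    if (nrow(long) == 0L) next
    # abundance: one credit per (hit, value); presence: per (target, value)
    ab <- tapply(long$value, long$value, length)
    pr <- tapply(long$target, long$value,
                 function(x) length(unique(x)))
    vals_u <- names(ab)
    out[[length(out) + 1L]] <- data.frame(
      field = f, value = vals_u,
      presence = as.integer(pr[vals_u]),
      abundance = as.integer(ab[vals_u]),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$field, -res$abundance, res$value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
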