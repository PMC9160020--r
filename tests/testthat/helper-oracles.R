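# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (substring scans, dense dynamic
# programming) and independent of the package's own index/codec code paths.

CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

rand_aa_seq <- function(len, alphabet = CANONICAL_AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# distinct canonical 7-letter windows of a sequence, by direct substring
# enumeration (no integer encoding involved)
brute_kmers <- function(s) {
  s <- toupper(s)
  L <- nchar(s)
  if (L < 7L) return(character(0))
  w <- substring(s, 1:(L - 6L), 7:L)
  unique(w[grepl("^[ACDEFGHIKLMNPQRSTVWY]{7}$", w)])
}

brute_shared <- function(query, target) {
  length(intersect(brute_kmers(query), brute_kmers(target)))
}

# dense O(mn) Smith-Waterman score with affine gaps: a length-L gap costs
# open + (L-1) * ext (score only, matrices indexed by residue letters)
naive_sw_score <- function(q, t, mat, open, ext) {
  qi <- strsplit(toupper(q), "")[[1L]]
  ti <- strsplit(toupper(t), "")[[1L]]
  m <- length(qi); n <- length(ti)
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(-Inf, m + 1L, n + 1L)
  FF <- matrix(-Inf, m + 1L, n + 1L)
  best <- 0
  for (i in seq_len(m) + 1L) {
    for (j in seq_len(n) + 1L) {
      E[i, j] <- max(H[i, j - 1L] - open, E[i, j - 1L] - ext)
      FF[i, j] <- max(H[i - 1L, j] - open, FF[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[qi[i - 1L], ti[j - 1L]],
                     E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

revcomp_chr <- function(d) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(d)), "")[[1L]]),
        collapse = "")
}

# deterministic codon choice per residue (first codon of the standard code)
reverse_translate <- function(peptide) {
  codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  paste(codons[strsplit(toupper(peptide), "")[[1L]]], collapse = "")
}

# n random proteins -> built database in a fresh temp dir
make_fixture_db <- function(n = 20L, len_range = c(30L, 120L), seed = 1L,
                            annotations = NULL, store_sequences = TRUE) {
  set.seed(seed)
  lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  prot <- data.frame(
    id = sprintf("prot%03d", seq_len(n)),
    sequence = vapply(lens, rand_aa_seq, character(1)),
    stringsAsFactors = FALSE
  )
  db <- build_database(prot, tempfile("fixdb"), annotations = annotations,
                       store_sequences = store_sequences)
  list(db = db, proteins = prot)
}

write_fasta_file <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
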