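# Amino-acid 7-mer integer codec.
#
# A 7-mer over the 20 canonical residues is packed into a single integer by
# base-20 positional arithmetic (A=0 ... Y=19, leftmost residue most
# significant).  The full code space is 20^7 = 1,280,000,000, so every code
# fits a 32-bit unsigned key (and, conveniently, a signed R integer).

#' @useDynLib aakmer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonical amino-acid alphabet (index order A = 0 ... Y = 19)
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Fixed k-mer length (residues)
#'
#' The word length is a build-time constant of the whole engine: 7 residues
#' pack into a 4-byte key while retaining good specificity between protein
#' targets. It is recorded in every database's metadata and is not
#' user-configurable.
#'
#' @export
KMER_K <- 7L

#' Number of distinct 7-mer codes (20^7)
#' @export
KMER_SPACE <- 20^7  # 1,280,000,000; max code 1,279,999,999 < 2^32

# 256-slot lookup: byte value of an uppercase canonical residue -> 0-based
# index; NA elsewhere (X, B, Z, J, U, O, '*', digits, ...).
.aa_index <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt(paste(AA_ALPHABET, collapse = "")) + 1L] <- 0:19
  tab
})

.base20 <- 20^(6:0)

# residue indices (0-based) for a sequence string; NA for non-canonical
.residue_indices <- function(sequence) {
  .aa_index[utf8ToInt(toupper(sequence)) + 1L]
}

#' Encode canonical amino-acid 7-mers as integer codes
#'
#' Each 7-mer is mapped to its base-20 positional code with index order
#' `A = 0 ... Y = 19` and the leftmost residue most significant, e.g.
#' `"AAAAAAA"` is 0 and `"YYYYYYY"` is `20^7 - 1 = 1279999999`. The mapping
#' is a bijection between canonical 7-mers and `[0, 20^7)`, and is strictly
#' monotone in the lexicographic order of the words.
#'
#' @param kmer character vector of 7-letter words over the 20 canonical
#'   residues (`ACDEFGHIKLMNPQRSTVWY`); lowercase is accepted.
#' @return integer vector of codes in `[0, 20^7)`.
#' @seealso [decode_kmer()], [kmerize()]
#' @examples
#' encode_kmer(c("AAAAAAA", "MKVLTAG"))
#' @export
encode_kmer <- function(kmer) {
  if (!is.character(kmer) || length(kmer) == 0L)
    stop("'kmer' must be a non-empty character vector", call. = FALSE)
  if (any(nchar(kmer) != KMER_K))
    stop("k-mers must have length exactly ", KMER_K, call. = FALSE)
  idx <- .aa_index[utf8ToInt(paste(toupper(kmer), collapse = "")) + 1L]
  if (anyNA(idx)) {
    bad <- unique(substring(paste(toupper(kmer), collapse = ""),
                            which(is.na(idx)), which(is.na(idx))))
    stop("non-canonical residue(s) in k-mer: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- matrix(idx, nrow = KMER_K)
  as.integer(colSums(m * .base20))
}

#' Decode integer codes back to 7-mers
#'
#' Inverse of [encode_kmer()]: `decode_kmer(encode_kmer(w)) == w` for every
#' canonical 7-mer `w`.
#'
#' @param code integer (or numeric) vector of codes in `[0, 20^7)`.
#' @return character vector of 7-letter words.
#' @export
decode_kmer <- function(code) {
  code <- as.numeric(code)
  if (length(code) == 0L || anyNA(code) || any(code < 0) ||
      any(code >= KMER_SPACE) || any(code != floor(code)))
    stop("codes must be integers in [0, 20^7)", call. = FALSE)
  out <- matrix("", nrow = KMER_K, ncol = length(code))
  rem <- code
  for (i in KMER_K:1) {
    out[i, ] <- AA_ALPHABET[rem %% 20 + 1]
    rem <- rem %/% 20
  }
  apply(out, 2L, paste, collapse = "")
}

#' Enumerate the canonical 7-mers of a protein sequence
#'
#' Slides a 7-residue window over the sequence and encodes every window whose
#' residues are all canonical; windows containing any other character
#' (`X`, `B`, `Z`, `J`, `U`, `O`, `*`, ...) are skipped, so exact-match
#' semantics are preserved at both build and query time. A fully canonical
#' sequence of length `L >= 7` yields exactly `L - 6` occurrences.
#'
#' @param sequence single amino-acid string; lowercase accepted, degenerate
#'   inputs (short sequences, all-ambiguous) yield an empty result.
#' @return data.frame with columns `offset` (0-based start of the window in
#'   `sequence`) and `code` (integer 7-mer code), in left-to-right order.
#' @examples
#' kmerize("ACDEFGHIK")   # 3 windows
#' kmerize("ACDEFGHXK")   # the X kills windows 1..2; only offset 0 survives
#' @export
kmerize <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  n <- nchar(sequence) - KMER_K + 1L
  if (n < 1L)
    return(data.frame(offset = integer(0), code = integer(0)))
  idx <- .residue_indices(sequence)
  codes <- numeric(n)
  for (j in 0:(KMER_K - 1L))
    codes <- codes + idx[seq_len(n) + j] * .base20[j + 1L]
  keep <- !is.na(codes)
  data.frame(offset = which(keep) - 1L, code = as.integer(codes[keep]))
}

# distinct canonical 7-mer codes of a sequence (sorted); the query-side and
# build-side unit of matching
.distinct_codes <- function(sequence) {
  occ <- kmerize(sequence)
  sort(unique(occ$code))
}
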