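# The database triple store.
#
# A database directory holds three logical key-value stores plus metadata:
#   kmer_store.bin         fixed-width records: 4-byte big-endian 7-mer code
#                          followed by the 8-byte combination key, sorted by
#                          code so on-disk iteration order is numeric
#   combination_store.bin  per combination: 8-byte key, 4-byte big-endian
#                          set size, then the sorted pids (4-byte big-endian
#                          each); records sorted by key
#   protein_store.tsv      one row per protein: pid, name, length, sequence
#                          (optional) and one column per annotation field
#   metadata.json          k, counts, key widths, format version, build time
#
# Combination keys are produced by hash-consing: every distinct sorted set of
# protein identifiers is hashed once (xxhash64 over the comma-joined pid
# list) and the resulting 8-byte key is reused by every k-mer that maps to
# that same set, mirroring the flyweight pattern. Correctness never depends
# on hash injectivity: a colliding insert is deterministically re-salted.
#
# The whole index is read into memory when a database is opened, so repeated
# queries pay the open cost once (the in-process analogue of serving a
# memory-mapped store).

#' @importFrom data.table data.table setkeyv fread fwrite
NULL

FORMAT_VERSION <- "1.0"
KMER_KEY_BYTES <- 4L
COMBINATION_KEY_BYTES <- 8L

.hex_to_raw <- function(h) {
  as.raw(strtoi(substring(h, seq(1L, 15L, 2L), seq(2L, 16L, 2L)), 16L))
}

.raw_to_hex <- function(b) {
  paste(sprintf("%02x", as.integer(b)), collapse = "")
}

#' Hash-consed identifier of a protein-identifier set
#'
#' Computes the stable 64-bit key under which a set of protein identifiers is
#' stored in the combination store. The set is sorted and deduplicated first,
#' so the key is independent of input order, and the hash (xxhash64 over the
#' comma-joined list) is stable across runs and platforms. Within one
#' database, distinct sets are guaranteed distinct keys: if an insert ever
#' collides, the builder re-salts deterministically (`salt = 1, 2, ...`)
#' until the key is free.
#'
#' @param pids non-empty vector of protein identifiers (0-based integers).
#' @param salt non-negative integer collision salt (0 = unsalted).
#' @return 16-character lowercase hex string encoding the 8-byte key.
#' @export
combination_id <- function(pids, salt = 0L) {
  if (length(pids) == 0L)
    stop("combination of zero proteins is not storable", call. = FALSE)
  pids <- sort(unique(as.integer(pids)))
  if (anyNA(pids)) stop("pids must be integers", call. = FALSE)
  key <- paste(pids, collapse = ",")
  if (salt > 0L) key <- paste0(key, "#", salt)
  digest::digest(key, algo = "xxhash64", serialize = FALSE)
}

# cons the keys for a list of distinct pid-sets; returns hex key per set
.cons_combination_ids <- function(pid_sets) {
  used <- new.env(parent = emptyenv())
  ids <- character(length(pid_sets))
  for (i in seq_along(pid_sets)) {
    salt <- 0L
    repeat {
      id <- combination_id(pid_sets[[i]], salt = salt)
      owner <- get0(id, envir = used)
      if (is.null(owner)) {
        assign(id, i, envir = used)
        break
      }
      if (identical(pid_sets[[owner]], pid_sets[[i]])) break  # true reuse
      salt <- salt + 1L
    }
    ids[i] <- id
  }
  ids
}

#' Build an amino-acid 7-mer database
#'
#' Indexes every canonical 7-mer of every input protein: for each 7-mer `w`
#' the k-mer store resolves, through the combination store, to exactly the
#' set of proteins whose sequences contain `w` (set semantics: a 7-mer
#' repeated within one protein contributes a single membership). Proteins are
#' assigned dense 0-based identifiers in input order. Identical pid-sets are
#' stored once and shared between k-mers (hash-consing).
#'
#' @param proteins data.frame with columns `id` (FASTA identifier) and
#'   `sequence` (amino-acid string); an optional `desc` column is kept as the
#'   `description` annotation. Typically from [read_fasta()].
#' @param out_dir output database directory (created; must not already
#'   contain a database).
#' @param annotations optional data.frame of annotation fields whose first
#'   column holds FASTA identifiers (as from [read_annotations()]); remaining
#'   columns become named annotation fields on the matching proteins.
#' @param store_sequences keep protein sequences in the protein store
#'   (default `TRUE`; required later for alignment-mode search).
#' @return the opened database, invisibly (see [open_database()]).
#' @examples
#' db <- build_database(
#'   data.frame(id = "p1", sequence = "ACDEFGHIK"),
#'   out_dir = tempfile("db")
#' )
#' db_info(db)
#' @export
build_database <- function(proteins, out_dir, annotations = NULL,
                           store_sequences = TRUE) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0L)
    stop("at least one input protein is required", call. = FALSE)
  if (anyDuplicated(proteins$id))
    warning("duplicate protein name(s): ",
            paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", "),
            "; keeping all records under distinct pids", call. = FALSE)

  seqs <- toupper(proteins$sequence)
  n <- nrow(proteins)
  pid <- seq_len(n) - 1L                      # dense 0-based identifiers

  code_sets <- lapply(seqs, .distinct_codes)
  if (sum(lengths(code_sets)) == 0L)
    stop("no indexable 7-mer in any input protein", call. = FALSE)

  dt <- data.table::data.table(
    code = unlist(code_sets, use.names = FALSE),
    pid  = rep(pid, lengths(code_sets))
  )
  data.table::setkeyv(dt, c("code", "pid"))
  by_code <- dt[, list(pids = list(pid)), by = "code"]    # sorted by code

  set_key <- vapply(by_code$pids, paste, character(1), collapse = ",")
  uniq <- !duplicated(set_key)
  pid_sets <- by_code$pids[uniq]
  combo_of_code <- match(set_key, set_key[uniq])
  combo_ids <- .cons_combination_ids(pid_sets)

  # annotations: description from FASTA plus any TSV fields, joined by name
  ann <- data.frame(row.names = seq_len(n))
  if (!is.null(proteins$desc)) ann$description <- as.character(proteins$desc)
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations), ncol(annotations) >= 2L)
    hit <- match(proteins$id, annotations[[1L]])
    for (f in names(annotations)[-1L]) {
      v <- as.character(annotations[[f]])[hit]
      v[is.na(v)] <- ""
      ann[[f]] <- v
    }
  }

  prot <- data.frame(
    pid = pid, name = as.character(proteins$id), length = nchar(seqs),
    sequence = if (store_sequences) seqs else "",
    stringsAsFactors = FALSE
  )
  for (f in names(ann)) prot[[f]] <- ann[[f]]

  meta <- list(
    format_version = FORMAT_VERSION,
    k = KMER_K,
    kmer_key_bytes = KMER_KEY_BYTES,
    combination_key_bytes = COMBINATION_KEY_BYTES,
    n_proteins = n,
    n_kmers = nrow(by_code),
    n_combinations = length(pid_sets),
    store_sequences = store_sequences,
    annotation_fields = names(ann),
    built = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  .write_database(out_dir, meta, by_code$code, combo_ids[combo_of_code],
                  combo_ids, pid_sets, prot)
  invisible(open_database(out_dir))
}

.write_database <- function(dir, meta, kmer_codes, kmer_combo_hex,
                            combo_ids, pid_sets, prot) {
  if (file.exists(file.path(dir, "metadata.json")))
    stop("output directory already contains a database: ", dir, call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  # k-mer store: 12-byte records (4-byte code, 8-byte combination key)
  nk <- length(kmer_codes)
  id_raw <- vapply(combo_ids, .hex_to_raw, raw(COMBINATION_KEY_BYTES))
  rec <- matrix(raw(), nrow = KMER_KEY_BYTES + COMBINATION_KEY_BYTES, ncol = nk)
  rec[1:4, ] <- matrix(writeBin(as.integer(kmer_codes), raw(), size = 4L,
                                endian = "big"), nrow = 4L)
  rec[5:12, ] <- id_raw[, match(kmer_combo_hex, combo_ids)]
  writeBin(as.vector(rec), file.path(dir, "kmer_store.bin"))

  # combination store: records sorted by key (numeric = byte order on hex)
  ord <- order(combo_ids)
  con <- file(file.path(dir, "combination_store.bin"), "wb")
  on.exit(close(con))
  for (i in ord) {
    writeBin(.hex_to_raw(combo_ids[i]), con)
    writeBin(length(pid_sets[[i]]), con, size = 4L, endian = "big")
    writeBin(as.integer(pid_sets[[i]]), con, size = 4L, endian = "big")
  }

  data.table::fwrite(prot, file.path(dir, "protein_store.tsv"), sep = "\t",
                     quote = TRUE, na = "")
  invisible(dir)
}

#' Open an existing database
#'
#' Reads the three stores into memory once; all subsequent lookups and
#' searches run against the in-memory index.
#'
#' @param dir database directory produced by [build_database()].
#' @return object of class `aakmer_db`.
#' @export
open_database <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path))
    stop("not a database directory (no metadata.json): ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.character(meta$format_version), FORMAT_VERSION))
    stop("unsupported database format version: ", meta$format_version,
         call. = FALSE)

  kpath <- file.path(dir, "kmer_store.bin")
  rec_bytes <- KMER_KEY_BYTES + COMBINATION_KEY_BYTES
  kraw <- readBin(kpath, raw(), n = file.size(kpath))
  if (length(kraw) %% rec_bytes != 0L)
    stop("corrupt k-mer store: ", kpath, call. = FALSE)
  nk <- length(kraw) %/% rec_bytes
  rec <- matrix(kraw, nrow = rec_bytes)
  kmer_codes <- readBin(as.vector(rec[1:4, , drop = FALSE]), integer(),
                        n = nk, size = 4L, endian = "big")
  kmer_hex <- apply(rec[5:12, , drop = FALSE], 2L, .raw_to_hex)

  cpath <- file.path(dir, "combination_store.bin")
  craw <- readBin(cpath, raw(), n = file.size(cpath))
  combo_ids <- character(0)
  combos <- list()
  pos <- 0L
  while (pos < length(craw)) {
    id <- .raw_to_hex(craw[pos + 1:8])
    cnt <- readBin(craw[pos + 9:12], integer(), size = 4L, endian = "big")
    pids <- readBin(craw[pos + 12L + seq_len(4L * cnt)], integer(),
                    n = cnt, size = 4L, endian = "big")
    combo_ids <- c(combo_ids, id)
    combos[[length(combos) + 1L]] <- pids
    pos <- pos + 12L + 4L * cnt
  }

  prot <- as.data.frame(data.table::fread(
    file.path(dir, "protein_store.tsv"), sep = "\t", colClasses = "character",
    na.strings = NULL
  ))
  prot$pid <- as.integer(prot$pid)
  prot$length <- as.integer(prot$length)

  db <- list(
    dir = normalizePath(dir),
    meta = meta,
    kmer_codes = kmer_codes,                 # sorted ascending
    kmer_combo = match(kmer_hex, combo_ids), # index into combos
    combo_ids = combo_ids,
    combos = combos,
    proteins = prot
  )
  class(db) <- "aakmer_db"
  db
}

#' Look up the proteins containing a 7-mer
#'
#' Traverses k-mer store -> combination store and returns the exact set of
#' proteins whose sequences contain the 7-mer.
#'
#' @param db opened database.
#' @param code integer 7-mer code (see [encode_kmer()]).
#' @return sorted integer vector of 0-based pids; empty when the 7-mer is
#'   absent from the database.
#' @export
lookup_kmer <- function(db, code) {
  stopifnot(inherits(db, "aakmer_db"), length(code) == 1L)
  i <- match(as.integer(code), db$kmer_codes)
  if (is.na(i)) return(integer(0))
  db$combos[[db$kmer_combo[i]]]
}

#' Fetch one protein record
#'
#' @param db opened database.
#' @param pid 0-based protein identifier.
#' @return list with `pid`, `name`, `length`, `sequence` (empty string when
#'   the database was built without stored sequences) and `annotations`
#'   (named character vector, possibly empty).
#' @export
get_protein <- function(db, pid) {
  stopifnot(inherits(db, "aakmer_db"), length(pid) == 1L)
  pid <- as.integer(pid)
  if (is.na(pid) || pid < 0L || pid >= nrow(db$proteins))
    stop("unknown pid: ", pid, " (database holds pids 0..",
         nrow(db$proteins) - 1L, ")", call. = FALSE)
  row <- db$proteins[pid + 1L, ]
  fixed <- c("pid", "name", "length", "sequence")
  ann_fields <- setdiff(names(row), fixed)
  list(
    pid = row$pid, name = row$name, length = row$length,
    sequence = row$sequence,
    annotations = stats::setNames(
      vapply(ann_fields, function(f) as.character(row[[f]]), character(1)),
      ann_fields
    )
  )
}

#' Database metadata
#'
#' @param db opened database.
#' @return named list: k, key widths, protein / distinct-7-mer / combination
#'   counts, format version, build time.
#' @export
db_info <- function(db) {
  stopifnot(inherits(db, "aakmer_db"))
  db$meta
}

#' @export
print.aakmer_db <- function(x, ...) {
  cat("aakmer database:", x$dir, "\n")
  cat("  proteins:       ", x$meta$n_proteins, "\n")
  cat("  distinct 7-mers:", x$meta$n_kmers, "\n")
  cat("  combinations:   ", x$meta$n_combinations, "\n")
  cat("  sequences stored:", x$meta$store_sequences, "\n")
  invisible(x)
}
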