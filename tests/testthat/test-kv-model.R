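test_that("combination ids are order-invariant, deterministic, and salt-sensitive", {
  expect_identical(combination_id(c(1L, 2L)), combination_id(c(2L, 1L)))
  expect_identical(combination_id(1L), combination_id(1L))
  expect_identical(combination_id(c(3L, 3L, 5L)), combination_id(c(5L, 3L)))
  expect_false(combination_id(1L) == combination_id(1L, salt = 1L))
  expect_match(combination_id(0L), "^[0-9a-f]{16}$")
  expect_error(combination_id(integer(0)), "zero proteins")
})

test_that("all 1023 subsets of {0..9} get pairwise-distinct ids after consing", {
  sets <- unlist(lapply(1:10, function(k)
    utils::combn(0:9, k, simplify = FALSE)), recursive = FALSE)
  expect_length(sets, 1023L)
  ids <- aakmer:::.cons_combination_ids(sets)
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("collision re-salting keeps distinct sets on distinct keys", {
  # identical sets reuse the key; a forced duplicate of the pid-set list
  # must not be re-salted
  sets <- list(c(0L, 1L), c(0L, 1L), 2L)
  ids <- aakmer:::.cons_combination_ids(sets)
  expect_identical(ids[1L], ids[2L])
  expect_false(ids[1L] == ids[3L])
})

test_that("a single-protein build populates the three stores as expected", {
  db <- build_database(data.frame(id = "p1", sequence = "ACDEFGHIK"),
                       tempfile("db"))
  info <- db_info(db)
  expect_identical(info$n_kmers, 3L)          # L - 6 windows
  expect_identical(info$n_combinations, 1L)   # all map to {0}
  expect_identical(info$n_proteins, 1L)
  expect_identical(lookup_kmer(db, encode_kmer("ACDEFGH")), 0L)
  expect_identical(lookup_kmer(db, encode_kmer("YYYYYYY")), integer(0))
  rec <- get_protein(db, 0L)
  expect_identical(rec$name, "p1")
  expect_identical(rec$length, 9L)
  expect_identical(rec$sequence, "ACDEFGHIK")
})

test_that("identical proteins share one combination {0,1}", {
  expect_warning(
    db <- build_database(
      data.frame(id = c("p1", "p1"), sequence = c("ACDEFGHIK", "ACDEFGHIK")),
      tempfile("db")),
    "duplicate")
  expect_identical(db_info(db)$n_combinations, 1L)
  expect_identical(lookup_kmer(db, encode_kmer("ACDEFGH")), c(0L, 1L))
})

test_that("k-mers with identical protein sets reuse one stored combination", {
  # p0 and p1 share the prefix ACDEFGHIK; its 3 7-mers must resolve through
  # a single hash-consed combination, distinct from the singleton sets
  db <- build_database(
    data.frame(id = c("p0", "p1"),
               sequence = c("ACDEFGHIKWWMKVLT", "ACDEFGHIKYYYPQRS")),
    tempfile("db"))
  shared_codes <- encode_kmer(c("ACDEFGH", "CDEFGHI", "DEFGHIK"))
  combo_idx <- db$kmer_combo[match(shared_codes, db$kmer_codes)]
  expect_identical(length(unique(combo_idx)), 1L)
  expect_identical(db$combos[[unique(combo_idx)]], c(0L, 1L))
  expect_gt(db_info(db)$n_combinations, 1L)
})

test_that("lookup agrees with a brute-force substring scan on a random fixture", {
  fix <- make_fixture_db(n = 20L, seed = 101L)
  for (code in fix$db$kmer_codes) {
    word <- decode_kmer(code)
    expected <- which(vapply(fix$proteins$sequence, grepl,
                             logical(1), pattern = word, fixed = TRUE,
                             USE.NAMES = FALSE)) - 1L
    expect_identical(lookup_kmer(fix$db, code), expected)
  }
})

test_that("build rejects empty and unindexable inputs, flags out-of-range pids", {
  expect_error(build_database(data.frame(id = character(0),
                                         sequence = character(0)),
                              tempfile("db")), "at least one")
  expect_error(build_database(data.frame(id = "p1", sequence = "ACD"),
                              tempfile("db")), "no indexable")
  db <- build_database(data.frame(id = "p1", sequence = "ACDEFGHIK"),
                       tempfile("db"))
  expect_error(get_protein(db, 1L), "unknown pid")
  expect_error(get_protein(db, -1L), "unknown pid")
})

test_that("annotations round-trip through the protein store verbatim", {
  ann <- data.frame(id = c("p2", "p1"),
                    gene = c("blaOXA-2", "aph(3')-IIb"),
                    class = c("beta-lactam", "aminoglycoside"),
                    stringsAsFactors = FALSE)
  db <- build_database(
    data.frame(id = c("p1", "p2"),
               sequence = c("ACDEFGHIK", "MKVLTAGWW"),
               desc = c("first protein", "")),
    tempfile("db"), annotations = ann)
  r1 <- get_protein(db, 0L)
  expect_identical(unname(r1$annotations["gene"]), "aph(3')-IIb")
  expect_identical(unname(r1$annotations["description"]), "first protein")
  r2 <- get_protein(db, 1L)
  expect_identical(unname(r2$annotations["class"]), "beta-lactam")
})

test_that("building twice yields identical logical stores, reopened from disk", {
  set.seed(55)
  prot <- data.frame(id = sprintf("p%02d", 1:15),
                     sequence = vapply(sample(20:80, 15, TRUE), rand_aa_seq,
                                       character(1)),
                     stringsAsFactors = FALSE)
  d1 <- tempfile("db1"); d2 <- tempfile("db2")
  db1 <- build_database(prot, d1)
  db2 <- build_database(prot, d2)
  expect_identical(db1$kmer_codes, db2$kmer_codes)
  expect_identical(db1$combo_ids, db2$combo_ids)
  expect_identical(db1$combos, db2$combos)
  expect_identical(db1$proteins, db2$proteins)

  reopened <- open_database(d1)
  expect_identical(reopened$kmer_codes, db1$kmer_codes)
  expect_identical(reopened$combos[reopened$kmer_combo],
                   db1$combos[db1$kmer_combo])
  expect_identical(reopened$proteins, db1$proteins)
})

test_that("referential integrity holds after every build", {
  for (seed in c(1L, 2L, 3L)) {
    fix <- make_fixture_db(n = 12L, seed = seed)
    db <- fix$db
    # every combination referenced by the k-mer store exists
    expect_true(all(db$kmer_combo %in% seq_along(db$combos)))
    # every pid in any combination exists in the protein store
    expect_true(all(unlist(db$combos) %in% db$proteins$pid))
    # exactly one combination per distinct pid-set
    keys <- vapply(db$combos, paste, character(1), collapse = ",")
    expect_identical(anyDuplicated(keys), 0L)
    # every protein with >= 1 canonical window appears in >= 1 combination
    indexable <- nchar(fix$proteins$sequence) >= 7L
    expect_true(all((which(indexable) - 1L) %in% unlist(db$combos)))
  }
})

test_that("on-disk key widths are 4 bytes (k-mer) and 8 bytes (combination)", {
  fix <- make_fixture_db(n = 5L, seed = 9L)
  info <- db_info(fix$db)
  expect_identical(info$kmer_key_bytes, 4L)
  expect_identical(info$combination_key_bytes, 8L)
  kfile <- file.path(fix$db$dir, "kmer_store.bin")
  expect_identical(file.size(kfile), (4 + 8) * info$n_kmers)
  cfile <- file.path(fix$db$dir, "combination_store.bin")
  expect_identical(file.size(cfile),
                   sum(8 + 4 + 4 * lengths(fix$db$combos)))
})
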