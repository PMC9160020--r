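test_that("k-mer matching reports shared counts and ratios as specified", {
  db <- build_database(data.frame(id = "p0", sequence = "ACDEFGHIK"),
                       tempfile("db"))
  h <- kmer_match(db, "q", "ACDEFGHM", search_options(min_kmatch = 1L))
  expect_identical(nrow(h), 1L)
  expect_identical(h$shared_kmers, 1L)   # of 2 distinct query 7-mers
  expect_equal(h$ratio, 0.5)

  # default sensitivity mode needs >= 10 shared 7-mers: 1 < 10, no hit
  expect_identical(nrow(kmer_match(db, "q", "ACDEFGHM")), 0L)

  self <- kmer_match(db, "p0", "ACDEFGHIK", search_options(min_kmatch = 1L))
  expect_identical(self$shared_kmers[1L], 3L)
  expect_equal(self$ratio[1L], 1.0)
  expect_identical(self$target_pid[1L], 0L)
})

test_that("queries without canonical 7-mers are flagged unqueryable", {
  db <- build_database(data.frame(id = "p0", sequence = "ACDEFGHIK"),
                       tempfile("db"))
  h <- kmer_match(db, "q", "XXXXXXXXXX", search_options(min_kmatch = 1L))
  expect_identical(nrow(h), 0L)
  expect_true(isTRUE(attr(h, "unqueryable")))
})

test_that("shared counts equal brute-force 7-mer set intersection on random fixtures", {
  for (seed in c(11L, 12L, 13L)) {
    fix <- make_fixture_db(n = 30L, len_range = c(20L, 150L), seed = seed)
    set.seed(seed + 1000L)
    # queries: database members, mutants, and unrelated sequences
    queries <- c(sample(fix$proteins$sequence, 3L),
                 vapply(1:3, function(i) rand_aa_seq(60L), character(1)))
    opts <- search_options(min_kmatch = 1L, max_results = Inf)
    for (q in queries) {
      hits <- kmer_match(fix$db, "q", q, opts)
      expected <- vapply(fix$proteins$sequence, brute_shared, integer(1),
                         query = q, USE.NAMES = FALSE)
      got <- integer(nrow(fix$proteins))
      got[hits$target_pid + 1L] <- hits$shared_kmers
      expect_identical(got, expected)
    }
  }
})

test_that("hits are ranked by shared count then pid, truncated to max_results", {
  fix <- make_fixture_db(n = 25L, seed = 77L)
  # a chimera of several database proteins guarantees many targets
  q <- paste(fix$proteins$sequence[c(1L, 8L, 15L, 22L)], collapse = "")
  all_hits <- kmer_match(fix$db, "q", q,
                         search_options(min_kmatch = 1L, max_results = Inf))
  expect_gte(nrow(all_hits), 4L)
  expect_true(all(diff(all_hits$shared_kmers) <= 0L))
  ties <- split(all_hits$target_pid, all_hits$shared_kmers)
  expect_true(all(vapply(ties, function(p) all(diff(p) > 0L), logical(1))))
  top3 <- kmer_match(fix$db, "q", q,
                     search_options(min_kmatch = 1L, max_results = 3L))
  expect_identical(top3, all_hits[1:3, ])
})

test_that("raising min_kmatch or min_ratio never increases the hit count", {
  fix <- make_fixture_db(n = 30L, seed = 21L)
  q <- fix$proteins$sequence[5L]
  n_at <- function(mk, mr) nrow(kmer_match(
    fix$db, "q", q, search_options(min_kmatch = mk, min_ratio = mr,
                                   max_results = Inf)))
  counts_k <- vapply(c(1L, 2L, 5L, 10L, 20L), n_at, integer(1), mr = 0)
  expect_true(all(diff(counts_k) <= 0L))
  counts_r <- vapply(c(0, .1, .25, .5, .9, 1), n_at, integer(1), mk = 1L)
  expect_true(all(diff(counts_r) <= 0L))
})

test_that("every protein retrieves itself first with ratio 1 at min_kmatch 1", {
  fix <- make_fixture_db(n = 20L, seed = 5L)
  opts <- search_options(min_kmatch = 1L)
  for (i in seq_len(nrow(fix$proteins))) {
    h <- kmer_match(fix$db, fix$proteins$id[i], fix$proteins$sequence[i],
                    opts)
    expect_identical(h$target_pid[1L], i - 1L)
    expect_equal(h$ratio[1L], 1.0)
  }
})

test_that("Smith-Waterman reproduces hand-checked alignments", {
  a <- smith_waterman("AAAA", "AAAA")          # 4 x (A<->A = 4)
  expect_identical(a$raw_score, 16L)
  expect_equal(a$pct_identity, 100)
  expect_identical(c(a$q_start, a$q_end, a$t_start, a$t_end),
                   c(1L, 4L, 1L, 4L))

  b <- smith_waterman("AAAA", "CCCC")          # A<->C = 0: empty alignment
  expect_identical(b$raw_score, 0L)
  expect_true(is.na(b$q_start))

  expect_error(smith_waterman("AAAA", "AAAA", matrix = "NOSUCH"),
               "unknown substitution matrix")
})

test_that("Smith-Waterman scores are symmetric and match the naive dynamic program", {
  set.seed(88)
  for (i in 1:200) {
    q <- rand_aa_seq(sample(5:40, 1L))
    t <- rand_aa_seq(sample(5:40, 1L))
    go <- sample(c(5L, 11L), 1L)
    ge <- sample(c(1L, 2L), 1L)
    got <- smith_waterman(q, t, gap_open = go, gap_extend = ge)$raw_score
    expect_identical(got, as.integer(naive_sw_score(q, t, blosum62, go, ge)))
  }
  for (i in 1:25) {
    q <- rand_aa_seq(30L); t <- rand_aa_seq(30L)
    expect_identical(smith_waterman(q, t)$raw_score,
                     smith_waterman(t, q)$raw_score)
  }
})

test_that("Smith-Waterman agrees with Biostrings local alignment", {
  # Biostrings charges gapOpening + gapExtension on the first gap column,
  # so its (gap_open - gap_extend, gap_extend) equals our (gap_open, gap_extend)
  set.seed(99)
  for (i in 1:25) {
    q <- rand_aa_seq(sample(10:40, 1L))
    t <- rand_aa_seq(sample(10:40, 1L))
    ref <- Biostrings::pairwiseAlignment(
      q, t, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
    got <- smith_waterman(q, t, gap_open = 11L, gap_extend = 1L)$raw_score
    expect_identical(got, as.integer(max(0, ref)))
  }
})

test_that("bit scores follow the Karlin-Altschul normalization", {
  expect_equal(bit_score(0), -log(0.041) / log(2))
  expect_equal(bit_score(16), (0.267 * 16 - log(0.041)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(bit_score(16), 2), 10.77)
  s <- bit_score(0:50)
  expect_true(all(diff(s) > 0))
  expect_error(bit_score(10, lambda = 0), "lambda")
  expect_error(bit_score(10, K = 1.2), "K must")
  expect_error(bit_score(-1), "raw_score")
})

test_that("alignment mode keeps exactly the alignment-free result set", {
  fix <- make_fixture_db(n = 20L, seed = 61L)
  queries <- data.frame(id = c("q1", "q2"),
                        sequence = fix$proteins$sequence[c(3L, 9L)])
  for (mk in c(1L, 5L)) {
    plain <- search(fix$db, queries, "protein",
                    search_options(min_kmatch = mk, max_results = Inf))
    aln <- search(fix$db, queries, "protein",
                  search_options(min_kmatch = mk, max_results = Inf,
                                 align = TRUE))
    key <- function(h) sort(paste(h$query, h$target_pid))
    expect_identical(key(aln), key(plain))
    expect_true(all(c("raw_score", "bit_score", "pct_identity")
                    %in% names(aln)))
    # bit-score re-ranking within each query
    for (q in unique(aln$query))
      expect_true(all(diff(aln$bit_score[aln$query == q]) <= 0))
  }
})

test_that("translated DNA queries recover indexed proteins with coordinates", {
  prot <- "MKVLTAGWWACDEFGHIK"
  db <- build_database(data.frame(id = "p0", sequence = prot),
                       tempfile("db"))
  dna <- reverse_translate(prot)
  hits <- search(db, data.frame(id = "g1", sequence = dna), "dna",
                 search_options(min_kmatch = 1L))
  fwd <- hits[hits$frame == 1L, ]
  expect_identical(nrow(fwd), 1L)
  expect_equal(fwd$ratio, 1.0)
  expect_identical(fwd$dna_start, 1L)
  expect_identical(fwd$dna_end, nchar(dna))

  # same gene on the reverse strand: frame sign flips, same span
  hits_rc <- search(db, data.frame(id = "g1", sequence = revcomp_chr(dna)),
                    "dna", search_options(min_kmatch = 1L))
  rev <- hits_rc[hits_rc$frame < 0L & hits_rc$ratio == 1.0, ]
  expect_identical(nrow(rev), 1L)
  expect_identical(rev$frame, -1L)
  expect_identical(rev$dna_start, 1L)
  expect_identical(rev$dna_end, nchar(dna))

  # alignment mode narrows the DNA span to the aligned region; a verbatim
  # hit aligns end to end
  aln <- search(db, data.frame(id = "g1", sequence = dna), "dna",
                search_options(min_kmatch = 1L, align = TRUE))
  a1 <- aln[aln$frame == 1L, ]
  expect_identical(c(a1$dna_start, a1$dna_end), c(1L, nchar(dna)))
  expect_equal(a1$pct_identity, 100)
})

test_that("search handles empty query files and guards alignment mode", {
  db <- build_database(data.frame(id = "p0", sequence = "ACDEFGHIK"),
                       tempfile("db"))
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  h <- search(db, empty, "protein", search_options(min_kmatch = 1L))
  expect_identical(nrow(h), 0L)

  noseq <- build_database(data.frame(id = "p0", sequence = "ACDEFGHIK"),
                          tempfile("db"), store_sequences = FALSE)
  expect_error(search(noseq, empty, "protein",
                      search_options(align = TRUE)),
               "stored sequences")
})

test_that("annotation fields can be attached to hits", {
  ann <- data.frame(id = "p0", gene = "fosA", class = "fosfomycin")
  db <- build_database(data.frame(id = "p0", sequence = "ACDEFGHIK"),
                       tempfile("db"), annotations = ann)
  h <- search(db, data.frame(id = "q", sequence = "ACDEFGHIK"), "protein",
              search_options(min_kmatch = 1L),
              annotation_fields = c("gene", "class"))
  expect_identical(h$gene, "fosA")
  expect_identical(h$class, "fosfomycin")
  expect_error(search(db, data.frame(id = "q", sequence = "ACDEFGHIK"),
                      "protein", search_options(min_kmatch = 1L),
                      annotation_fields = "nope"), "unknown annotation")
})
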