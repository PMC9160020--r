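---
title: "aakmer: design and methods of the amino-acid 7-mer search engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aakmer: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aakmer)
```

## The problem and the approach

Protein identification in (meta)genomics usually routes through alignment
software. `aakmer` takes the alignment-free route: a protein collection is
indexed by its amino-acid 7-mers, and a query is scored against every target
by the number of *exact* 7-mers they share. This trades sensitivity to
distant homology for speed and simplicity: close homologues share many exact
7-mers, and counting them requires only index lookups. An optional
Smith-Waterman pass refines the scoring of the hits the alignment-free stage
already found — it never changes which (query, target) pairs are reported.

## The triple store

A database holds three logical key-value stores:

* **k-mer store** — maps each 7-mer code to the key of the protein-set that
  contains it. The word length is fixed at 7 residues because
  $20^7 = 1.28\times10^9 < 2^{32}$: every word packs into a 4-byte key
  (base-20 positional code, $A=0 \dots Y=19$, leftmost residue most
  significant), keeping the store compact while retaining specificity.
* **combination store** — maps an 8-byte key to a sorted set of protein
  identifiers. Keys are produced by *hash-consing* (the flyweight pattern):
  every distinct pid-set is hashed once (xxhash64 over the sorted,
  comma-joined list) and all k-mers contained in exactly that set of
  proteins reference the single stored copy. Correctness never relies on
  hash injectivity: a colliding insert is re-salted deterministically
  (`salt = 1, 2, ...`) until a free key is found, so within one database
  distinct sets always have distinct keys.
* **protein store** — pid → name, length, sequence (optionally) and
  free-form annotation fields, joined from a TSV keyed by FASTA identifier.

On disk these are flat files of fixed-width big-endian records (so iteration
order is numeric), a TSV and a JSON metadata file; `open_database()` reads
them into memory once, which is what makes the HTTP service cheap per
request. Any engine satisfying this mapping contract would do — the store
layout here favours transparency and byte-level testability over
write-optimized designs. The build accumulates the (code → pid-set) map in
one in-memory pass; the scales this package targets never approach a memory
budget that would require external merging, and the on-disk result is
independent of input chunking by construction (the map is keyed, not
appended).

Non-canonical residues (`X`, `B`, `Z`, `J`, `U`, `O`, `*`, …) are handled by
*skipping every 7-residue window that contains one*, at build and query time
alike. Remapping them would manufacture exact matches that are not exact;
skipping preserves the semantics at the cost of a few windows around each
ambiguity. Sequences shorter than 7 residues contribute nothing and a query
with zero canonical windows is reported as unqueryable rather than silently
empty-handed.

## Search semantics

For a query with $n_q$ distinct canonical 7-mers and a target sharing $s$ of
them:

* `shared_kmers` $= s$ counts **distinct** query words found in the target,
  not positional occurrences — the store maps a word to a protein *set*, so
  multiplicities do not exist in the index, and the score inherits that.
* `ratio` $= s / n_q$, the alignment-free score in $[0, 1]$. For translated
  DNA/read queries the denominator is per stop-free segment.

Hits must pass `min_kmatch` (default 10; 1 is the most sensitive mode) and
`min_ratio` (default 0), and are ranked by `shared_kmers` descending with
ties broken by ratio descending, then target pid ascending — a deterministic
total order. Raising either threshold can only shrink the hit set.

DNA and FASTQ queries are translated in all six frames (standard code;
fuzzy codons → `X`), each frame split at stop codons, and every segment of
length ≥ 7 searched independently. Coordinates are reported 1-based
inclusive on the forward strand with strand carried by the frame sign, so
GFF output needs no further arithmetic. FASTQ qualities are parsed
(structure-checked) and discarded: results are independent of quality
strings by contract.

### Alignment refinement

`align = TRUE` runs an exact affine-gap Smith-Waterman (no banding, no
heuristics; compiled dynamic program with full traceback) of the query
against each *reported* target's stored sequence. A gap of length $L$ costs
`gap_open` $+ (L-1)\,$`gap_extend` (defaults 11/1 with BLOSUM62; any
Biostrings matrix may be named). Raw scores are normalized to bits,
$S' = (\lambda S - \ln K)/\ln 2$, with the standard gapped BLOSUM62
constants $\lambda = 0.267$, $K = 0.041$ (configurable); no E-value is
computed. Hits are re-ranked by bit score, but the *set* of pairs is
exactly the alignment-free result set — alignment improves scoring, not
retrieval. For translated queries the reported DNA span is narrowed to the
aligned region. When no cell of the matrix is positive the score is 0 and
the alignment is empty (`NA` spans) rather than an arbitrary anchor.

## The service

`serve()` opens a database once and exposes `GET /info` and
`POST /search` (raw FASTA/FASTQ body, options as query parameters) over
httpuv; `client_search()` reconstructs exactly the data frame a local
`search()` returns, and the suite asserts byte-identical TSV renderings.
Requests are handled sequentially on one event loop — concurrent clients
are served in arrival order, which keeps responses deterministic; there is
no authentication or TLS. The endpoint schema is this package's own
convention.

## The synthetic benchmark

`generate_families()` emulates a homology-group database: one random
ancestor per family, members derived by independent per-residue
substitutions at rate `sub_rate` (replacement uniform over the 19 other
residues). The benchmark conditions used throughout — 20 families × 10
members, length 120, `sub_rate` 0.15 — give members that differ pairwise at
≈ 28% of sites, deep enough that the k10 and k1 sensitivity modes separate
while an all-vs-all run stays in the seconds range. The generator makes
*substitutions only*: no indels, no length variation, no compositional bias,
no shared domains between families. Passing benchmarks on it therefore
demonstrates the correctness of the index, scoring and sweep machinery — not
retrieval performance on real, indel-rich protein families, where
alignment-free exact matching is known to fade with evolutionary distance.

`evaluate_homology()` implements the homology-pair protocol: self-pairs are
discarded; each *subject* protein is credited at most once, to its
highest-scoring pair (ties by query name ascending — the "identified once"
rule is ambiguous between query- and subject-side crediting, and this
implementation fixes the subject-side reading deterministically); a credited
pair is a true positive iff query and subject share a group. Sweeping the
threshold from high to low gives monotone cumulative tp/fp, with
`precision` $= tp/(tp+fp)$ and `recall` $= tp/N$ for a database of $N$
proteins — the crediting rule makes $tp = N$ the ceiling. On the standard
conditions the k1 mode dominates the k10 mode in recall at every common
threshold, the expected sensitivity ordering.

## Reports

* `annotate_genome_gff()` writes 9-column GFF3 `protein_match` features from
  translated-genome hits, sorted (seqid, start, target) for byte-determinism.
* `arg_report()` counts, per annotated resistance gene, the number of
  distinct query *loci* — one locus = one (source sequence, frame, segment)
  — so tandem copies of a gene are counted separately. Default thresholds
  (90% identity, 80% target coverage) follow common AMR-typing practice and
  are plain arguments.
* `profile_features()` summarizes annotation fields over a hit set:
  `presence` counts distinct hit targets carrying a value, `abundance`
  counts hits to such targets; comma-separated multi-valued fields credit
  each value once per target/hit.

## Numerical and degenerate-input choices

* Codes are exact integers (max $20^7 - 1$ fits R's 32-bit integers); no
  floating-point enters the codec.
* The hash-consed key space is $2^{64}$, represented as 16-hex-char strings
  in R and 8 big-endian bytes on disk.
* `evaluate_homology` on an empty (or all-self) hit set returns a zero-row
  sweep; `kmerize` of short or fully ambiguous input returns zero windows;
  an empty query *file* yields an empty result while an empty FASTA
  *record* is an error.
* Duplicate protein names are kept (distinct pids) with a warning, since
  identifiers, not names, key the stores.

## Problem sizes in the shipped checks

The test-suite fixtures use up to 50 random proteins of length ≤ 300, 200
random peptide pairs (length ≤ 40) for the alignment oracle, and the
20 × 10 family benchmark above; the acceptance script runs the same
benchmark end to end. These sizes characterize correctness exhaustively at
desk scale; nothing in the design caps databases at these sizes, but the
in-memory build is the binding constraint for very large collections.
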