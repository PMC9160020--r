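# aakmer

Alignment-free protein search built on an amino-acid 7-mer index, for
genomics and metagenomics workflows that need fast identification of close
protein homologues with rich annotations attached — plus an HTTP
microservice so a database can be opened once and queried remotely.

## The method

A protein collection is indexed into three logical key-value stores:

* **k-mer store** — every canonical 7-mer, packed into a 4-byte key
  (base-20 positional code over the 20 residues, `A`=0 … `Y`=19;
  20⁷ − 1 = 1,279,999,999 < 2³²), pointing at
* **combination store** — hash-consed 8-byte keys, one per *distinct set*
  of protein identifiers, shared by all 7-mers contained in exactly that
  set of proteins (the flyweight pattern), pointing at
* **protein store** — per-protein record: name, length, sequence and
  free-form annotation fields from a TSV.

A query with *n<sub>q</sub>* distinct canonical 7-mers is scored against
every target by the shared count *s* and the ratio *s / n<sub>q</sub>*;
hits pass `min_kmatch` (default 10; use 1 for the most sensitive mode) and
`min_ratio` filters. Optional refinement runs an exact affine-gap
Smith-Waterman (gap of length *L* costs `gap_open` + (*L*−1)·`gap_extend`;
BLOSUM62 11/1 by default) on the already-reported hits and re-ranks them by
bit score *S′* = (λS − ln K)/ln 2 (λ = 0.267, K = 0.041) — alignment never
changes which pairs are reported. DNA and FASTQ queries are translated in
six frames and searched per stop-free segment, with 1-based forward-strand
coordinates carried into the output.

## Worked example

```r
library(aakmer)

db <- build_database(data.frame(id = "p1", sequence = "ACDEFGHIK"),
                     out_dir = tempfile("db"))
db_info(db)[c("n_proteins", "n_kmers", "n_combinations")]
#> $n_proteins
#> [1] 1
#> $n_kmers
#> [1] 3          # the 3 windows ACDEFGH, CDEFGHI, DEFGHIK
#> $n_combinations
#> [1] 1          # all three share the protein set {0}

kmer_match(db, "q", "ACDEFGHM", search_options(min_kmatch = 1))
#>   query target_pid target_name shared_kmers ratio target_length
#> 1     q          0          p1            1   0.5             9
```

The query `ACDEFGHM` has two distinct 7-mers; one (`ACDEFGH`) occurs in
`p1`, so the hit reports 1 shared 7-mer and ratio 0.5. With the default
`min_kmatch = 10` the same query reports nothing. Alignment mode attaches
Smith-Waterman scores to the same hit set:

```r
smith_waterman("AAAA", "AAAA")[c("raw_score", "pct_identity")]
#> $raw_score
#> [1] 16        # 4 x (A<->A = 4 under BLOSUM62)
#> $pct_identity
#> [1] 100
round(bit_score(16), 2)
#> [1] 10.77
```

A database also serves over HTTP (`serve(dbdir, port = 8553)`), with
`client_search()` returning exactly what a local `search()` would. The
command-line interface wraps the same functions:

```sh
Rscript inst/exec/aakmer db-build -i proteins.fasta -a annotations.tsv -o DBDIR
Rscript inst/exec/aakmer search -d DBDIR -i genome.fasta -t dna --aln -m 1 -o hits.tsv
```

Downstream helpers turn hits into GFF3 genome annotations
(`annotate_genome_gff`), per-gene antimicrobial-resistance tables with
tandem copies counted per locus (`arg_report`), and presence/abundance
profiles of annotation features (`profile_features`).

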