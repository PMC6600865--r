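# tfkit

Data structures and queries for transcription-factor (TF) bioinformatics.

## The problem

Work with human TFs is fragmented across resources that do not share a
nomenclature: motif-model catalogs (CISBP-style, identifiers such as
`T004843_1.02`), binding-model collections (HOCOMOCO-style, with TFClass
subfamily suffixes such as `{2.3.3}` on class strings), Gene Ontology
annotations (`GO:0003700`, "DNA binding transcription factor activity"), and
MSigDb-style TF-target (TFT) gene sets whose names pack motif, gene and
version tokens into underscore-delimited strings like
`GGGNNTTTCC_NFKB_Q6_01`. Integrative analyses — e.g. asking which TFs are
direct GWAS hits for a trait, or which traits are enriched among a TF's
targets — need these resources harmonized onto a common key. `tfkit` uses the
HGNC gene symbol as that key and provides:

* **Catalogs** — an S4 `TFCatalog` (native ids + a metadata table with an
  obligatory `HGNC` column), loaders for CISBP-, HOCOMOCO- and GO-schema
  snapshots, HGNC universes, membership-signature overlap tables
  (`overlap_counts`), class-frequency tables, and TFClass suffix parsing.
* **Target sets** — GMT read/write, TFT set-name parsing with a documented
  exact/close/unknown HGNC matching heuristic, set grep, identifier
  remapping, and per-TF target unions.
* **Binding tracks** — interval queries over position-sorted, optionally
  bgzip+tabix-indexed BED-like tracks of motif-scan scores (p-values carried
  as `-log10 p`, with `p = 0` capped at 400), a reduce-by-file harvest over
  track sets, family annotation from a catalog, narrowPeak reading, and
  per-experiment ChIP-seq peak retrieval from an experiment registry.
  All internal coordinates are 0-based half-open; command-line regions are
  1-based inclusive and converted at the boundary.
* **GWAS joins** — `direct_hits(trait, ...)` (TFs appearing as mapped genes
  for a trait) and `top_traits_of_targets(tf, ...)` (per-trait record counts
  over a TF's target genes), with mapped-gene fields split on the `"; "`,
  `", "` and `" - "` delimiters.
* **Fixtures** — deterministic generators for all of the above with planted,
  exactly-known structure, so everything runs and tests offline.
* **CLI** — `exec/tfkit` with subcommands `catalog`, `targets`, `binding`,
  `gwas`, `fixtures`; TSV/JSON to `--out` or stdout, logs to stderr.

## Worked example

```r
library(tfkit)

# four synthetic catalog snapshots with planted overlap structure
suite <- make_catalog_suite(seed = 1)
head(overlap_counts(unname(suite$catalogs)), 5)
#>               region count n_catalogs
#> 1              CISBP   475          1
#> 2          CISBP&TFT   200          2
#> 3 CISBP&HOCOMOCO&TFT   180          3
#> 4                TFT   160          1
#> 5     CISBP&HOCOMOCO   150          2

suite$catalogs$CISBP
#> TFCatalog instance CISBP
#>   2647 native ids (T000001_1.02 ... T002647_1.02)
#>   1344 unique HGNC symbols
```

The `region` column is the membership signature (which catalogs contain a
symbol); `count` is the number of unique HGNC symbols with exactly that
signature, so the counts sum to the size of the union of all universes. The
CISBP-style catalog has more native ids (motif models) than symbols because
several models map to one gene.

```r
# TFT set-name parsing: motif token, gene token, version qualifiers
str(parse_tft_name("GGGNNTTTCC_NFKB_Q6_01",
                   hgnc_universe(suite$catalogs$CISBP))[
      c("motif_token", "gene_token", "match_kind", "qualifier_tokens")])
#> List of 4
#>  $ motif_token     : chr "GGGNNTTTCC"
#>  $ gene_token      : chr "NFKB"
#>  $ match_kind      : chr "unknown"
#>  $ qualifier_tokens: chr [1:2] "Q6" "01"
```

`NFKB` is a legacy name, not an HGNC symbol, so the match kind is `unknown` —
the parser reports rather than guesses.

```r
# harvest scored binding sites in a window of interest
trk <- make_scored_track(seed = 1, n_files = 4, sites_per_file = 200)
hits <- query_track(trk$tracks$files[1],
                    genomic_interval("chr17", 38.077e6, 38.084e6))
head(hits, 3)
#>   chrom    start      end motif_id  score strand      pvalue neglog10p
#> 1 chr17 38077409 38077421  M2016_1  1.177      - 1.76219e-08  7.753947
#> 2 chr17 38079034 38079046  M2016_1 19.330      - 7.87539e-02  1.103728
#> 3 chr17 38080521 38080533  M2016_1 21.467      + 3.02594e-03  2.519140
```

The same query through the tabix index and through a full linear scan returns
identical records; `neglog10p` is the `-log10`-transformed motif-scan
p-value.

From a shell, the same workflows run via the CLI:

```sh
exec/tfkit fixtures make --dir /tmp/fx --seed 1
exec/tfkit binding query --manifest /tmp/fx/tracks/manifest.tsv \
    --region chr17:38077001-38084000 --out hits.tsv
exec/tfkit gwas direct-hits --gwas /tmp/fx/gwas/gwas.tsv \
    --cisbp /tmp/fx/catalogs/cisbp.tsv --trait "Trait A"
```

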