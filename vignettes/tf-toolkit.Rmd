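---
title: "Harmonizing transcription-factor catalogs, target sets, binding tracks and GWAS records"
author: "tfkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing transcription-factor catalogs, target sets, binding tracks and GWAS records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfkit)
```

# Scope and model

Transcription factors (TFs) are proteins that bind DNA, typically near
promoters, and modulate transcription. Bioinformatic work with TFs is
complicated by the lack of a shared nomenclature across the resources that
catalog them: motif-model collections key records by model ids, binding-model
collections by model names, ontology annotations by gene symbols, and
TF-target gene-set collections by composite set names. `tfkit` treats the
HGNC gene symbol as the harmonization key and builds four thin, explicit
layers on top of it: catalogs, target sets, binding tracks, and GWAS joins.
A fifth layer, the fixture generators, exists so that every operation is
exercisable and testable with no network access.

This vignette explains the modelling choices, the tunable parameters and
their defaults, the numerical conventions, and what the synthetic fixtures
do and do not establish about real data.

# Catalogs

A `TFCatalog` holds a catalog label, the vector of catalog-native record
identifiers, and a metadata table with exactly one row per record and an
obligatory `HGNC` column. Two deliberate asymmetries are preserved rather
than normalized away:

* **Duplicate native ids and repeated symbols are kept.** Motif-model
  catalogs legitimately map several models to one gene (a CISBP-style
  snapshot can have thousands more records than unique symbols), so
  deduplication happens only when a *universe* is requested.
* **Missing or blank HGNC values stay in the table** but are excluded from
  universes; `hgnc_universe()` reports how many it excluded via the
  `n_blank` attribute, so silent shrinkage is visible.

Symbol comparison is case-sensitive after stripping surrounding whitespace.
No alias expansion happens in this layer: alias handling is a property of
the heuristic set-name matcher (below), where it can be replaced, not of the
catalog contract. Loader column matching is exact on canonical names, with a
user-suppliable rename map, because header spellings vary across snapshot
vintages (one widely used snapshot spells a column "Transcription factor",
with a space).

The GO loader takes only *direct* annotations to the requested term
(default `GO:0003700`) and performs no ontology-ancestor propagation.
Counts produced this way are therefore smaller than ontology browsers that
fold in descendant or related terms report; that is intended behaviour, not
disagreement.

`overlap_counts()` assigns every symbol in the union of the input universes
its membership signature — the set of catalogs containing it — and counts
symbols per signature. Signatures are rendered as the member catalog names
sorted alphabetically and joined with `&`, which makes the output invariant
to the order catalogs are passed in; rows sort by descending count with ties
broken by signature string. Two invariants are enforced by tests:
counts sum exactly to the union size (every symbol has exactly one
signature), and permuting the input list changes nothing but nothing.

`class_frequency()` counts *distinct* TFs per class value — a TF represented
by five records in one class counts once — and breaks count ties by class
string ascending. The tie rule is a determinism choice: a frequency-ranked
table needs a total order, and the class string is the only other column.

TFClass subfamily suffixes on class strings (`...{2.3.3}`) are split by
`parse_tfclass_label()`. A suffix is accepted when it holds one to three
dot-separated non-negative integers; anything else brace-like is treated as
part of the label and flagged `malformed` with a warning, because class
strings are curated free text and a hard error would make whole snapshots
unloadable over one typo.

# Target sets and TFT set names

GMT is read and written directly (tab-separated: name, description,
members). Lines with fewer than three fields are an error naming the line;
duplicate members within a set are dropped with per-set counts reported,
because GMT files in the wild contain repeats and losing that information
silently would bias set sizes. Round-tripping a well-formed collection is
lossless and byte-stable, which the suite checks by writing twice.

TFT-style set names are underscore-delimited strings mixing up to three
vocabularies. The parser classifies tokens in a fixed order:

1. **Motif token**: the first token of length ≥ 6 drawn wholly from the
   IUPAC nucleotide alphabet. The length threshold is what keeps gene-like
   tokens (`MYC`, `GATA`, `E2F1`) from being absorbed as motifs; observed
   motif tokens in real collections are length 9+.
2. **Qualifier tokens**: `Q` followed by digits, bare digits, or a single
   letter — version/quality markers.
3. **Gene token**: the leftmost remaining token; any residue after it joins
   the qualifiers.

Matching the gene token against a supplied HGNC universe is a deliberately
replaceable heuristic: exact case-insensitive lookup (`exact`), then
trailing digits stripped one at a time with a retry at each step (`close`),
else `unknown`. The literal token `UNKNOWN` short-circuits to `unknown`.
Legacy names that are not HGNC symbols (`NFKAPPAB`, `NFKB`) deliberately
stay `unknown`: resolving decades of vintage nomenclature needs curation,
not string surgery, and a wrong silent match is worse than a reported miss.
The parse result keeps all tokens with their roles, and joining the tokens
with underscores always reproduces the raw name — the reconstruction
invariant fuzz-tested over random token strings.

`targets_of()` unions members over every set whose parsed name matches the
requested TF, so versioned duplicate sets (`YY1_Q6`, `YY1_01`) merge rather
than shadow each other.

# Binding tracks and peaks

All internal coordinates are 0-based half-open (the BED convention); the
CLI accepts 1-based inclusive `chrom:start-end` strings and converts once at
that boundary. The overlap predicate everywhere is "any shared base", which
matches tabix semantics.

Scored tracks are BED-like tables with a fixed seven-column dialect —
chrom, start, end, motif id, score, strand, p-value — and the column map is
configurable per call for snapshots that deviate. `query_track()` uses a
tabix index when the file is bgzip-compressed and a `.tbi` sibling exists,
and otherwise scans the file linearly; a corrupt index degrades to the
linear scan with a warning instead of failing. The two paths return
identical record sets, which the test suite asserts record-for-record over
hundreds of random intervals — the indexed path is an optimization, never a
semantic change. Querying a chromosome absent from a track returns an empty
table, not an error, because track sets routinely tile only part of the
genome. Tabix cannot index coordinates beyond 2^29, so indexed query ends
are clamped there; records past that point cannot exist in an indexed file.

P-values are carried into analysis as `-log10(p)`. A p-value of exactly 0
(possible in upstream scan output) maps to a cap of 400 with a `capped`
flag, keeping downstream tables finite while remaining far above any real
score.

`reduce_by_file()` evaluates a per-file, per-interval map over a track set
and returns the file-major nested list, in metadata order; it is
extensionally the cross product of single `query_track()` calls, and an
error in one file is re-signalled with the file's identity attached so a
16-file harvest does not fail anonymously. `annotate_family()` joins track
metadata to a catalog by symbol using the *first* catalog occurrence — the
match rule of a plain index lookup — so results are reproducible when a
symbol carries several family annotations.

narrowPeak files are read as strict BED6+4 (ten columns, summit offset
`peak` with −1 allowed); a wrong column count is an error naming the line.
`peaks_in_region()` reports experiments whose peak file is missing instead
of dropping them, because an absent file and an empty overlap are different
facts.

# GWAS joins

Trait matching in `direct_hits()` is exact, case-sensitive string equality
on the trait field; fuzzy matching is an explicit opt-in at the CLI (via
prior filtering), never a default, because trait strings are curated labels
and substring matches conflate distinct phenotypes. Mapped-gene fields are
split on the three delimiter forms observed in catalog exports (`"; "`,
`", "`, `" - "`). The hit table is unique on HGNC, ordered by first
appearance in the catalog, and each row carries the family value from the
first catalog occurrence.

`top_traits_of_targets()` chains the layers: remap the collection to
symbols (an entrez-typed collection without an id map is an explicit
error), union the TF's target sets, select records with at least one mapped
gene in the target set, and tabulate records per trait. A record counts
once per trait even when several of its mapped genes are targets — the unit
of evidence is the association record, not the gene mention — and counts
therefore sum exactly to the number of hit records. Trait tables sort
alphabetically for determinism. The pipeline is insensitive to record
order, which the suite checks by permutation.

# Synthetic fixtures: what they emulate and what they do not

Every generator plants structure whose ground truth is known exactly and
returns it alongside the files, making the central test loop "module output
equals planted answer". Defaults mirror the published study conditions for
this kind of toolkit: four catalogs whose all-catalog intersection is 119
symbols and whose motif-catalog-exclusive region is 475 (the printed
comparison's counts, used as planting parameters), 16 scored track files,
motif-scan p-values log-uniform over [1e-8, 1] so `-log10 p` spreads evenly
over 0–8 for plotting tables, TFT-style names built from real token
grammars, and a four-cell-line ChIP-seq registry with planted in-region
peak counts. Symbols come from a synthetic namespace plus a handful of real
symbols (`TFAP2B`, `YY1`, `MTF1`, `TP53`) so documented examples run
verbatim. A fixed seed yields byte-identical files.

The fixtures are deliberately simple in ways real data is not: sites are
uniform in position with no spatial autocorrelation, no linkage structure
underlies the GWAS records, catalogs agree perfectly on symbol spelling,
and class labels are drawn from a short list. Passing tests therefore
establish that the *mechanics* — parsing, joining, counting, interval
retrieval — are exact, not that the heuristics (set-name gene matching
above all) are complete against the mess of real nomenclature. That
limitation is inherent to the matcher and documented there.

Problem sizes in the shipped suite (hundreds of sites per track, hundreds
of symbols per catalog, 200-interval query sweeps, 1,000-name parser fuzz)
were chosen as the smallest sizes at which every code path — index block
boundaries, multi-signature overlaps, multi-delimiter splits — is exercised
with comfortable margin.

# Numerical and degenerate-input choices

* Interval validity requires `0 <= start < end`; zero-length intervals are
  rejected at construction rather than silently matching nothing.
* `-log10` cap at p = 0 is 400, flagged.
* Empty required inputs are distinct from malformed ones at the CLI: exit
  code 3 versus 2, with messages to stderr and data only on stdout/`--out`.
* Header-only catalog files are an error (an empty catalog is almost always
  a wrong file), but a GO term absent from an annotation table is a warning
  with an empty catalog (a legitimate query with a negative answer).
* Ties: class frequencies and overlap tables break count ties by label
  ascending; trait tables sort alphabetically.

# Known limitations

Class terminology is not harmonized across catalog schemas — the same
binding-domain family appears under different strings in different
resources, and this package reports them verbatim. The set-name matcher
will not resolve vintage non-HGNC names. No statistical enrichment is
computed over trait tabulations (counts are reported, not p-values); LD or
positional expansion of GWAS hits is out of scope, as is running motif
scans — scores are consumed, not produced.
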