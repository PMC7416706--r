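---
title: "repkit: models, statistics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{repkit: models, statistics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repkit)
```

## The problem

T cell receptor (TCR) repertoire sequencing reads out the CDR3 region of
the TCR β chain as a clonal barcode: each unique rearrangement stands in
for a T cell clone, and its read count for the clone's relative size.
Upstream tools (MiXCR, Decombinator, MiTCR) assemble reads into clonotype
tables; `repkit` consumes those tables and provides the downstream
statistics in a three-tier hierarchy — single-sample description, pairwise
comparison, and multi-sample group analysis — driven by an *experiment
design file* so the same samples can be regrouped by any combination of
study variables (patient, timepoint, tissue, cohort, ...).

## Clonotype identity

A clonotype can be defined at the nucleotide or amino-acid level, with or
without the V/J gene calls. Published analyses use both views and rarely
state which; `repkit` therefore never guesses: every operation takes an
explicit `key_mode` in `{nt, aa, nt+vj, aa+vj}`. The default is `nt+vj`
(CDR3 nucleotide sequence plus gene-level V and J call), the convention of
MiXCR clone tables. Segment calls are collapsed to gene level (allele
suffixes `*01` and alignment scores stripped); of multi-gene hit lists the
first — best-scoring — hit is kept, deterministically, and the number of
such ambiguous calls is surfaced per file.

Non-productive clonotypes (CDR3 with a stop `*` or frameshift `_`, or an
AIRR `productive = F` flag) are filtered by `filter_functional()`. The CLI
applies the filter by default for diversity/overlap analyses (`pairwise`,
`multi`), where non-productive sequences are noise, but not for raw
distribution export (`single`, `convert`); `--functional` /
`--no-functional` forces either behaviour.

## Single-sample statistics

* **Segment usage** — fraction of the repertoire per V or J gene, read
  weighted (Σ counts per gene / total reads; what usage bar plots show) or
  clonotype weighted (clones per gene / clones). Whether published
  spectratype/usage figures weight by reads or clones is typically
  unstated, so both are exposed; read weighting is the default since
  frequency-based plots are the norm.
* **CDR3 spectratype** — mass per CDR3 length, default in nucleotides
  (repertoire peaks are conventionally quoted in bp, e.g. a 45 bp modal
  length for human TRB), optionally stratified by J gene; the stratified
  table marginalises exactly to the unstratified one. Peak ties break
  toward the smaller length, deterministically.
* **Clonotype frequency distribution** — ranked frequencies with
  cumulative sum, maximum clone frequency and D50 (minimal number of top
  clones covering half the reads).

## Pairwise statistics

`overlap_pair()` joins two repertoires exactly on the clonotype key and
reports shared clones with paired frequencies, private clones per side,
and a coefficient of determination. **R² is computed on log10
frequencies**: repertoire overlap scatter plots are log–log, and a
raw-scale R² is dominated by the single largest clone. `log_freq = FALSE`
switches to the raw scale. When fewer than 3 clones are shared, or either
log-frequency vector is constant, R² is reported as an explicit
undefined marker with a reason — never silently 0, which would fake a
signal on tiny overlaps.

`convergence_pair()` quantifies convergent recombination: for each
amino-acid CDR3 it counts the distinct nucleotide sequences encoding it in
each sample and pooled. The default scope is the amino-acid clonotypes
shared by both samples, i.e. the degeneracy of the shared clones; matching
is exact string equality (no 1-mismatch clustering — out of scope).

## Multi-sample statistics

* **Clonal space homeostasis** — read mass per clone-frequency class. The
  default half-open bins `(0,1e-5] … (1e-1,1]`, labelled rare →
  hyperexpanded, follow common repertoire-analysis convention (the edges
  are configurable; published figures show the bins but not their edges).
* **Homeostasis comparison** — Pearson chi-square (no continuity
  correction) on the 2 × k table of *reads* per bin: read mass is what the
  homeostasis plot shows. `use = "clones"` switches to clone counts; bins
  empty in both profiles are dropped with the df reduced.
* **Clonotype tracking** — a frequency matrix of tracked clones over an
  ordered sample list; tracked set = top *n* by maximum frequency across
  samples, or by frequency in a designated anchor sample. Absence is an
  explicit 0.
* **Similarity** — Jaccard and overlap coefficient on clone sets,
  Morisita–Horn `2Σp_iq_i/(Σp_i²+Σq_i²)` and Bhattacharyya `Σ√(p_iq_i)`
  on frequencies over the union key set. All are symmetric with unit
  diagonal and values in [0,1]; Jaccard ≤ overlap coefficient always.
  The original tool's exact estimator list is not published; this set is a
  stated substitute covering the set-based and abundance-based families.
* **Clustering** — agglomerative clustering (average/complete/single
  linkage) on distance 1 − similarity via `stats::hclust`, exported as
  Newick through `ape`.
* **Diversity** — Shannon H = −Σ p_i ln p_i (natural log; a base option
  gives bits), normalized Shannon H/ln S, inverse Simpson 1/Σp_i²,
  Gini–Simpson, clonality 1 − H/ln S (degenerate cases pinned: S = 1 gives
  H = 0, clonality = 1), Chao1 with singletons/doubletons defined on read
  counts and the bias-corrected form when f₂ = 0, and D50.
* **Rarefaction** — `rarefied_diversity()` reports mean ± sd of an index
  over `n_resamples` hypergeometric downsamples to a common depth, the
  depth-fair way to compare samples sequenced to different depths.
  Downsampling is a sequential-conditional multivariate hypergeometric
  draw, bit-reproducible given the seed.
* **Group comparison** — two-sided unpaired Mann–Whitney U. The exact
  null distribution of U is used when both groups have ≤ 8 values and the
  pooled data are tie-free; otherwise the normal approximation with tie
  correction and *no* continuity correction (so identical groups give
  p = 1 exactly). The unpaired test is the right choice for independent
  cohorts (e.g. patients vs donors); a paired variant is out of scope. The
  CLI reports Benjamini–Hochberg-adjusted p values alongside raw ones when
  it runs more than one pairwise group test.

## The synthetic generator: what it emulates, and what not

`simulate_repertoire()` is the package's stated world for testing:

* **Clonal expansion structure** — abundances follow a power law over
  clone rank, p_i ∝ i^(−α) with default α = 1, reproducing the heavy tail
  of real clonotype frequency plots; lognormal (σ = 1) and uniform models
  are alternatives. Reads are allocated multinomially to the target depth
  (default 50,000 over 200 clones); clones drawn to zero are dropped.
* **Segment usage** — V and J drawn from explicit usage vectors; the
  defaults are a skewed 12-gene TRBV panel and 12-gene TRBJ panel, with
  the usage ranks loosely modelled on human TRB repertoires.
* **CDR3 length spectrum** — a discretised Gaussian over in-frame lengths
  30–60 nt peaked at 45 bp with σ = 6 bp, matching the conventional human
  TRB modal length.
* **Convergence** — a `convergence_rate` fraction of clones is duplicated
  with a synonymous variant. Variants substitute the third base of a
  4-fold degenerate codon (prefixes TC/CT/CC/CG/AC/GT/GC/GG), which
  guarantees the same amino acid without a translation-table lookup at
  mutation time.
* **Non-productive clones** — a `nonproductive_fraction` of clones gets a
  random in-frame stop codon.
* **Longitudinal dynamics** — `simulate_longitudinal()` keeps one clone
  pool (sequences and base weights fixed) and re-draws reads per timepoint
  after multiplying selected clones' weights by per-timepoint fold
  changes, so tracking and overlap analyses can find the programmed
  clones.

What the generator does **not** emulate: V(D)J recombination biology
(CDR3s are unconstrained random codon strings — no junctional structure,
no OLGA/IGoR-style generative model), sequencing error at the read level,
and any V-gene/length correlation. A green test therefore establishes that
the *counting and statistics* are correct on data with the right shape —
not that the package's numbers on real data would match any particular
published value.

## Numerical and reproducibility choices

* Frequencies always renormalise to Σ = 1 within 1e-9 after construction,
  filtering and downsampling; TSV output carries 10 significant digits so
  round-tripped sums hold within 1e-8.
* All orderings are deterministic: clones descending by count with
  lexicographic key tie-break; groups and similarity matrices ordered
  lexicographically; peak-length ties toward the smaller length. This
  keeps golden files stable.
* Every stochastic operation takes an explicit integer seed; nested
  randomness (rarefaction replicates, simulated sample series) uses
  sub-seeds derived from the master seed via a seeded `sample.int`, kept
  below 2³¹. RNG state is saved and restored around each draw
  (`withr::with_seed`), so library calls never perturb user RNG state.
* CLI outputs contain no timestamps; identical config + seed + inputs
  reproduce byte-identical files. The manifest records inputs, per-file
  dialect detection, all effective parameters and the seed.

## Design decisions taken where the design was open

* The design-file schema (mandatory `sample_id` and `file`, all other
  columns grouping variables) is an explicit stated schema rather than a
  sniffed one; groups come from the cross-product of *observed* value
  combinations, empty combinations omitted.
* MiXCR column matching is case-insensitive (capitalisation varies across
  MiXCR versions); AIRR matching is case-sensitive per the standard.
  `bestVHit` is preferred over `allVHitsWithScore`, `duplicate_count` over
  `consensus_count`, each fallback logged.
* The chi-square calibration check in the acceptance suite draws paired
  profiles by deeply downsampling one fixed two-class parent repertoire
  whose class frequencies sit many standard deviations from every bin
  edge. This makes the binned read table multinomial to excellent
  approximation, which is the regime in which the Pearson test's nominal
  level is meaningful; repertoires with clones *near* bin edges violate
  the multinomial variance assumption (whole clones switch bins together)
  and inflate the statistic — a documented limitation of applying the
  test to homeostasis tables, not a defect of the implementation.

## Known limitations

* Exact-match clonotype identity only; no Levenshtein-neighbourhood
  clustering.
* Single-chain (β) analysis; no paired αβ logic, no BCR somatic
  hypermutation handling.
* Chao1 assumes read counts are raw clone sizes; UMI-collapsed tables
  make singleton/doubleton counts less interpretable.
* The Mann–Whitney exact path requires tie-free data; heavily tied
  small-sample data silently uses the approximation (the method label in
  the output says which path ran).
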