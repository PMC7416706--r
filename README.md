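# repkit — hierarchical TCR repertoire analysis

`repkit` is a scriptable analysis engine for T cell receptor (TCR)
repertoire sequencing data. It consumes clonotype tables produced by
upstream extraction tools (MiXCR `exportClones` TSV, AIRR Rearrangement
TSV, or its own canonical TSV) and organises the downstream statistics in
three tiers:

* **single sample** — TRBV/TRBJ segment usage, CDR3 length spectratype,
  ranked clonotype frequency distribution (max frequency, D50), top
  clones;
* **pairwise** — shared / private clonotype frequencies with a log-scale
  coefficient of determination (R²), and convergent-recombination
  analysis (how many distinct CDR3 nucleotide sequences encode each
  shared amino-acid clonotype);
* **multi sample** — clonal space homeostasis (read mass per
  clone-frequency class, rare → hyperexpanded) with Pearson chi-square
  comparison, longitudinal clonotype tracking, similarity matrices
  (Jaccard, overlap coefficient, Morisita–Horn
  2Σp·q/(Σp²+Σq²), Bhattacharyya Σ√(p·q)) with hierarchical
  clustering, diversity indices (Shannon H = −Σpᵢ ln pᵢ, normalized
  Shannon, inverse Simpson 1/Σpᵢ², Gini–Simpson, clonality
  1 − H/ln S, Chao1, D50) with hypergeometric rarefaction, and two-sided
  Mann–Whitney group comparison.

Samples are grouped through a delimited **experiment design file**
(`sample_id`, `file`, plus arbitrary study variables), so the same data
can be regrouped by any combination of variables — per patient, per
timepoint, patients vs donors — without touching the tables. A bundled
synthetic-repertoire generator (power-law/lognormal/uniform clonal
expansion, V/J usage bias, CDR3 length spectrum, programmed convergence
and longitudinal fold changes) makes every statistic testable without
external data.

## Worked example

Simulate a two-timepoint series in which three clones expand 15–40×
(the signature of an antigen-driven CD8⁺ response), then analyse it:

```r
library(repkit)

base <- simulation_params(n_clones = 150, depth = 20000, alpha = 0.6, seed = 42)
script <- longitudinal_script(base, list(
  list(label = "t1", fold = numeric()),
  list(label = "t5", fold = c(`1` = 40, `2` = 25, `3` = 15))))
reps <- simulate_longitudinal(script)

segment_usage(reps$t1, "V")$weights[1:4]
#> TRBV29-1   TRBV27   TRBV13  TRBV5-8
#>   0.1824   0.1368   0.1066   0.1046
spectratype(reps$t1)$peak_length
#> [1] 42                              # modal CDR3 length in bp

fd1 <- clonotype_frequency_distribution(reps$t1)
fd5 <- clonotype_frequency_distribution(reps$t5)
#> t1: max clone freq 0.060, D50 = 34
#> t5: max clone freq 0.508, D50 = 1   # one clone now covers half the reads

diversity(reps$t1, "shannon"); diversity(reps$t5, "shannon")
#> <diversity_result> t1: shannon = 4.7176
#> <diversity_result> t5: shannon = 2.08568
diversity(reps$t5, "clonality")
#> <diversity_result> t5: clonality = 0.58375

overlap_pair(reps$t1, reps$t5)
#> <overlap_result> t1 vs t5 (key nt+vj): 150 shared, 0/0 private;
#>   R^2 = 0.7675 (log10 scale)

clonal_space_homeostasis(reps$t5)$mass_per_bin
#>   rare  small medium  large expanded hyperexpanded
#>  0.000  0.000  0.056  0.128    0.100         0.717

ch <- compare_homeostasis(clonal_space_homeostasis(reps$t1),
                          clonal_space_homeostasis(reps$t5))
#> chi2 = 25217.1, df = 3, p < 1e-300  # timepoints differ strongly

clonotype_tracking(unname(reps), n = 3)
#>                                                        t1     t5
#> TACGGCGTGG...|TRBV29-1|TRBJ2-5                     0.0599 0.5078
#> ACGAGCGACT...|TRBV29-1|TRBJ2-7                     0.0406 0.2095
#> GGAGATACGA...|TRBV5-8|TRBJ1-5                      0.0310 0.0997
```

Reading the numbers: between t1 and t5 the maximum clone frequency rises
from 6% to 51%, Shannon diversity falls from 4.72 to 2.09 nats and
clonality rises to 0.58 — the hyperexpanded bin (> 10% of reads) grows
from 0 to 72% of read mass, and the tracking matrix shows exactly the
three programmed clones driving it.

## Command line

```sh
REPKIT_CLI=$(Rscript -e 'cat(system.file("cli/repkit.R", package = "repkit"))')

Rscript $REPKIT_CLI simulate --out sim --n-samples 5 --seed 7
Rscript $REPKIT_CLI single   --design sim/design.tsv --out single_out
Rscript $REPKIT_CLI pairwise --design sim/design.tsv --pair sim01,sim02 --out pair_out
Rscript $REPKIT_CLI multi    --design sim/design.tsv --group-by replicate \
        --depth 1000 --out multi_out
```

Commands: `convert`, `single`, `pairwise`, `multi`, `simulate`. Common
flags: `--design`, `--out`, `--config` (YAML; flags override it),
`--key-mode nt|aa|nt+vj|aa+vj`, `--seed`, `--group-by VAR[,VAR...]`,
`--functional`/`--no-functional`. Every run writes a `manifest.json`
(inputs, per-file dialect detection, effective parameters, seed); outputs
carry no timestamps, so identical config + seed reproduces byte-identical
files.

## Scope

`repkit` starts from clonotype tables: read assembly, V(D)J alignment and
error correction belong to the upstream extractors, raw FASTQ handling and
GUI/database layers are out of scope, as are paired-chain analysis and
BCR-specific logic. See `vignettes/repkit-methods.Rmd` for the models,
defaults, numerical choices and known limitations.
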