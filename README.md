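# cnvclust

Gene-network cluster enrichment for population-differential copy-number
variants (CNVs) — a pipeline for nominating candidate gene modules behind
health disparities, plus a seeded synthetic-data generator that makes every
stage testable without external downloads.

## The problem

CNVs whose occurrence frequencies differ between populations (here African
Americans, AA, versus Caucasians, CA) are candidate genetic contributors to
health disparities, but a CNV's consequences play out through the
interaction partners of the genes it covers. `cnvclust` finds network
clusters that are *jointly* enriched for disease-associated (pathogenic)
genes and for genes inside population-preferred CNVs:

* the network is partitioned with the Markov Cluster (MCL) algorithm over
  the inflation sweep *I* = 1.1 … 2.0 (step 0.1);
* CNVs are repartitioned by the majority-occurrence rule
  (*f* = count_AA / (count_AA + count_CA); *f* > 0.5 → CNV_AA,
  *f* < 0.5 → CNV_CA, exactly 0.5 excluded) and mapped to genes by
  1-based inclusive coordinate overlap, as are pathogenic SNP positions;
* each cluster (size *m*, in a network of *N* genes, with *q* of the *Q*
  pathogenic genes and *s* of the *S* CNV genes) is scored with
  right-tailed Fisher's exact tests, P(X ≥ q) and P(X ≥ s) under the
  hypergeometric law; p-values become robust FDRs
  (π₀ = min(1, 2·mean p), step-up monotonised); clusters with
  p < 0.10 and FDR < 0.20 in both tests are ranked by
  FDR_path × FDR_cnv;
* clusters from different inflation runs with Jaccard ≥ 0.5 are grouped
  into families, and the family most consistently ranked first per
  population is selected and annotated by hypergeometric term enrichment
  (raw p ≤ 1e-3 reported).

See `vignettes/disparity-pipeline.Rmd` for the full model, parameter and
design discussion.

## Worked example

A fully synthetic run: 400 genes, 8 planted modules, one 12-gene
"disparity module" with 9 of the 40 pathogenic genes and an AA-skewed
duplication over its central gene.

```r
library(cnvclust)
cfg <- pipeline_config(synthetic = TRUE, seed = 1, out_dir = tempfile())
rep <- run_pipeline(cfg)

subset(rep$tables$families, population == "AA")[1:3,
       c("rank", "family_id", "first_place_count", "runs_present",
         "representative_size")]
#>  rank family_id first_place_count runs_present representative_size
#>     1      F003                 4            6                  13
#>     2      F002                 1            1                  36
#>     3      F075                 0           10                   1
```

Family `F003` holds first place in 4 of the inflation runs whose AA ranked
list is non-empty — no other family tops more than one run — and it is
exactly the planted module:

```r
disparity_family(rep)
#> $family_id   "F003"
#> $best_jaccard 1
#> $aa_rank      1
#> $aa_tally     4
#> $is_top_aa    TRUE

head(rep$tables$ranked_AA[, c("run", "rank", "cluster_id", "m", "q", "s",
                              "joint_score")], 3)
#>   run rank cluster_id  m q s  joint_score
#>  I1.4    1       C002 36 9 7 1.354561e-02
#>  I1.5    1       C014 12 9 6 4.985520e-09
#>  I1.6    1       C011 12 9 6 9.698286e-09
```

At coarse inflation (I = 1.4) the winner is a 36-gene blob containing the
module; from I = 1.5 on, MCL isolates the 12-gene module itself (q = 9
pathogenic, s = 6 CNV_AA genes) with a vanishing FDR product. The family's
term enrichment recovers the planted annotation:

```r
subset(rep$tables$term_enrichment, population == "AA" & reported)
#>  term_id            label  k  n  b   B            p
#>   TMOD01 module 1 process 12 13 14 400 3.970871e-20
```

All tables are also written as TSV files under `out_dir`, together with
the generated input bundle, its ground-truth sidecar and a reproducibility
manifest; rerunning the same configuration reproduces the directory byte
for byte.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/cnvclust.R simulate --seed 3 --out bundle/
Rscript inst/scripts/cnvclust.R run-all --synthetic --seed 1 --out run/
```

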