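# famdel

Family-based evaluation of structural deletion call sets.

Short-read structural-variant callers disagree wildly on deletions, and
in a cohort of multiplex families there is usually no external gold
standard to arbitrate. `famdel` implements the two family-based levers
that make evaluation possible anyway:

* **Relatives share true variants at predictable rates.** A full sibling
  of a deletion carrier should itself carry the deletion roughly half the
  time (for a rare variant); samples drawn at random share it only at the
  population call rate. Reproducible false calls — mapping artifacts that
  recur at the same locus — hit samples independently of relatedness.
* **Known spike-ins measure sensitivity directly.** Synthetic events
  inserted into real alignments, recovered under a 50% reciprocal-overlap
  criterion, give per-size-bin, per-zygosity detection probabilities.

## The statistics

**D-score.** For a site called in k out of n ordered full-sibling pairs
(n counts pairs whose first member is called; k those with both called),
with overall call rate f, the score is the log-likelihood ratio

    D = ln [ P(X1 < k) / P(X0 > k) ]
    X1 ~ Binomial(n, f_sib)      (true variant: sibling sharing)
    X0 ~ Binomial(n, f)          (reproducible false call: random sharing)

where f_sib = F(f, β_HET, β_HOM) is the probability that the sibling of a
called carrier is also called. `famdel` evaluates F exactly, by
enumeration over Hardy–Weinberg parental genotypes at the allele
frequency q implied by f, Mendelian transmission to two children, and
genotype-specific detection with probabilities β_HET and β_HOM (the
caller sensitivities for heterozygous and homozygous carriers, estimated
from spike-ins). Positive D means sharing looks familial — the call is
likely real; D near or below zero means sharing looks like a recurrent
artifact.

**Sensitivity.** `sensitivity = detected events / true events`, per size
bin and zygosity, where "detected" requires min(overlap/len(truth),
overlap/len(call)) ≥ 0.5 and one-to-one greedy assignment.

**Kinship calibration.** The KING-robust within-pair estimator
φ = (N_het,het − 2·N_opp,hom) / (N_het(i) + N_het(j)) over full-sib
pairs should sit at 0.25 for a clean call set; heterozygote-inflating
artifacts push it up, under-detection pulls it down.

**QC cascade.** Fixed-order site filters with first-fail attribution:
excess heterozygosity (one-sided Levene–Haldane exact test, p < 5×10⁻⁸),
monomorphic sites, call rate < 90%, alternate allele count < 5, plus an
optional external multi-mapping annotation stage. A 75% rule flags
family segregation: a site segregates when ≥ 75% of the affected,
genotyped members of a family carry it.

All of this is exercised end-to-end by a built-in simulator:
Hardy–Weinberg founders, Mendelian transmission, genotype-specific
detection, random false positives, and locus-reproducible artifacts.

## Worked example

```r
library(famdel)

cfg <- sim_config(n_families = 150, n_sites = 400, q_range = c(0.05, 0.2),
                  fp_locus_fraction = 0.25, fp_locus_call_rate = 0.9)
cohort <- simulate_cohort(cfg, seed = 42)

## 100 of the 400 sites are reproducible artifacts calling 90% of samples
## as heterozygous. Sibling kinship is inflated before QC:
mean(sib_pair_kinship(cohort$observed, cohort$ped)$phi)
#> [1] 0.3651582

## the excess-heterozygosity stage removes exactly the artifact sites,
## and kinship returns to the sibling expectation of 0.25:
qc <- qc_cascade(cohort$observed, cohort$ped)
qc$removed
#>    excess_het  hom_ref_only low_call_rate        low_ac
#>           100             0             0             0
mean(sib_pair_kinship(qc$calls, cohort$ped)$phi)
#> [1] 0.2493173

## the D-score separates the two site classes without any filtering:
scan <- score_callset(cohort$observed, cohort$ped, betas = c(1, 1))
lab <- cohort$labels[scan$table$site_id]
median(scan$table$D[lab == "true_variant"])
#> [1] 23.69835
median(scan$table$D[lab == "reproducible_false"])
#> [1] -3.948384
```

A spike-in sensitivity run looks like:

```r
truth <- generate_spikein_truth(seed = 42)   # 11,200 events, half HET
calls <- degrade_truth_to_calls(truth, beta_het = 0.8, beta_hom = 0.95,
                                seed = 43)
b <- estimate_beta(truth, match_calls(truth, calls), bins = validation_bins())
b[b$bin == "all", c("beta_het", "beta_hom")]
#>   beta_het  beta_hom
#> 7 0.792615 0.9405784
```

The same workflows are scriptable through the installed CLI
(`system.file("cli", "famdel", package = "famdel")`) with subcommands
`simulate`, `sensitivity`, `dscore` and `qc`.

## Documentation

The methods vignette (`vignettes/family-deletion-evaluation.Rmd`) covers
the model assumptions, the simulator's scope, numerical choices and known
limitations, including the behaviour of the score at very rare and very
common sites.
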