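---
title: "Evaluating deletion call sets with family structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating deletion call sets with family structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famdel)
```

## The problem

Short-read deletion callers produce call sets whose error structure is
dominated by two failure modes: missed carriers (limited sensitivity,
strongly size- and zygosity-dependent) and reproducible false calls
(mapping artifacts that recur at the same locus across many samples).
In a cohort of multiplex families neither failure mode can be measured
against an external truth set, but both leave fingerprints in the family
structure. `famdel` turns those fingerprints into statistics.

## The sibling-sharing model behind the D-score

Consider one biallelic deletion site with alternate-allele frequency
$q$, and a caller that detects a heterozygous carrier with probability
$\beta_{HET}$ and a homozygous carrier with probability $\beta_{HOM}$
(non-carriers are never "detected"; spurious calls are handled by the
competing hypothesis, not by this model). For a *true* variant, the
probability that a full sibling of a called sample is itself called is

$$f_{sib} = P(\text{call in sib}_2 \mid \text{call in sib}_1),$$

which `sib_sharing_prob()` evaluates exactly: both parents are drawn
independently from Hardy–Weinberg genotype frequencies at $q$, two
children are generated by Mendelian transmission, and each child is
called with probability $0$, $\beta_{HET}$ or $\beta_{HOM}$ according to
its genotype. The enumeration runs over the nine parental mating types
and the child genotype distributions they induce; no approximation is
involved. Two limits anchor intuition: as $q \to 0$,
$f_{sib} \to \beta_{HET}/2$ (a single heterozygous parent transmits to
the second sibling with probability one half), and at $q = 1$,
$f_{sib} = \beta_{HOM}$.

The allele frequency is not observed directly; it is inferred from the
overall call rate $f$ (the proportion of non-missing samples called) by
inverting

$$f(q) = 2q(1-q)\,\beta_{HET} + q^2\,\beta_{HOM}.$$

This map is not monotone on $[0,1]$ in general — with
$\beta_{HOM} < 2\beta_{HET}$ it peaks at
$q^\ast = \beta_{HET}/(2\beta_{HET}-\beta_{HOM})$ — so
`infer_allele_frequency()` bisects on the rare-variant branch
$[0, q^\ast]$, to $|f(q) - f| \le 10^{-12}$. A call rate above the
attainable ceiling $f(q^\ast)$ is an error from this function; during
call-set scoring such sites (typically artifacts calling most of the
cohort) are instead saturated at $q^\ast$, which gives them the most
favourable $f_{sib}$ the model allows — a deliberately conservative
choice, since even then their observed sharing matches the null.

Observed sharing at a site is summarised by ordered sibling pairs:
over all ordered full-sib pairs $(i, j)$, $n$ counts pairs whose first
member is called and $k$ pairs with both called; pairs with a missing
genotype in either member are dropped. The ordered convention makes the
conditional $P(\text{call} \mid \text{call in sib})$ symmetric in the
two siblings and makes $n$ the natural binomial size. The score is

$$D = \ln\frac{P(X_1 < k)}{P(X_0 > k)}, \qquad
  X_1 \sim \mathrm{Bin}(n, f_{sib}), \quad
  X_0 \sim \mathrm{Bin}(n, f).$$

The numerator asks how unusual it would be for a true variant to show
*less* sharing than observed; the denominator how unusual for a
reproducible false call (which hits samples independently of
relatedness, so siblings share only at the population rate $f$) to show
*more*. High observed sharing drives $D$ up.

```{r dscore-example}
## hand-checkable case: k = 1 of n = 2, f = 0.05, f_sib = 0.5
## P(X1 < 1) = 0.25, P(X0 > 1) = 0.0025, D = ln(100)
d_score(k = 1, n = 2, f = 0.05, f_sib = 0.5, n_called = 2)$D
```

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `betas` (β_HET, β_HOM) | — (required) | caller sensitivities; constant or per size bin from `estimate_beta()` |
| `min_calls` | 2 | sites with fewer called samples are not scored; two calls are the logical minimum for a sharing statement |
| `strict` | `TRUE` | strict tail inequalities $P(X_1<k)/P(X_0>k)$, matching the definition above; `FALSE` uses $P(X_1\le k)/P(X_0\ge k)$ |
| `f_cohort` | `"all"` | call rate over all samples; `"founders"` restricts to pedigree founders |
| `reciprocal_fraction` | 0.5 | overlap required of *both* intervals for a truth/call match |
| `hwe_p_threshold` | 5×10⁻⁸ | one-sided excess-het exact-test cut-off |
| `min_call_rate` | 0.90 | site call-rate filter |
| `min_alt_allele_count` | 5 | minimum alternate allele count |
| `hwe_cohort` | `"founders"` | cohort for the excess-het test; founders avoid pseudo-replication from transmitted genotypes |

## Numerical choices

* **Log base.** Natural log. Nothing in the likelihood-ratio
  construction pins the base; natural log keeps the score additive with
  the rest of the package's log-scale quantities.
* **Strict tails by default.** The definition above uses strict
  inequalities on the count scale. The non-strict variant is exposed as
  a flag because the two differ materially exactly where the score is
  degenerate (see limitations below).
* **Probability flooring.** Both tail probabilities are floored at
  $10^{-300}$ before the log, and floored results carry
  `status = "capped"`. Scores stay finite and sortable for
  prioritisation; $\pm\infty$ would destroy ranking.
* **Tie-breaks in matching.** One-to-one assignment accepts candidate
  pairs in decreasing order of the minimum reciprocal fraction, ties
  broken by smaller truth start then lexicographic ids, so matching is
  reproducible regardless of input order.
* **Size-bin edges.** Bins are integer-inclusive on both printed
  endpoints ("20–40" contains sizes 20..40); size 100 belongs to
  "81–100", not "101–900".
* **Coordinates.** Internally 0-based half-open everywhere; VCF's
  1-based anchored records are converted only at the I/O boundary.
  Deletion extent comes from `len(REF) − len(ALT)` for sequence alleles
  and `END − POS` for symbolic `<DEL>` records; records carrying both,
  disagreeing, are rejected. Multiallelic records are skipped with a
  warning rather than decomposed.
* **Degenerate inputs.** All-missing sites and sites below `min_calls`
  return statuses, not errors; a cohort without sibling pairs yields
  `no_sib_pairs` everywhere; `hwe_excess_het_pvalue()` returns 1 when no
  heterozygote excess is possible; KING-robust kinship is undefined
  (NA, with counts reported) when neither sample has a heterozygous
  site.

## The excess-heterozygosity exact test

Mapping artifacts tend to appear as heterozygous calls in a large
fraction of samples — far more heterozygotes than Hardy–Weinberg
equilibrium permits at the implied allele frequency. Conditional on the
sample size and allele counts, the heterozygote count follows the
Levene–Haldane distribution
$P(n_{het}) \propto 2^{n_{het}}\, n! / (n_{AA}!\, n_{het}!\, n_{aa}!)$,
and the test reports the upper tail only: heterozygote *deficits* (a
signature of consanguinity or population structure, not of artifacts)
are never flagged. The default threshold of $5\times10^{-8}$ removes
only overwhelming excess. The test is computed on founders by default;
including transmitted genotypes would count each founder chromosome
several times.

## The QC cascade

Stages run in a fixed order — excess heterozygosity, no called carriers,
call rate, allele count, then (when an external annotation is supplied)
multi-mapping — and every site is attributed to the *first* stage it
fails. First-fail attribution is what makes per-stage removal counts
well defined and makes the counts plus survivors add up to the input;
the cascade is idempotent by construction. The alternate-allele-count
stage is placed last; its position relative to the other stages is a
convention, and only the attribution, not the surviving set, depends on
it.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates nuclear families (two founders, a
configurable number of full siblings), true genotypes by Hardy–Weinberg
founders and Mendelian transmission, and observed calls through the
error model: carriers detected with probability $\beta_{HET}$ or
$\beta_{HOM}$, random false positives at a per-sample-site rate, and
locus-reproducible artifacts whose calls hit samples i.i.d. at a fixed
rate — the minimal model under which expected sibling sharing at
artifact sites equals the population call rate. Deletion sizes are drawn
log-uniformly over 2–5,000 bp, mimicking the strong skew of real size
spectra toward small events; sites are placed without overlap on a toy
contig, since no implemented statistic depends on real reference
coordinates. `generate_spikein_truth()` mirrors a spike-in design:
4,040 deletions, 4,040 insertions, 1,560 inversions and 1,560 tandem
duplications (11,200 events), half heterozygous, sizes 2–5,000 bp, with
2.92% of events flagged as failed insertions and excluded from
sensitivity denominators.

The simulator does **not** model: linkage between sites (sites are
independent, so it cannot exercise LD-aware methods), sequencing-center
or library effects, genotype-likelihood uncertainty, breakpoint errors
beyond bounded jitter, non-nuclear pedigrees, or ascertainment of
affected families. Passing tests on simulated data therefore demonstrate
the *statistics* behave as designed under their own assumptions — not
that any particular real caller's errors follow this model.

## Known limitations

* **Very rare sites.** With two to five carriers in the whole cohort,
  the binomial tails are degenerate: a site whose only informative
  configuration is one ordered pair with no sharing ($n=1, k=0$) has
  strict numerator $P(X_1 < 0) = 0$, which floors to
  $D \approx \ln(10^{-300}/f)$ — a large negative sentinel — while a
  fully shared sibling pair ($k = n$) floors the denominator and
  produces the mirror-image large positive value. Median D over such
  sites is therefore dominated by capped sentinels rather than sitting
  near zero; the informative statement at this depth is the `capped`
  status itself, not the magnitude. Under the non-strict variant the
  same configurations stay finite (e.g. $D = \ln(1 - f_{sib})$ for
  $n=1,k=0$, about $-0.69$ when $f_{sib}=0.5$) and the score collapses
  toward zero as the folk description suggests. Either way, scores at
  fewer than ~20 carriers should be treated as uninformative for
  prioritisation.
* **Very common sites.** As $f$ approaches the model ceiling the
  inferred $q$ saturates, $f_{sib}$ approaches $f$, and the two
  hypotheses merge — D loses power by construction near 50% call rate.
* **Kinship is sensitivity-dependent.** KING-robust kinship over
  siblings returns 0.25 only when carriers are called symmetrically;
  genotype-specific under-detection biases it downward even on an
  artifact-free call set, which is exactly why it works as an overall
  quality meter rather than a pure specificity meter.
* **β transfer.** Spike-in sensitivities are estimated from synthetic
  events; using them per size bin (supported via `estimate_beta()`
  tables, with pooled fallback) is recommended when bins are well
  populated, pooled otherwise.

## Problem sizes used in the test suite

The packaged checks run at desk scale, chosen to keep every Monte-Carlo
band at least three standard errors wide: kinship calibration on 200
families × 2 siblings × 5,000 sites; sharing-model verification against
4×10⁶-family Monte Carlo per grid point; the excess-het test verified
exhaustively against an independent conditioning oracle for all sample
sizes up to 50; matching verified against an all-pairs brute force on up
to 50 intervals; D-score ranking measured on 600-site cohorts of 200
families.
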