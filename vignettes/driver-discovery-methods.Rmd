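---
title: "Methods: integrative CNV-expression driver discovery and survival validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative CNV-expression driver discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdrive)
```

# The procedure and its assumptions

`cnvdrive` targets tumor cohorts with *complex genomics*: thousands of
copy-number alterations per sample and no recurrent anchoring mutation.
The working hypothesis is that although individual altered genes differ
across tumors, oncogenesis is driven by recurrently altered *pathways*;
driver genes are then the members of universally altered pathways whose
own alteration tracks the clinical subgroup of interest (here, metastatic
evolution). The pipeline makes four assumptions worth stating explicitly:

* **Probe states are trustworthy after filtering.** Copy-number input is
  per-probe, already segmented/called (or as log2 ratios thresholded by
  `threshold_logratio_probes()`). Somatic specificity is approximated by
  excluding probes in constitutional CNV regions, on sex chromosomes,
  outside genes, or altered in *any* normal-DNA control — the strictest
  reading of "altered in controls", chosen because germline/technically
  unstable probes are worse than lost probes.
* **A gene has one status per sample.** Aggregation is a strict plurality
  vote over the gene's probes; *any* tie (lost/gained, lost/normal,
  gained/normal) resolves to `normal`. This is the most conservative
  concrete rule consistent with "one status from all probes"; the
  alternatives (`any_nonnormal`, `consensus`) are exposed via `tie_rule`.
* **Dosage matters only when transcribed.** A copy alteration counts only
  when expression moves concordantly past the control-group quartile
  (under Q1 for losses, over Q3 for gains, strict inequalities — "under"
  and "above" read as strict; `boundary = "inclusive"` flips this). The
  control group for a gene is the set of tumors copy-normal *for that
  gene*; its own non-normal samples can never leak into its quartiles.
* **Pathway involvement is a sample-level OR.** One altered member flags
  the pathway in that sample; losses and gains count alike. No ontology
  propagation is performed — the catalog is flat, and whether annotations
  are propagated is a property of the input file, which is why the
  manifest records catalog provenance.

# Tunable parameters

| parameter | default | unit / range | rationale |
|---|---|---|---|
| `min_controls` | 30 | samples | quartiles of the copy-normal group are unstable below ~30; genes under the floor become `not_evaluable` rather than silently mis-called |
| `gain_cut`, `loss_cut` | ±0.2 | log2 ratio | conventional single-copy bounds for noisy arrays; only used for numeric input |
| `fraction` | 1.0 | of samples | universal = altered in *every* tumor; lower values relax selection monotonically |
| `alpha` | 0.05 | — | two-sided Fisher, direction filter applied separately |
| `use_adjusted` | FALSE | — | selection on raw p mirrors the frequency-based screening style this procedure comes from; BH-adjusted values are always reported alongside |
| `tie_rule` | majority | — | see above |
| `boundary` | strict | — | see above |
| KDE bandwidth | Silverman (`bw.nrd0`) per group | expression units | no estimator is canonical here; Silverman is the R default and is recorded in the manifest |
| KDE grid | 1024 points over pooled range ± 3 pooled bandwidths | — | wide enough that boundary effects cannot create artefactual crossings |

Quantiles everywhere use linear interpolation at position `p·(n−1)`
(`stats::quantile` type 7). Quantile conventions differ across software
ecosystems and *change alteration calls at small n*, so the convention is
fixed, stated here, and written into the run manifest.

# Dichotomization and survival

The expression threshold for a candidate gene is the crossing of the two
Gaussian kernel densities (copy-deleted vs copy-normal tumors), computed
on a shared grid. Overlapping unimodal densities also cross in the tails,
so candidate crossings are restricted to the window between the two group
medians — the biologically meaningful separator lies between the modes —
and, among several, the one nearest the midpoint of the medians wins.
Degenerate cases are explicit: a zero-variance group falls back to the
midpoint of group means, no in-window crossing falls back to the pooled
mean, each with a warning. `low` is strictly below the threshold.

Strata are compared with the Kaplan–Meier estimator and the two-group
log-rank test (`survival::survfit` / `survdiff` under the hood). The
hazard ratio is the non-iterative O/E estimate
\((O_1/E_1)/(O_2/E_2)\) with CI \(\exp(\log HR \pm z\sqrt{1/E_1+1/E_2})\),
deliberately paired with the log-rank test instead of a Cox fit: it needs
no iteration, is defined whenever both groups have expected events, and a
proportional-hazards model is out of scope for this package. Patients
metastatic at diagnosis have no meaningful metastasis-free interval and
are excluded by default (`exclude_metastatic_at_diagnosis = TRUE`, never
silently); unknown chemotherapy status stays `NA` and subsetting on it
errors rather than coercing.

# What the generator emulates — and what it does not

`sim_config()` defaults encode the cohort conditions this pipeline was
built for: 106 tumors of which 32 metastatic, ~12,100 genes with an
expected 2,960 copy-altered genes per sample split 53% gains / 47%
losses, five normal-DNA controls, a deletion driver (default id `RCBTB1`)
lost in 62.5% of metastatic vs 34% of non-metastatic tumors with
concordant expression loss, and censored metastasis-free survival whose
hazard is multiplied (default 2.5) when the driver is lost-and-low.
Expression is `gene baseline (N(8, 1)) + status shift (−1.5 loss / +1.0
gain) + N(0, 0.5)` on the log2 scale — placing the driver's density
intersection in the ~7 range. Probe states inherit the gene state with a
2% flip rate; decoy probes exercise each exclusion rule, with the
constitutional BED emitted alongside.

Survival has two modes, because a single generative chain cannot hold
both the conditional deletion frequencies and the hazard ratio fixed:

* `"retrospective"` (default): metastatic labels first (fixed subgroup
  size), deletion planted conditionally on the label, event times for
  metastatic patients drawn with the driver-low hazard multiplier. This
  is the shape of a retrospective cohort and is what enrichment-recovery
  experiments should use.
* `"generative"`: the hazard model runs forward — `T ~ Exp(h0 ·
  HR^{driver low})`, uniform censoring over the follow-up window,
  metastasis ≔ event — so the planted hazard ratio *is* the data's hazard
  ratio. Hazard-recovery experiments should use this mode.

The planted driver pathway keeps its companion genes at a tenth of the
passenger rate. This is an identifiability choice, not realism: if the
companions were ordinary passengers, the pathway's sample-level OR flag
would saturate and carry no subgroup signal at simulated cohort sizes, and
no pathway-level enrichment could ever support a driver call.

Deliberate non-realism, relevant when reading test results: passenger
alterations are independent Bernoulli events per gene and sample (no
segmental correlation along chromosomes), arrays have no batch or GC
artefacts, expression noise is homoscedastic Gaussian, and censoring is
uninformative uniform. Passing recovery tests therefore demonstrates that
the *logic and arithmetic* of every stage are right under the assumed
statistical structure — not that the pipeline is robust to wave artefacts,
segmentation errors, or informative censoring in real arrays.

# Statistical behavior the user should expect

Two properties of the exact-test core follow from theory and are worth
stating so that simulation results are read correctly; the package's own
test suite computes both.

**Attained size is below nominal.** Fisher's exact test is discrete: at
α = 0.05 and the 2×2 margins typical of a 120-sample cohort, the attained
null rejection rate is ~0.03–0.04, not 0.05. Under permuted labels the
observed fraction of raw p < 0.05 across the candidate pool sits *below*
the nominal level — conservative, never anti-conservative.

**Recovery power is bounded by the exact test.** With a driver
deleted-and-low in 60% of 36 metastatic vs 30% of 84 non-metastatic
samples, the exact power of the two-sided Fisher test at α = 0.05 is
0.85 (0.89 even for a balanced 60/60 split, by full enumeration of the
binomial×binomial table distribution). Concordance noise and the
requirement that a supporting pathway pass as well bring per-simulation
driver recovery to roughly 0.78–0.82 under those conditions. Across
repeated simulations one should therefore expect the planted driver among
the candidates in about four runs of five — a ceiling set by the test's
power at that effect size and sample size, not by the implementation.

# Numerical and design choices

* Coordinates are 0-based half-open internally; declared 1-based input is
  converted on load. One internal convention prevents off-by-one drift.
* Probe→gene mapping is taken from the input files, never recomputed from
  annotation databases: array-era mappings are version-bound, and
  reproducibility requires explicit inputs. A probe annotated to several
  genes counts toward each.
* Multi-probe IQR ties in representative-probe selection resolve to the
  lexicographically smallest probe id (determinism).
* Odds-ratio conventions: the conditional MLE is reported (from
  `fisher.test`), plus the sample OR `ad/bc` with `x/0 → Inf`, `0/0 →
  NaN`.
* Chi-squared association is offered without Yates correction by default
  (flag-exposed); on 2×2 tables of this size the uncorrected statistic is
  the conventional companion to the exact test.
* Gene and pathway universes are reported pre- and post-filtering; genes
  whose control group is too small are excluded from downstream counts
  and reported separately, since the control group is a precondition of
  the alteration definition.
* All randomness in the generator flows through one seed; identical seed
  and configuration reproduce every output file byte for byte, and the
  manifest stores md5 digests of each written table.

The test suite runs its heavier recovery experiments at reduced scale —
2,000 genes / 50 pathways / 120 samples for end-to-end recovery, 600
genes for null calibration, 150–200 samples for hazard recovery, 20 seeds
each — sizes chosen so the statistical questions (direction, calibration,
centering) are answerable while the whole suite stays fast enough to run
on every change.

# Known limitations

* No segmentation: input is per-probe; raw-signal segmentation (e.g. CBS)
  belongs upstream.
* No ontology parsing: the pathway catalog is flat membership; results at
  `fraction = 1` are sensitive to whether the catalog was propagated.
* No multivariable or competing-risks survival modeling; the O/E hazard
  ratio assumes proportional hazards loosely and degrades gracefully (CI
  widens) with few events.
* Selection on raw p (default) reproduces the screening style the
  procedure comes from but inflates the family-wise error; the BH column
  is always present, and `use_adjusted = TRUE` switches selection to it.
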