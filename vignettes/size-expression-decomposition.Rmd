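---
title: "Decomposing cell-size and expression phenotypes in knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing cell-size and expression phenotypes in knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizexpr)
```

## The problem

Genome-wide deletion screens in *E. coli* measure, for thousands of
single-gene knockout strains carrying a dual fluorescent reporter construct
(two genes, here called mVenus and mCherry, expressed from identical
promoter/5'-UTR sequences), per-cell flow-cytometry readouts: forward
scatter (FSC, a proxy for cell size) and the two fluorescence channels.
Because slowly dividing cells dilute their contents less, reporter
concentration is coupled to cell size ("growth feedback"): a knockout can
change reporter output without touching expression at all. The point of the
analysis implemented here is to separate three per-strain phenotype axes:

* **S** — mean cell size (mean FSC of the gated population);
* **E** — size-normalized global expression, affecting both reporters
  equally;
* **G** — gene-specific imbalance between the two reporters, after size
  and global-expression effects are removed.

## The decomposition model

All statistics operate on per-strain population summaries (arithmetic means
of trimmed events; `summarize_strain()`). The decomposition is a sequence
of ordinary least-squares regressions (`decompose_screen()`):

1. Each channel's mean fluorescence is regressed on S
   (intercept + slope). The residuals `mC_reg` and `mV_reg` are the
   fluorescence signals with the size trend removed.
2. `E = (mC_reg + mV_reg) / 2`, the pairwise residual average, is the
   global expression score.
3. `G_signed` is the residual of regressing `mC_reg` on E. Because E is
   the unweighted mean of the two residual vectors, the residual of
   `mV_reg` on E is exactly `-G_signed`: the two channels yield identical
   sets of absolute values, and the package asserts this antisymmetry at
   every call (a violated assertion means E was not the unweighted mean).
   Positive `G_signed` means mCherry above mVenus after normalization.

Degenerate inputs are handled explicitly: a constant S is a degenerate-fit
error; when E has zero variance (e.g. perfectly antisymmetric residuals)
the OLS slope is undefined and `compute_G()` uses the continuous limit,
mean-centering of `mC_reg`.

The regression scale is selectable. `scale = "raw"` regresses the summary
values as reported and is the default. `scale = "log"` log-transforms S and
the channel means first; because cytometry intensities are approximately
lognormal, effects are multiplicative, and raw-scale residuals are strongly
heteroscedastic (a strain at half the baseline fluorescence can never show
a raw residual as large as a strain at twice the baseline). For screens
with effects on both sides of the baseline — including the synthetic
screens below — the log scale treats up- and down-shifted strains
symmetrically, and the recovery analyses in this package's test-suite use
it for that reason.

## Phenotype calling

Two complementary calling schemes are provided:

* **Quantile scheme** (`quantile_bins()`): the top and bottom 5% tails of
  the S and E distributions (rank-based, stable ties by strain id; bin
  sizes are `ceiling(q*n)` and `n - floor((1-q)*n)`). G extremes are
  two-sided, the union of both 5% tails of `G_signed`, since an imbalance
  in either direction is a gene-specific phenotype. On a 3824-strain
  screen the 5% bins hold 192 strains each.
* **Z-score scheme** (`classify_patterns()`): S and E Z-scores (across
  the whole screen, sample-SD convention) are coded `+1`/`-1` beyond
  ±2 SD, `0` inside the closed near-zero window [-0.5, 0.5], and
  *intermediate* otherwise. A strain is classified only when both codes
  are non-intermediate and not both zero; with the binary `|Z_G| > 2`
  flag this defines exactly 16 pattern classes.

Association statistics are resampling-based (`bootstrap_cooccurrence()`,
`class_membership_test()`): the null redraws same-size sets uniformly
without replacement from the strain universe, and empirical p-values use
the add-one correction `(1 + #{null >= obs}) / (B + 1)`, so p is never 0
and resolves to 1e-4 at the default `B = 10000`.

## Functional enrichment

Over-representation (`overrepresentation()`) is the one-sided Fisher exact
test (hypergeometric upper tail) on the 2x2 membership table, with the
conservative EASE variant (overlap decremented by one, floored at zero) as
an option, Bonferroni-corrected over the terms tested in the call.
Differential enrichment between two gene groups
(`differential_enrichment()`) compares log odds ratios:
`z = (logOR_A - logOR_B) / sqrt(SE_A^2 + SE_B^2)` with
`SE = sqrt(sum of reciprocal cell counts)` and the Haldane 0.5 correction
on zero cells. A term is flagged differential when `z > 2`, or `p_A < 0.1`,
or jointly `-log10(p_A) >= 1.3` (p <= 0.05) and `z >= 0.5`; we read the
combined log-p threshold as a floor on `-log10(p)` since it accompanies a
log10-transformed p-value axis, and all four thresholds are parameters.
Annotation tables are flat term-to-gene sets (two-column delimited or GAF
2.x); no ontology-graph propagation is performed.

## The synthetic-screen generator

The raw screens this pipeline targets are rarely redistributable, so
`generate_screen()` draws complete synthetic screens with the statistical
structure the analysis assumes, and every downstream stage is validated
against the generator's ground truth. The model, per strain *i* and cell:

* strain log-size deviation `d_i = dS_i + N(0, sigma_strain)`;
* `FSC = baseline_size * exp(d_i + e_s)`, `e_s ~ N(0, sigma_cell)`;
* `fluor = baseline_fluor * exp(gamma*(d_i + e_s) + dE_i ± dG_i + e_ch)`,
  with `+dG` on mVenus, `-dG` on mCherry, and `e_ch ~ N(0, sigma_cell)`
  independent per channel.

Per-cell noise is lognormal — the simplest family consistent with
positive, right-skewed cytometry intensities; the true distributional
family of per-cell measurements is unknown and this is an explicit
assumption. Growth feedback is encoded solely as the `gamma` coupling
(fluorescence proportional to size^gamma at both the strain and the
single-cell level); there is no explicit growth-rate variable because the
analysis observes only size and fluorescence. Under this coupling the
per-strain mean of a channel is
`baseline_fluor * exp(dE ± dG + gamma*d_i) * exp((1 + gamma^2) * sigma_cell^2 / 2)`,
the lognormal closed form used by the generator's tests.

Defaults (chosen once as the study conditions):

| parameter | default | why |
|---|---|---|
| `n_strains` | 3822 (+2 WT controls) | non-essential-gene deletion library scale |
| `n_events_per_strain` | 2000 | typical per-well cytometry acquisition |
| `baseline_size`, `baseline_fluor` | 100, 1000 | arbitrary instrument units |
| `gamma` | 1 | proportional size-fluorescence coupling |
| `sigma_strain` | 0.2 (log) | few-fold strain-to-strain variation across a library |
| `sigma_cell` | 0.3 (log) | per-cell CVs of ~30%, typical of bacterial cytometry |
| `sigma_replicate` | `sqrt(0.1) * sigma_strain` | replicate variance one order of magnitude below across-strain variance |
| `effect_classes` | 150 DB (+3σ/+3σ), 150 MM (−3σ/−3σ), 90 EPR (−3σ/+3σ, dG +3σ) | three seeded systems at clearly separable effect sizes |

The generator emulates: size-expression coupling, strain effects organized
into systems, lognormal cell noise, day-level replicate noise, a 96-well
row-major plate layout (optionally clustering effect classes onto
contiguous plates), and a concordant annotation term per seeded system
plus random background terms. It does **not** emulate instrument
artifacts — saturation, spectral spillover, doublets, debris, bead
calibration — nor growth curves or time courses. Tests passing on
synthetic screens therefore demonstrate the statistical machinery, not
robustness to instrument-specific distortions of real data.

The RNG is split hierarchically (screen → strain → cell, via deterministic
substream seeds), so the same configuration and seed reproduce a screen
bit-for-bit and adding strains never perturbs earlier strains' draws.

## Quality control

Replicate error (`estimate_replicate_error()`) is a one-way random-effects
decomposition on log-scale summaries (multiplicative error model): the
replicate component is the mean per-strain variance across days and the
across-strain variance comes from the full screen's strain means. Plate
bias (`plate_shift_qc()`) compares each plate's median to medians of
random same-size strain subsets (B resamples, without replacement), with a
two-sided flagging band at α = 0.01 Bonferroni-corrected across plates —
a quantitative stand-in for the usual visual plate-versus-dataset overlay.
Population summaries trim 1% per tail (events gated on FSC; per-channel
trimming for CVs) and require 200 gated events; both are conventional
cytometry defaults, configurable, and strains failing QC are excluded from
the regressions rather than imputed, to avoid leverage artifacts.

## Design choices on open points

* "About 192 genes showed an extreme value" is read as the per-tail bin
  count (5% of 3824 ≈ 192 per bin), not a union count.
* The near-zero window is interpreted in Z units, consistent with the
  Z-score rule it accompanies, and as a closed interval.
* Z-scores use the sample (n−1) SD; extreme-value screens conventionally
  do, and at screen scale the distinction is negligible.
* G-extreme phenotypes are two-sided (union of both `G_signed` tails):
  an imbalance is a phenotype whichever reporter wins.
* The Bonferroni family is the set of terms tested in the current call.

## Validation design and problem sizes

The test-suite validates each stage against independent oracles:
normal-equations OLS for the regressions; explicit combinatorial sums for
the Fisher tail (exhaustively over all tables with universe ≤ 30);
exhaustive subset enumeration for bootstrap p-values on universes ≤ 12;
and closed-form lognormal/hypergeometric expectations elsewhere.
Null calibration of the bootstrap uses 200 repetitions with per-repetition
set sizes drawn from 50–150 out of a 1000-strain universe: varying the
sizes makes the mixture of discrete p-value supports fine-grained enough
for a chi-squared uniformity check, which a single fixed size would fail
for pure discreteness reasons.

End-to-end parameter recovery runs a full-scale default screen (3822
strains × 2000 events) through summaries, log-scale decomposition,
pattern classification and differential enrichment, and requires
sensitivity and precision ≥ 0.8 per seeded system *among classified
strains* — the pattern scheme deliberately leaves borderline strains
unclassified, so recovery is judged on the calls the scheme actually
makes. Unit tests exercise the same properties on scaled-down screens
(200–500 strains, 100–400 events per strain) with effect-class sizes
scaled proportionally and effect sizes unchanged.

## A worked example

```{r example, eval = FALSE}
library(sizexpr)

# seeded classes scaled down with the screen
cfg <- screen_config(n_strains = 400, n_events_per_strain = 300,
                     effect_classes = lapply(default_effect_classes(),
                       function(e) { e$n <- round(e$n * 400 / 3822); e }),
                     seed = 1)
scr <- generate_screen(cfg)

summaries <- summarize_screen(scr$events)
decomp <- decompose_screen(summaries, scale = "log")
phenotypes <- call_phenotypes(decomp)
report <- report_landscape(phenotypes)
print(report)

db_union <- phenotypes$strain_id[phenotypes$classified &
                                   phenotypes$s_code == 1]
enr <- overrepresentation(db_union, scr$annotations, phenotypes$strain_id)
head(enr)
```

## Known limitations

* The lognormal cell model and the purely multiplicative replicate model
  are assumptions; real screens add instrument artifacts the generator
  does not produce.
* Raw-scale regression (the default, for fidelity to how screen summaries
  are usually reported) is sensitive to the heteroscedasticity noted
  above; use `scale = "log"` when effects span both directions.
* Enrichment treats terms as flat sets; no GO-graph ancestor closure.
* The analysis observes only size and fluorescence: mechanisms (growth
  rate, ribosome content, division timing) are outside the model and can
  only be inferred, not estimated.
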