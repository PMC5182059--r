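---
title: "Methods: simulation and estimation in hdxkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and estimation in hdxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hdxkit)
```

This vignette documents the models, default parameters, and numerical
choices behind the package, and what the simulators do and do not attempt to
emulate.

## 1. Exchange model and its assumptions

Deuterium uptake is simulated in the EX2 limit of the Linderstrøm-Lang
model: each exchangeable amide *i* of state *s* exchanges independently with
effective first-order rate `k_int(i) / P(s, i)`, so the expected deuteron
count of a peptide spanning residues `start..end` at time `t` is

    D(t) = sum_i [ 1 − exp(−k_int(i) · t / P(s, i)) ]

summed over the peptide's exchangeable amides. Assumptions baked in:

* **EX2 only.** Protection factors rescale rates; correlated (EX1) opening,
  which produces bimodal isotope envelopes, is not modeled. Consequently a
  single centroid mass per spectrum is a sufficient observation.
* **Exchangeable amides** exclude residue 1 of the protein, prolines (no
  backbone amide hydrogen), and the first residue of each *peptide*
  (`nterm_skip = 1`, the conventional correction for rapid back exchange at
  the newly created N-terminus after pepsin cleavage).
* **Back exchange** is a single per-experiment survival factor
  `1 − b` (default `b = 0.3`, a typical bench value) applied to the deuteron
  count. Because the fully-deuterated control is attenuated identically,
  percent deuteration is invariant to `b`; the test suite checks this
  identity numerically rather than assuming it.
* **Mass observations.** Centroid masses are the theoretical peptide
  monoisotopic mass plus `1.00628 Da` per deuteron, with additive Gaussian
  noise (default `noise_sd = 0.05 Da`, a realistic centroid repeatability).
  m/z values use a proton mass of `1.00728 Da`.

`make_truth()` draws `k_int` log-uniformly on `[0.05, 10] /min` and
protection factors log-uniformly on `[1, 1000]` by default — ranges chosen
so that the default 0.5–300 min time course spans the full dynamic range
from fully exchanged to essentially silent amides. Both are ordinary
arguments; studies in the tests narrow them (e.g. `pf_range = c(1, 2)` for a
uniformly dynamic protein with one planted protected block).

## 2. Peptide pool generation

`make_peptide_pool()` emulates a pepsin digest's *coverage structure*, not
its sequence specificity: lengths are uniform on `length_range = c(4, 20)`
and cleavage positions are random. Real pools from good digests cover nearly
the whole sequence while averaging only a few peptides per residue, so a
naive "add random peptides until the mean redundancy is reached" loop is
wrong — at redundancy 1.7–2.5 it leaves 20–45 % of the sequence uncovered.
The generator therefore works in two passes:

1. **Tiling pass**: cover every accessible segment end to end with abutting
   random-length peptides (a too-short tail is backed up so it still fits).
2. **Fill pass**: add random peptides (segment chosen proportional to
   length, duplicates rejected) until the mean number of peptides per
   *covered* residue reaches `target_redundancy`, with a ±20 % tolerance
   check at the end.

`exclude` ranges emulate regions that never produce recoverable peptides
(e.g. glycosylated or poorly ionizing stretches); they are skipped by both
passes, so fractional coverage below 100 % is a modeling input, not an
artifact. At 354 residues / redundancy 2.5 the pools come out at ~100 %
coverage, mean ≈ 2.5, max ≈ 6 peptides per residue; at 491 residues /
redundancy 1.7 with 13 % excluded, ~87 % coverage and mean ≈ 1.7 — the
regime of typical published pools.

## 3. Percent deuteration and its error budget

`percent_deuteration()` implements `DP = 100 (m_t − m0)/(m100 − m0)` with
per-peptide nondeuterated and fully-deuterated controls;
`build_uptake_table()` averages controls per peptide/state, computes DP per
replicate, and reports mean and sample SD (singletons get `dp_sd = NA`
rather than 0).

A note on accuracy claims: with `noise_sd = 0.05 Da` on all three masses and
3 replicates, a peptide with only 2 exchangeable amides and `b = 0.3` has a
per-record DP standard error of roughly 2 percentage points — the noise
floor scales as `1/(n_exch (1 − b))`. "Recovered within 2 points" is
therefore a statement about the **mean absolute error across records**
(observed ≈ 0.6 points), not a per-record maximum, which is unattainable at
this noise level for the shortest peptides. The acceptance checks assert the
mean.

## 4. Residue projection and classification

`residue_deuteration()` averages each peptide's DP over the earliest
`time_window = 2` time points (early times are most sensitive to protection
differences before uptake saturates), then projects to residues with
length-capped weights `w = min(1/L, 0.2)` — short peptides localize
information and get up to 5× the weight of long ones, while the cap stops a
4-mer from dominating entirely. `classify_difference()` calls a residue
deprotected/protected when the profile difference exceeds ±25 percentage
points, and reports a display scalar `ΔD/25` clipped to `[−1, 1]` for
structure coloring. Peptide-level smoothing means a planted protected block
is recovered widened by a few residues at each edge; the block-recovery
tests assert full recall on residues covered by a peptide lying entirely
inside the block, and zero positives ≥ 10 residues away.

`coverage_statistics()` computes per-residue peptide counts by interval
stabbing; `mean_overlap` averages over covered residues by default
(`denominator = "covered"`), matching how redundancy is conventionally
quoted, with `"all"` available.

## 5. Nucleotide-exchange kinetics

`fit_single_exponential()` fits `F(t) = baseline + ΔFmax (1 − e^{−kt})` by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`), with the rate start
taken from a log-linear regression of `log(plateau − F)` on `t`. Derived
quantities: `v0 = k·ΔFmax` (fluorescence units/min; the instantaneous
velocity is `v(t) = k·ΔFmax·e^{−kt}`, of which `v0` is the `t = 0` value)
and `molar_rate = k · conc0` under the single-turnover assumption that the
full substrate pool `conc0` converts with rate constant `k`.

A fit object distinguishes `converged` (the optimizer succeeded and
`k > 0`) from `reliable` (the trace additionally spans at least two
half-lives of the fitted rate). Below two half-lives `k` and `ΔFmax` are
strongly anti-correlated and the rate is poorly identified, so such fits
carry `reliable = FALSE` with a reason string instead of failing outright.
For the same reason, the recovery studies record traces for
`max(10 min, 3 half-lives)` at 10 s sampling; under that condition the
median rate error at 2 % amplitude noise is ≈ 2–3 %.

`compare_activities()` implements the two-sample *t* test from summary
statistics (pooled variance, `df = n1 + n2 − 2`; Welch optional), since
per-replicate traces are typically not retained — only mean ± SD per
variant. Significance stars follow the convention `* p < 0.01`,
`** p < 0.005`, `*** p < 0.001`.

## 6. DSF melting temperature

The simulator produces a two-state sigmoid in the F350/F330 ratio,
`low + (high − low)/(1 + exp(−(T − tm)/width))`, with baselines
`(0.8, 1.1)`, scan `20–75 °C` at `0.12 °C` steps, and `width = 1.5 °C` —
values representative of intrinsic-fluorescence DSF instruments. Tm is
defined as the argmax of the first derivative of the ratio.

The obvious estimator — fit one polynomial across the whole scan and take
its analytic derivative's argmax — **fails**: a degree-5 polynomial cannot
represent 55 °C of flat baseline plus a sharp sigmoid, and its derivative
peaks at the scan edge (≈ 75 °C for a true Tm of 47 °C, even noise-free).
`melting_temperature()` therefore uses a local fit:

1. coarse peak: smoothed finite differences of the ratio;
2. polynomial (degree 5 by default) fit on centered/scaled temperature
   within ±8 °C of the coarse peak;
3. analytic derivative evaluated on a dense 0.01 °C grid inside the window.

Noise-free this recovers Tm to < 0.02 °C; at 1 % amplitude noise the maximum
error over 200 simulations is < 0.2 °C across Tm 38–47 °C. Transitions at
the scan edge are flagged `reliable = FALSE`; additional derivative peaks
are reported as `secondary_tms`.

## 7. Problem sizes in the tests

The sizes exercised in the test suite and acceptance script — proteins of
120–491 residues, pools of ~50–190 peptides, 8-point time courses with 3
replicates, 200-seed recovery ensembles — are the package's own choices,
picked to be large enough that the statistical claims are meaningful and
small enough that the full suite runs in well under a minute.

## 8. Limitations

* EX2 only; no bimodal envelopes, no per-residue back-exchange variation.
* Intrinsic rates are drawn at random, not computed from sequence context
  (no Bai-style residue-specific `k_int` tables).
* The peptide generator reproduces coverage statistics, not pepsin's actual
  cleavage preferences.
* The kinetics module fits a single exponential; multi-phase exchange must
  be handled upstream.
* Structure coloring writes B-factors and a PyMOL script; it does not
  validate residue numbering against the construct beyond chain and offset.
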