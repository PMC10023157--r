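---
title: "Methods: dipeptide-repeat/condensate association and PRE validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dipeptide-repeat/condensate association and PRE validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatsep)
```

# Scope

`repeatsep` implements two quantitative tracks that meet in the biology of
serine/arginine-rich (SR) splicing factors. The *proteome track* asks whether
uninterrupted dipeptide repeats — RS repeats being the motivating case — are
statistically associated with a protein's presence in liquid-liquid
phase-separated condensates. The *NMR track* implements the paramagnetic
relaxation enhancement (PRE) machinery used to test structural ensembles of
such proteins against spin-label relaxation data. A synthetic-data module
generates inputs for both tracks with known ground truth, so the full
pipeline runs and is testable without any external download.

# The repeat model

A *dipeptide repeat* of the unordered pair {A, B} is a maximal substring
that strictly alternates between A and B (for A ≠ B) or repeats a single
residue (for the 20 homo-pairs such as GG or QQ, which behave as
mono-residue runs). Three conventions matter and are fixed package-wide:

* **Either phase counts.** An RS run may begin and end with either residue;
  counting starts at the first residue of the run whichever of the two it
  is. `"SRSRSRSR"` is one run of length 8, not two interleaved runs.
* **Minimum length 2; non-canonical codes terminate runs.** Codes outside
  the 20 canonical letters (X, U, B, Z) are retained in sequences but break
  alternation, as do sequence ends.
* **Coordinates are 0-based, half-open.** A reported run occupies
  `[start, start + length)`.

Because every adjacent pair of canonical residues belongs to exactly one
unordered motif, a single pass over a sequence's adjacency classification
recovers the maximal runs of all 210 motifs at once; `scan_proteins()`
exploits this to scan whole proteomes in one vectorized pass, and
`scan_all_motifs()` provides an independent per-sequence implementation.
The two paths are cross-checked against each other and against a regex
oracle in the test suite.

## k-mer unit counting

Two defensible ways exist to count "4-mer RS repeats" in a protein, and
published counts rarely say which was used. The package's default is the
**tiling** convention: each maximal run of length L contributes
`floor(L / 4)` non-overlapping units, so runs of 16, 5 and 6 residues give
4 + 1 + 1 = 6 units. The alternative **runs** convention counts maximal
runs of length ≥ 4 (here: 3). Tiling is the default because it is the
convention that reproduces very large unit counts for long low-complexity
domains of SR-related nuclear-speckle proteins (dozens of 4-mer units in a
single protein); the `convention` argument switches to run counting
throughout. The bundled `synthetic_srrm2_like.fasta` stand-in plants a run
architecture whose tiling count is 56 while its run count is 36, so the two
conventions are discriminated by a single number.

## Composition windows

Low-complexity regions are alternatively defined by windowed composition.
`composition_windows()` slides a 20-residue window (default) and keeps the
single maximum-composition window per protein (earliest window on ties),
reporting it only if it reaches the threshold — 0.40 R/S fraction by
default. The single-hit rule means one protein contributes at most one hit
regardless of how many windows qualify. The 40% figure is used as the
analysis threshold; a lower percentage appearing in search-tool
configurations is treated as a search floor, not an analysis criterion.

# The association statistics

## Categories, fractions and population-based error

For a motif, each protein is placed by the length x of its *longest* run
(the number of runs is deliberately ignored at this step) into x = 0
(no run anywhere) or cumulatively into x ≥ 2, x ≥ 4, x ≥ 6, x ≥ 8: a
protein with a 16-mer run sits in all four cumulative categories. Within a
category the condensate fraction is

  f_ps = N_ps / (N_ps + N_np)

with N_ps and N_np the counts of category members found / not found in the
condensate databases. Because some motifs populate the long-repeat
categories with only a handful of proteins, a population-based error

  E_ps = 1 / sqrt(N_ps)

accompanies each fraction. The square-root form is the default on
counting-statistics grounds (the relative Poisson error of the condensate
count); the linear form 1/N_ps is selectable via `eps_form = "linear"`
since typography of the source material leaves the intended form ambiguous.
E_ps is undefined when N_ps = 0, which marks the category ineligible for
the error criterion below.

## Correlation screen

`correlation_screen()` computes the Pearson correlation r of the five
category abscissae x = {0, 2, 4, 6, 8} against f_ps and a two-tailed
p-value from the t transform `t = r sqrt(n-2) / sqrt(1-r^2)` with n − 2
degrees of freedom. The abscissa choice x = {0, 2, 4, 6, 8} with n = 5 is
what makes a printed correlation of r = 0.93 correspond to a two-tailed
p of 0.02, which the acceptance suite verifies. A motif is flagged
significant when all three hold:

1. r > 0 (positive association),
2. p < 0.05 (two-tailed),
3. the error criterion `E_ps(x ≥ 8) < 2 f_ps(x ≥ 8)` with the x ≥ 8
   category populated.

Fewer than three categories with defined fractions, or zero variance in
f_ps, leaves p undefined and the motif non-significant.

## Contingency, rank tests and multiple testing

Fisher's exact test (`fisher_exact()`, two-sided by the probability-mass
rule) assesses 2×2 associations such as repeat presence × RRM occurrence,
stratified by condensate status. Mann-Whitney (`mann_whitney()`, midranks,
tie-corrected normal approximation, no continuity correction by default)
compares repeat-unit-count distributions between condensate and
non-condensate proteins; the tie-corrected variance equals the exact
permutation variance of U, which is how the test suite validates it by
enumeration at small n. Where two such comparisons address one question,
the Bonferroni-adjusted threshold `bonferroni(0.05, 2) = 0.025` applies.

## Size-matched resampling

Category sizes are wildly unequal (the x = 0 class dominates). To check
that the screen is not an artifact of unequal sample sizes,
`size_matched_resample()` repeats the analysis on replicates (default 50)
in which every category is downsampled without replacement to the size of
the smallest category, and reports the per-replicate screens plus the
fraction significant. All resampling requires an explicit seed; there is no
hidden global randomness anywhere in the package, and seeded generators
save and restore the caller's RNG state.

# The PRE model

## Forward model

For a nucleus at distance r from an unpaired electron, the transverse PRE
is

  Γ2 = (1/r⁶) (μ0/4π)² (1/15) γI² g² μB² S(S+1) (4τc + 3τc / (1 + (ωH τc)²))

with γI the proton gyromagnetic ratio, g the electron g-factor, μB the Bohr
magneton, S the electron spin (1/2 for a nitroxide such as MTSL,
overridable), ωH the proton Larmor angular frequency (from the spectrometer
frequency, e.g. 850 MHz), and τc the PRE correlation time, optionally
decomposed as 1/τc = 1/τr + 1/τs. **τc has no default**: it is a property
of the system that the user must supply (synthetic fixtures use 4 ns, a
plausible value for a small labelled domain). Constants are SI internally;
distances cross the interface in Å and Γ2 in s⁻¹.

For flexible proteins a single structure is inadequate, so back-calculation
averages over an ensemble of N members: `⟨r⁻⁶⟩_h = (1/N) Σ_i r_i⁻⁶` per
residue h, with r_i measured from the paramagnetic center (the nitroxide
oxygen) to the amide proton in member i. `read_pre_ensemble()` pulls both
from multi-model PDB files via bio3d.

## Agreement metrics

Observed and back-calculated profiles are compared by the Q-factor

  Q = sqrt( Σ_h (Γ2_obs − Γ2_calc)² / Σ_h Γ2_obs² )

and the Pearson correlation R over the n residues with defined values.
Q = 0 is perfect agreement; a uniformly scaled profile calc = c·obs gives
Q = |1 − c| exactly, which anchors the unit tests.

## Data reduction and classification

Observed Γ2 comes from two-time-point intensity ratios:

  Γ2 = ln( I_dia(t2) I_para(t1) / (I_dia(t1) I_para(t2)) ) / (t2 − t1)

with first-order error propagation from the per-spectrum noise standard
deviation (a user input, not estimated internally). A weighted multi-point
fit of ln(I_para/I_dia) against time is available via `method = "lsq"`.
Residues are classified before fitting, with the boundary conventions
exactly as stated in the underlying protocol:

* **bleached** — paramagnetic/diamagnetic ratio at the first time point
  (≈12 ms after the first 90° pulse) **≤ 0.5** (inclusive): relaxation too
  fast to fit, indicating close approach to the label;
* **noisy** — diamagnetic intensity at the second time point **< 5×** the
  spectrum noise sd (strict);
* **excluded** — both at once;
* only `"ok"` residues enter fits and Q/R sums.

`bleach_distance()` inverts the forward model to the distance at which the
first-point ratio hits a threshold; at τc = 4 ns, 850 MHz and 12 ms this is
12.3 Å, consistent with the conventional expectation that bleached residues
lie within roughly 12–15 Å of the label.

# The synthetic-data generators

`synth_proteome()` emulates a labelled proteome: sequences drawn from a
background composition (uniform by default), one planted uninterrupted
motif run per protein with length drawn from
{0, 2, 4, 6, 8, 10, 16} (defaults 0.50/0.15/0.12/0.09/0.07/0.04/0.03 —
about half the proteome repeat-free, with a long-repeat tail thick enough
to populate the x ≥ 8 category at n = 2000), flanks redrawn from the
non-motif alphabet so planted runs cannot extend by chance, planted phase
(R-first or S-first) randomized, and labels drawn from
`plogis(-1.5 + 0.25·run_length + 1.0·has_RRM)` with RRM prevalence 0.1.
These coefficients give a baseline condensate prevalence of ~18% rising to
>90% for 16-mer carriers — a strong, monotone planted signal. What the
generator deliberately does *not* mimic: real proteome composition biases,
domain architecture, multiple runs per protein, or database curation biases.
Passing tests therefore demonstrate that the statistics recover a planted
monotone enrichment and stay calibrated under the null — not that any
particular real proteome value is correct.

`synth_ensemble()` draws center-proton distances uniformly over 8–20 Å —
the informative window of a nitroxide label, inside which close residues
bleach and beyond which Γ2 is barely measurable — realizes them as
coordinates, and *quantizes the coordinates to the 0.001 Å PDB precision
before computing the ground truth*, so a written file re-read from disk
reproduces the truth to floating-point accuracy. `synth_decay()` inverts
the two-point estimator (`I_dia = I0 e^{−R2,dia t}`,
`I_para = I_dia e^{−Γ2 t}`, additive Gaussian noise). Default acquisition
uses time points 12 and 36 ms: the first matches the protocol's initial
observation delay, and the 24 ms spacing puts Γ2·Δt near 1 over the
mid-window Γ2 range, the usual design point for a two-point rate
measurement. R2,dia defaults to 10 s⁻¹ and noise to 1% of I0. Under these
conditions the end-to-end Q between fitted and forward profiles comes out
near 0.08 (predicted ~0.08–0.09 from first-order propagation; the
acceptance suite requires ≤ 0.1).

# Numerical and design choices

* **Problem sizes.** Calibration runs use the generator defaults
  (2000 proteins) over 20 seeds for both the null and planted fixtures;
  oracle suites use 1000 random sequences for the scanner, 300 tables for
  Fisher, 60 sample pairs for Mann-Whitney, 100 sequences for composition;
  PRE recovery uses 200 decay realizations and a 120-residue ensemble.
* **Null calibration.** The screen's significance rule is one-sided in
  effect (r > 0 plus a two-tailed p), so its null rate is expected well
  below the nominal 5%; the acceptance bound is 7.5% over ≥ 4200
  motif-screens and the observed rate is far under it, mostly because
  random-composition proteomes rarely populate the x ≥ 8 category for
  arbitrary motifs (an undefined screen is counted as a screen without a
  false positive).
* **Ties and degeneracies.** Composition-window ties resolve to the
  earliest window. All-tie Mann-Whitney samples return p = 1. Fisher on
  degenerate margins returns p = 1. Zero-variance correlation inputs
  return NA and non-significance. An all-zero observed PRE vector is an
  error rather than a zero Q.
* **Stand-in sequences.** `inst/extdata/synthetic_srsf1_like.fasta` and
  `synthetic_srrm2_like.fasta` are *synthetic* sequences constructed to
  carry the documented repeat architectures of the corresponding human
  proteins (maximal RS runs of 16, 6, 5; and 56 tiled 4-mer RS units,
  respectively); they are generated stand-ins for testing the scanner at
  protein scale, not database sequences.
* **Reproducibility.** Report bundles contain the resolved configuration
  and package version but no timestamps; identical configuration and seed
  give byte-identical outputs, which the acceptance suite checks by hash.

# Known limitations

* Repeats of period > 2 (e.g. tripeptide units) and interrupted/fuzzy
  repeat models are out of scope by design.
* Only Bonferroni adjustment is provided; no FDR procedures, and no
  regression modelling of condensate probability.
* The PRE track back-calculates and validates; it performs no restrained
  docking, MD, or peak picking. Published ensemble-agreement figures for
  specific proteins (Q ≈ 0.45–0.55, R ≈ 0.92–0.94 for SR-protein/peptide
  ensembles) additionally require the observed-PRE tables and structure
  ensembles of those studies, so they serve as context for the metrics'
  expected ranges rather than as recomputable targets here.
* Condensate membership is whatever the supplied database exports say it
  is; the package neither queries databases nor models their curation
  biases.

# A worked miniature

```{r example}
truth <- synth_proteome(proteome_sim_spec(n_proteins = 600), seed = 404)
scans <- scan_proteins(truth[, c("accession", "sequence")])
assoc <- motif_association_screen(
  scans, data.frame(accession = truth$accession,
                    in_condensate = truth$in_condensate))
subset(assoc, significant, select = c(motif, pearson_r, p_two_tailed))
```

The planted RS enrichment is recovered as a significant positive
correlation between repeat-length category and condensate fraction.
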