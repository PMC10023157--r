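# repeatsep

Quantifying the association between uninterrupted dipeptide repeats and
membership in biomolecular condensates, and validating structural ensembles
against paramagnetic relaxation enhancement (PRE) measurements.

## The problem

Serine/arginine-rich (SR) splicing factors and SR-related proteins carry
low-complexity regions built from alternating arginine/serine (RS) repeats.
These regions drive liquid-liquid phase separation — SR proteins populate
nuclear speckles — and they also make the proteins notoriously insoluble.
Two quantitative questions arise for anyone working on these systems:

1. **Proteome scale** — is the length, number, or windowed composition of a
   dipeptide repeat statistically associated with a protein being found in
   phase-separated condensates (as curated by phase-separation databases),
   and does the association survive controls for RRM domain content,
   unequal category sizes, and multiple testing?
2. **Residue scale** — given a structural ensemble of a spin-labelled
   protein or protein–peptide complex, do back-calculated PRE rates agree
   with the measured ones?

`repeatsep` implements both tracks as composable R functions with a thin
command-line layer, plus a synthetic-data module that generates labelled
proteomes and PRE observables with known ground truth, so the entire
pipeline runs and is tested with no network access.

## The statistics and the model

**Repeat scanning.** A repeat of the unordered pair {A, B} is a maximal
substring strictly alternating between the two residues (a maximal
single-residue run for homo-pairs such as GG). Runs may start with either
residue, are at least 2 residues long, and are terminated by non-canonical
codes and sequence ends. All 210 unordered motifs are scanned in one pass.

**Category screen.** Per motif, proteins fall in categories by longest run
x ∈ {0, ≥2, ≥4, ≥6, ≥8}. Each category gets a condensate fraction and a
population-based error

    f_ps = N_ps / (N_ps + N_np),    E_ps = 1 / sqrt(N_ps)

and the screen computes Pearson's r of x = {0, 2, 4, 6, 8} against f_ps
with the two-tailed p from t = r·sqrt(n−2)/sqrt(1−r²), df = n−2. A motif is
flagged significant when r > 0, p < 0.05, and E_ps(x≥8) < 2·f_ps(x≥8).
Fisher's exact tests (two-sided, probability-mass rule), Mann-Whitney rank
tests (midranks, tie-corrected normal approximation), Bonferroni adjustment
(0.05/2 = 0.025), size-matched resampling, and 20-residue composition
windows (threshold 40% R/S) complete the association toolkit.

**PRE forward model.** For a nucleus at distance r (Å) from the nitroxide
oxygen of an MTSL label,

    Γ₂ = (1/r⁶) (μ₀/4π)² (1/15) γ_I² g² μ_B² S(S+1)
         (4τ_c + 3τ_c / (1 + (ω_H τ_c)²))

ensemble-averaged per residue as ⟨r⁻⁶⟩ = (1/N) Σᵢ rᵢ⁻⁶ over N members read
from a multi-model PDB. Observed Γ₂ comes from two-time-point intensity
ratios with first-order error propagation; residues are classified
*bleached* (para/dia ratio ≤ 0.5 at the first ~12 ms time point), *noisy*
(dia intensity < 5× spectrum noise sd at the second point), or *excluded*
(both). Agreement is summarized by the Q-factor
sqrt(Σ(Γ₂ᵒᵇˢ−Γ₂ᶜᵃˡᶜ)²/Σ(Γ₂ᵒᵇˢ)²) and Pearson's R.

## Worked example

Generate a 600-protein synthetic proteome in which condensate probability
rises with planted RS run length, scan it, and screen every motif:

```r
library(repeatsep)

truth <- synth_proteome(proteome_sim_spec(n_proteins = 600), seed = 404)
scans <- scan_proteins(truth[, c("accession", "sequence")])
L     <- longest_runs_for_motif(scans, truth$accession, "RS")
categorize(L, truth$in_condensate)
#>   x cumulative N_ps N_np  f_ps   E_ps
#> 1 0      FALSE   23   60 0.277 0.2085
#> 2 2       TRUE  170  347 0.329 0.0767
#> 3 4       TRUE   99  109 0.476 0.1005
#> 4 6       TRUE   79   62 0.560 0.1125
#> 5 8       TRUE   48   26 0.649 0.1443
```

The condensate fraction climbs from 28% of repeat-free proteins to 65% of
proteins with an 8-mer-or-longer RS run. The correlation screen quantifies
that trend and, across all 210 motifs, only the planted one survives the
significance criteria:

```r
assoc <- motif_association_screen(
  scans, data.frame(accession = truth$accession,
                    in_condensate = truth$in_condensate))
subset(assoc, significant, select = c(motif, pearson_r, p_two_tailed))
#>     motif pearson_r p_two_tailed
#> 191    RS     0.992     0.000882
```

On the PRE side, the forward model at 850 MHz with τ_c = 4 ns gives

```r
cst <- pre_constants(field_mhz = 850, tau_c = 4e-9)
gamma2_from_distance(15, cst)   # 17.36 s^-1 at 15 A
bleach_distance(cst)            # 12.28 A: bleaching radius at 12 ms
```

so a residue whose paramagnetic peak is already halved at the first
observation point sits within ~12 Å of the label. End-to-end:
`synth_ensemble()` → `ensemble_gamma2()` → `synth_decay_table()` →
`fit_decay_table()` → `pre_validate()` returns Q ≈ 0.08 at 1% intensity
noise.

## Command line

A thin dispatcher over the same functions (installed at
`inst/cli/repeatsep`):

```sh
repeatsep ingest --fasta proteome.fasta --annotations ann.tsv \
  --condensates db1.txt,db2.txt,db3.txt --out table.tsv
repeatsep scan --table table.tsv --motifs all --out scans.tsv
repeatsep associate --fasta proteome.fasta --annotations ann.tsv \
  --condensates db1.txt,db2.txt,db3.txt --resample 50 --seed 17 --out assoc/
repeatsep pre --ensemble ens.pdb --decays decays.csv --tau-c 4e-9 --out pre/
```

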