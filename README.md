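# myofilquant

Quantitative analysis of cardiac myofilament protein modification and
function, built around two measurements:

1. **Label-free mass-balance phosphorylation stoichiometry.** Site-specific
   phosphorylation of troponin I (TnI, serines 23/24) and α-tropomyosin
   (α-Tm, serine 283) is quantified from extracted-ion-chromatogram (XIC)
   peak areas of tryptic peptides, measured in paired sample runs before and
   after complete dephosphorylation with alkaline phosphatase. For each
   reference peptide *r*, the fraction of molecules phosphorylated is

   ```
   f_r = 1 − (A_untreated / R_r,untreated) / (A_treated / R_r,treated)
   ```

   where *A* is the peak area of the *non*-phosphorylated analog peptide and
   *R_r* the area of reference peptide *r* in the same run (five references
   per protein normalize out protein loading). The same machinery yields the
   relative abundance of the mono- (S24) and bis-phosphorylated (S23+S24)
   TnI peptides versus control, and a C-terminal truncation ratio from the
   summed TnI C-terminal peptide forms.

2. **In vitro motility analysis.** Per-filament sliding velocities, percent
   moving and the motility index (velocity × fraction moving) are computed
   from filament centroid tracks, and velocity–pCa curves are fitted with
   the Hill relation

   ```
   V(pCa) = Vmax / (1 + 10^( n · (pCa − pCa50) ))
   ```

   giving the calcium sensitivity pCa50 and cooperativity coefficient *n*.

Both analyses are driven by synthetic-data generators with known ground
truth — simulated Gaussian-peak XIC chromatograms of the study's peptides
(paired untreated/phosphatase-treated, with loading variability and
multiplicative area noise) and simulated 10 frames/s filament-tracking
videos — so every pipeline stage is verifiable end to end without any
external data. The generators' defaults encode the study conditions:
control / IR2 (ischemia + 2 h reperfusion) / IDNR (ischemia, failed
resuscitation) groups, 3 replicates each, area CV 0.10.

## Worked example

Peptide mass arithmetic — the doubly protonated bis-phosphorylated TnI
peptide:

```r
library(myofilquant)
mz_printed(peptide("RRSSANYR", start_residue = 21,
                   mods = "phospho@3;phospho@4"), charge = 2)
#> [1] 585.23
```

Simulate the full paired LC-MS design at the default ground truth and
quantify it:

```r
runs <- simulate_lcms(ground_truth(), n_replicates = 3, seed = 42)
quantify_runs(runs)
#> # A tibble: 15 × 8
#>    group   quantity         target estimate     sd     sem n_values p_vs_control
#>  1 IDNR    fraction_phosph… TnI S…    0.396 0.0772 0.0199        15     5.62e- 2
#>  2 IR2     fraction_phosph… TnI S…    0.477 0.0957 0.0247        15     1.12e- 3
#>  3 control fraction_phosph… TnI S…    0.308 0.153  0.0396        15    NA
#> 10 IDNR    relative_abunda… TnI b…    3.25  0.736  0.190         15     2.45e-12
#> 11 IR2     relative_abunda… TnI b…    4.58  0.572  0.148         15     3.42e-20
#> ...
```

Each row is one group × quantity: the mass-balance phosphorylation fraction
(TnI S23/S24 and Tm S283), the mono-/bis-phosphopeptide abundance relative
to control, and the C-terminal truncation ratio, with SD/SEM over the
5 references × 3 replicates and a pooled Student's *t* against control.
At this noise level the single-simulation estimates scatter around the
generating truth (bis 2.8× for IDNR, 4.2× for IR2).

Simulate and analyze a velocity–pCa motility study:

```r
tracks <- simulate_motility_study(seed = 42)
an <- analyze_motility(tracks)
an$hill
#> # A tibble: 3 × 9
#>   condition  vmax vmax_se pca50 pca50_se     n   n_se     rss converged
#> 1 IDNR       3.86  0.0285  6.61  0.00527 2.77  0.0834 0.00624 TRUE
#> 2 IR2        3.19  0.206   6.53  0.0861  0.826 0.111  0.0573  TRUE
#> 3 control    3.07  0.139   6.43  0.0421  1.35  0.204  0.0428  TRUE

autoplot(an$fits[["IDNR"]])   # velocity-pCa curve with the fitted Hill relation
```

The recovered ordering mirrors the generating parameters: IDNR filaments
slide ~25% faster at full activation and are more calcium sensitive
(higher pCa50) than control. `run_study(default_config(), seed = 1,
out_dir = "out")` executes both branches and writes TSV + JSON report
tables with full seed/config provenance; re-running with the same seed
reproduces them byte for byte.

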