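# agecourse

Longitudinal transcriptome trajectories and tipping-point analysis of cardiac
aging.

`agecourse` is an R package for studies that treat age as a **continuous
covariate** in a bulk transcriptome cohort (e.g. left-ventricle samples from
adult nonhuman primates spanning 7.5–22.1 years) and ask not just *which*
genes change with age but *when* their trajectories change direction. It
implements the full analysis chain:

1. **Preprocessing** — low-count filtering (row sum < 30 removed) and TMM
   (trimmed mean of M-values) normalization, with log2 expression values.
2. **Co-expression modules** — a weighted correlation network: unsigned
   soft-thresholded adjacency `a_ij = |cor(x_i, x_j)|^β` (β = 12), the
   topological overlap matrix

   ```
   TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)
   ```

   average-linkage clustering of `1 − TOM`, eigengene extraction (first
   principal component per module), merging of similar modules
   (eigengene dissimilarity < 0.25), and screening of modules against age
   (Pearson `|r| ≥ 0.30` and `p ≤ 0.05`).
3. **Directional pathway enrichment** — per-gene directions from the module–age
   correlation sign (post-vertex slope sign for quadratic fits), two-tailed
   Fisher exact tests against a transcript universe, Benjamini–Hochberg
   correction, and the activation z-score `z = Σ_i x_i / √N` over member
   directions `x_i = ±1`; plus exact binomial tests for category skew.
4. **Trajectory model selection** — per-transcript OLS fits of
   `y = B0 + B1·x` and `y = B0 + B1·x + B2·x²`, compared by the extra
   sum-of-squares F test (α = 0.05); for quadratic winners the **vertex**
   (tipping point) `−B1 / (2·B2)` is extracted and aggregated per pathway as
   mean ± SD.
5. **Sigmoid onset estimation** — a 4-parameter logistic
   `f(x) = b + L / (1 + e^{−k(x − x0)})` fitted to staining fractions (e.g.
   Alcian-blue glycosaminoglycan area fraction) with onset/end ages from the
   tangent at the inflection point: `a_on = x0 − 2/k`, `a_end = x0 + 2/k`,
   and a fast-accumulation window where the tangent still overlaps the curve.
6. **Timeline assembly** — all events (pathway tipping points, staining
   windows, morphometric vertices) ordered by age, with human-equivalent ages
   (factor 4).
7. **Synthetic cohorts** — a generator that plants modules with flat, linear
   or quadratic latent trajectories (known vertices), negative-binomial count
   noise, pathway sets with controlled direction composition, and logistic
   staining curves, so every stage is testable against known ground truth.

## Worked example

```r
library(agecourse)
res <- run_pipeline(seed = 3, fit_scope = "assigned")
print(res$modules)
#> Module set: 4 modules over 240 transcripts ( 80 unassigned )
#>  module   pearson_r      p_value significant n_transcripts
#>      M1 -0.65876308 1.688756e-05        TRUE            40
#>      M2  0.37522883 2.634233e-02        TRUE            40
#>      M3  0.66289032 1.431424e-05        TRUE            40
#>      M4 -0.08775223 6.161854e-01       FALSE            40
print(res$onset)
#> Logistic fit: b = 0.01744, L = 0.1068, x0 = 16.454 yr, k = 0.368 /yr (rss 0.000129)
#>   accumulation 11.0-21.9 yr, fast phase 13.7-19.2 yr
head(res$timeline)
#>                     label age_start  age_end        sd          source human_start human_end
#> 1        GAG accumulation  11.01855 21.88994        NA staining_window          44        88
#> 2      metabolism_decline  12.79640       NA 0.1929887 pathway_tipping          51        NA
#> 3 gag_precursor_synthesis  13.52979       NA 0.2090468 pathway_tipping          54        NA
#> 4   GAG fast accumulation  13.68716 19.22134        NA staining_window          55        77
#> 5     cardiac_hypertrophy  14.83100       NA 0.2189225 pathway_tipping          59        NA
```

The simulated cohort plants a metabolic module tipping downward at 12.5
years, a glycosaminoglycan-precursor module tipping upward at 13.65 years, a
hypertrophy module at 14.8 years, and a logistic staining curve with midpoint
16.3 years and rate 0.4/yr. The run recovers the four modules (three pass the
eigengene–age screen in this replicate), estimates each pathway's tipping age
within a few tenths of a year of the planted value, brackets staining
accumulation at 11.0–21.9 years with a fast phase at 13.7–19.2 years, and
orders the events: metabolic decline precedes glycosaminoglycan precursor
upregulation and fast staining accumulation, which precede the
hypertrophy-pathway tipping point — with human-equivalent ages (51, 54–55, 59
years) alongside.

The same stages are scriptable through the installed command line:

```sh
CLI=$(Rscript -e 'cat(file.path(find.package("agecourse"), "exec", "agecourse"))')
Rscript $CLI run-all --out demo --seed 3
Rscript $CLI simulate --out demo/sim --seed 3        # or stage by stage:
Rscript $CLI preprocess --counts demo/sim/counts.tsv --out demo/pp
```

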