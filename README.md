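# rfqus

Quantitative ultrasound RF spectral features of thyroid nodules and their
statistical association with cervical lymph node metastasis (CLNM) in
papillary thyroid carcinoma (PTC).

PTC spreads to cervical lymph nodes in ~40% of nodules, yet the nodes are
poorly visible on ultrasound. The raw radio-frequency (RF) echo signal of the
primary nodule — the pre-envelope-detection voltage per scan line — retains
spectral content that B-mode images discard and that reflects tissue
microstructure. `rfqus` implements the full pipeline that links that signal
to nodal status, for researchers who want to reproduce, stress-test or extend
this class of analysis without access to clinical RF recordings:

1. **Phantom simulation** — pulse-echo RF frames from a 1-D scatterer field
   (Poisson scatterers, Gaussian reflectivity, Gaussian-modulated 10 MHz
   receive pulse, depth attenuation, white noise), plus a two-group cohort
   simulator parameterized by the published study summaries.
2. **Feature extraction** — the eight RF quantitative parameters of an ROI.
   With $\hat X_{ROI}[k] = \bar X_{ROI}[k]/\max \bar X_{ROI}$ the
   max-normalized mean magnitude spectrum on $f_k = k/N \in (0, 0.5]$:
   the OLS **slope**, **intercept** and **mid-band** (fitted value at the
   band midpoint) of $\hat X_{ROI}$ vs $f_k$; the sub-band means
   **S1–S4** over the four quarters of the axis; and the **Higuchi fractal
   dimension** $D$ of the raw lines, from $-$slope of
   $\ln L(k)$ vs $\ln k$, $L(k)$ the Higuchi curve length.
   The clinical reading protocol is included: typical frame ± 1 averaged,
   then two readers averaged.
3. **Association cascade** — pooled t / Pearson chi-square screening
   (no continuity correction), ROC with tie-corrected AUC
   $\big(\#\{x_+ > x_-\} + \tfrac12\#\{x_+ = x_-\}\big)/(n_+ n_-)$ at fixed
   orientation and Hanley–McNeil CIs for the $p<0.05$ survivors, and one
   standardized-coefficient OLS regression
   ($\beta_j = B_j s_{x_j}/s_y$) on the $\mathrm{AUC}>0.50$ survivors.

## Worked example

The analysis workflow is four scripts under `analysis/`, run from the
repository root:

```sh
Rscript analysis/01_simulate_rf.R      # phantom case -> results/case_demo/
Rscript analysis/02_extract_features.R # eight parameters per section
Rscript analysis/03_simulate_cohort.R  # 74 + 108 nodule cohort
Rscript analysis/04_association_cascade.R
```

Step 2 prints the feature rows for the demo case (a nodule twice as dense as
its background, imaged at 50 MHz, 312 lines, 20 frames/section):

```
 nodule_id      section higuchi  slope intercept mid_band     s1    s2    s3     s4
      demo   transverse    1.98 -0.553     0.394    0.256 0.0840 0.746 0.162 0.0289
      demo longitudinal    1.98 -0.552     0.391    0.253 0.0846 0.738 0.160 0.0283
```

The slope is negative (backscattered power falls with frequency across the
band) and S2 dominates because the 10 MHz receive band sits at 0.2
cycles/sample, in the second quarter of the normalized axis. Step 4 screens
25 cohort variables and prints the cascade result; for the default seed:

```
Screened 25 variables; 13 passed p < 0.05; 6 passed AUC > 0.50
            variable   auc ci_low ci_high  p_value
     max_diameter_mm 0.637  0.554   0.720 1.24e-03
          long_slope 0.619  0.535   0.703 5.47e-03
 echogenic_foci_code 0.617  0.533   0.701 6.43e-03
 ...
Binormal AUC from published longitudinal-slope summaries: 0.611
```

Tumor maximum diameter, longitudinal spectral slope and echogenic foci — the
three variables whose published AUCs exceed 0.5 — reach stage 3, with AUCs
close to the published 0.68 / 0.61 / 0.62; variables whose risk direction
points the other way show AUCs below 0.5 and are excluded by the fixed-
orientation gate, as in the source tables. Run-to-run membership of the
borderline variables varies with the seed; the methods vignette
(`vignettes/rf-qus-methods.Rmd`) quantifies why.

In code, the same pipeline is three calls:

```r
library(rfqus)
cohort <- simulate_cohort(reference_cohort_params(), seed = 1)
report <- run_association_cascade(cohort)
report$roc
```

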