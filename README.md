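# dsbquant

Quantification toolkit for CRISPR double-strand-break (DSB) repair
assays. When a Cas9 cut is repaired, the cell either restores the locus
(wild type), copies a donor template (homology-directed repair, HDR —
here a precise +8 bp insertion or an mClover knock-in), or ligates the
ends imprecisely (non-homologous end joining, NHEJ). Measuring the
balance between these outcomes — and the cellular context that shapes it
(cell-cycle phase, γH2AX damage foci, micronuclei, migration, viability)
— requires several quantification pipelines that are usually buried in
point-and-click tools. dsbquant provides them as tested, scriptable R
functions for anyone analysing editing experiments or benchmarking such
pipelines:

- **IDAA fragment analysis** — peak detection with a 100-RFU floor and
  rolling baseline, Local Southern size calling
  (`size = c/(m − m₀) + L₀` on bracketing ladder triplets, averaged),
  a ±25 bp retention window, and outcome fractions from peak areas:
  `frac_wt + frac_hdr + frac_nhej = 1`, total editing `= 1 − frac_wt`.
- **High-content imaging** — Li-threshold nucleus segmentation with
  watershed splitting, EdU/DAPI cell-cycle gating (S by EdU Otsu split;
  G1/G2M at the midpoint of the 2N/4N DAPI modes), γH2AX focus counting
  by top-hat enhancement plus three-class Otsu (middle class =
  background), a strict-95th-percentile damage call against a control,
  per-nucleus Pearson colocalization, micronucleus scoring, and
  scratch-wound closure with a frozen 0-h entropy threshold and a
  monotonic (shrink-only) wound mask.
- **Flow cytometry** — reproducible intact/singlet/live gating chains,
  transfection efficiency against a negative control, and the HDR
  readout: `hdr_percent = 100 · n_mClover+ / n_iRFP670+`.
- **Statistics** — mean ± SD summaries, two-tailed pooled t-test,
  one-way ANOVA with Tukey HSD, significance stars, and
  competitive-growth fitness `= KO_d10 / KO_d0`.
- **Synthetic data** — seeded generators for every input modality
  (traces, multi-channel fields, event tables, wound series, competition
  pairs) with ground truth attached, so every stage is validated by
  parameter recovery.

Everything is tibble-in/tibble-out and pipe-friendly; fitted results
have `tidy()`/`glance()` methods and plot helpers
(`plot_chromatogram()`, `plot_gate()`, `autoplot()` on wound series).

## Worked example

Simulate an edited amplicon pool (50% wild type, 30% HDR at +8 bp, 20%
NHEJ at −4 bp), quantify it end to end, and read off the outcome
fractions:

```r
library(dsbquant)

sim <- simulate_trace(mix = data.frame(offset = c(0, 8, -4),
                                       fraction = c(0.5, 0.3, 0.2)),
                      noise_sd = 5, seed = 1)
res <- idaa_pipeline(sim, wt_size = 300)
glance(res)
#> # A tibble: 1 × 6
#>   frac_wt frac_hdr frac_nhej total_editing hdr_nhej_ratio ratio_defined
#>     <dbl>    <dbl>     <dbl>         <dbl>          <dbl> <lgl>
#> 1   0.500    0.303     0.197         0.500           1.53 TRUE

tidy(res)[, c("size", "offset", "class", "area")]
#> # A tibble: 3 × 4
#>    size   offset class   area
#>   <dbl>    <dbl> <fct>  <dbl>
#> 1  296. -4.01    NHEJ   4249.
#> 2  300. -0.00342 WT    10748.
#> 3  308.  8.00    HDR    6517.
```

The detector found three peaks, sized them from the ladder (296, 300 and
308 bp), classified the +8 bp product as HDR, and recovered the mix
fractions from the peak areas to within half a percent.

The flow readout works the same way — generate 50,000 labelled events
with 25% HDR among transfected cells, gate, and read the HDR
percentage:

```r
f <- simulate_flow_events(50000,
                          fractions = c(debris = 0.1, doublet = 0.05,
                                        dead = 0.05, transfected = 0.4,
                                        hdr = 0.25), seed = 1)
hdr_percent(gate_chain(f$events))
#> # A tibble: 1 × 4
#>   n_transfected n_hdr hdr_percent defined
#>           <int> <int>       <dbl> <lgl>
#> 1         16111  4006        24.9 TRUE
```

See `vignettes/dsbquant-methods.Rmd` for the models, parameter
conventions and numerical choices behind each stage.

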