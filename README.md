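# gestaltmask

Perceptual (gestalt) contour extraction for grayscale images: a candidate
edge set from a Canny front-end is *screened* by a deformable, rotatable
rectangular sampling mask driven by an EM loop, so that only edge pixels a
human observer would group into object boundaries survive.  The package is
aimed at image-analysis work where raw edge maps are too cluttered to use —
segmentation preprocessing, shape extraction from noisy micrographs or
natural scenes — and at methodologists who need the accompanying
distance-tolerant evaluation metrics.

## The method in brief

For a target candidate pixel, a rectangular mask of constant area
`L·W = Bn` samples the thresholded orientation (level-line) field around it
and builds an orientation histogram with `Bn` bins.  Writing `H` for the
histogram's Shannon entropy, `Hmax = ln Bn`, `h_T` for the target pixel's
bin height and `h_max` for the modal height, the gestalt likelihood is

    p = (h_T / h_max) · (Hmax − H) / Hmax

— the normalized entropy deficit ("directivity") of the local orientation
distribution, weighted by the belief that the target itself participates in
the principal direction.  A complement likelihood `p̄ = (h̄_min / h̄_T) ·
H̄ / Hmax` is computed from the weak-gradient field.  The EM loop updates
the mask width to `W = ⌊r(1−p)⌋` (or the ceiling when `p` dropped; `r =
√Bn`), re-lengthens `L = Bn/W`, and rotates the long axis onto the modal
bin — the current principal-direction estimate — until `W` stabilizes.  A
Bayes rule with the normalized log-magnitude `g^N` as prior,

    P(Ω | x,y) = p·g^N / (p·g^N + p̄·(1 − g^N)) ,

accepts the target when the posterior reaches `k` (default 0.5), and
accepted targets co-label the aligned pixels of their converged footprint
(continuity shortcut).  The loop provably descends a Lyapunov objective
`[W − r(1−p)]²`, and the converged mask geometry per accepted pixel is
exported for downstream contour linking.

## Worked example

A 96×96 synthetic scene: a square object (contrast 0.85) over a grass-like
texture strip, corrupted by 10% salt-and-pepper noise, median-prefiltered —
the package's noise-screening study condition:

```r
library(gestaltmask)

sc <- shape_scene(
  shapes = list(
    list(kind = "rect",    r0 = 25, c0 = 33, r1 = 72, c1 = 80, intensity = 0.95),
    list(kind = "texture", r0 = 4,  c0 = 4,  r1 = 93, c1 = 28, base = 0.05, amp = 0.5)),
  size = 96, background = 0.1, shading = 0,
  noise = list(kind = "impulse", param = 0.1), seed = 1)

fit <- gestalt_contours(sc$image, prefilter_kind = "median")
summary(fit)
#> Gestalt contour extraction (96 x 96)
#>   tau = 0.6805, k = 0.5, H_t = 0.2, mask 7x7 (area)
#>   candidates 612: accepted 325, co-labeled 193, rejected 94
#>   screening rate 15.4%; mean Lyapunov residual 0.2891
#>   posterior over processed pixels:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.0000  0.5262  1.0000  0.7642  1.0000  1.0000
```

Of 612 Canny candidates, 94 (15.4%) are rejected as non-gestalt — texture
and noise responses — while the square's perimeter is kept (most of it
co-labeled without even running the EM loop).  Against the exact ground
truth at tolerance `d0 = 1`:

```r
eval_report(fit$gestalt_map, sc$gt_contours, d0 = 1, n_cep = fit$stats$n_cep)
#> Edge-map evaluation (d0 = 1): TP 188, FP 330, FN 0
#>   EQ 0.363 | MQ 0.363 | MQ_f1 0.533 | FoM 0.317 | sR 15.4%

eval_report(cep_to_map(fit$cep), sc$gt_contours, d0 = 1)   # raw Canny set
#> Edge-map evaluation (d0 = 1): TP 188, FP 424, FN 0
#>   EQ 0.307 | MQ 0.307 | MQ_f1 0.470 | FoM 0.269
```

Screening lifts every quality metric over the raw candidate set (F1-form
map quality 0.47 → 0.53) without losing a single true contour pixel.
`plot(fit)` displays the contour map; `write_contours()` exports the map,
the posterior image and the converged-mask store.  A command-line wrapper
lives at `inst/cli/extract-contours.R`.

Lower-level entry points mirror the processing stages: `gradient_field()`
and `feature_maps()` (features), `canny_cep()` / `external_cep()` /
`union_cep()` (candidates), `run_em()` (the mask loop for one target, with
full per-iteration trace), `posterior_gestalt()` / `co_label()`
(classification), `pratt_fom()` / `eq_mq()` / `screening_rate()` /
`pr_sweep()` (evaluation), and `shape_scene()` / `line_field()` /
`fig6_fixture()` / `add_noise()` (synthetic data).  The methods vignette
(`vignettes/gestalt-contours.Rmd`) documents the model, the parameter
defaults and the design decisions.

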