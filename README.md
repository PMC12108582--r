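# tunnelmorph

Quantitative analysis of graft **bone tunnels** in HR-pQCT knee images after
anterior cruciate ligament reconstruction (ACLR). The drilled femoral and
tibial tunnels widen and slowly refill with trabecular bone; tunnelmorph
measures that process. It is aimed at orthopaedic imaging researchers who
have per-slice CT stacks (and, optionally, expert tunnel annotations) and
want reproducible per-tunnel morphometry and cohort reports from R.

The pipeline has two stages:

1. **Per-slice segmentation.** An encoder-decoder convolutional network
   (ResNet50 encoder, U-net-style decoder with skip connections, batch norm
   after every convolution) maps each slice to a tunnel mask. Training
   minimises the dice coefficient loss
   `L = 1 − (2|P∩T| + ε) / (|P| + |T| + ε)` with Adam (lr 1e-4, β₁ = 0.9,
   β₂ = 0.999, weight decay 1e-10, batch 12, 100 epochs, decaying schedule).
   A 600×600×3 input reaches a 19×19×2048 bottleneck (five stride-2 steps,
   `⌈600/32⌉ = 19`) and is decoded back to a 600×600×2 score map. The whole
   network, including its reverse-mode autodiff, is implemented natively in
   R; a shape-identical reduced-width variant trains in seconds on a CPU.
2. **3D morphometry.** Stacked masks form the tunnel ROI; inside it the
   package computes BV/TV (bone voxel fraction under an Otsu or fixed
   threshold), Tb.Th and Tb.Sp (volume-weighted means of
   Hildebrand–Rüegsegger local thickness maps of the bone and void phases,
   via an exact 3D Euclidean distance transform and maximal-sphere painting
   in compiled code), Tb.N (1/(Tb.Th+Tb.Sp) by default), tunnel volume
   (`voxels × spacing³`) and mean grayscale value (mGV).

Because clinical tunnel datasets are private, the package ships a
**parametric plate-lattice phantom** with a carved, partially refilled
cylindrical tunnel and closed-form expected indices (BV/TV = t/p, Tb.Th = t,
Tb.Sp = p−t, Tb.N = 1/p); every stage of the pipeline is validated against
it and against brute-force oracles. Segmentation scoring (precision, recall,
IoU, pixel accuracy, dice) and multi-annotator agreement tables round out
the toolbox, plus cohort-level summary reports; a 48-tunnel worked-example
cohort (24 patients × femur/tibia) is included.

## Worked example

Summarise the shipped cohort:

```r
library(tunnelmorph)
library(dplyr)

tab <- load_cohort_table(system.file("extdata", "table4_cohort.csv",
                                     package = "tunnelmorph"))
summarize_cohort(tab) |> filter(metric %in% c("bvtv", "volume"))
#>   compartment metric     n    mean      sd     min     max
#> 1 femur       bvtv      24   0.134  0.0282  0.0623   0.199
#> 2 overall     bvtv      48   0.128  0.0395  0.026    0.274
#> 3 tibia       bvtv      24   0.122  0.0475  0.026    0.274
#> 4 femur       volume    24 257.    80.9    53.3    389.
#> 5 overall     volume    48 226.    76.9    53.3    389.
#> 6 tibia       volume    24 195.    58.1    81.5    290.
```

Femoral tunnels in this cohort average BV/TV 0.134 ± 0.028 and 257 ± 81 mm³,
tibial tunnels 0.122 ± 0.048 and 195 ± 58 mm³ — low bone fractions relative
to healthy metaphyseal bone, as expected for partially refilled tunnels.
`render_report()` writes the same numbers, rounded at reporting precision,
to CSV or JSON, and `autoplot()` draws the mean ± SD/range panel.

Measure a synthetic tunnel end to end:

```r
spec <- phantom_spec(shape = c(40, 40, 40), spacing = 0.1,
                     plate_thickness_t = 0.3, plate_period_p = 1.0,
                     noise_sd = 0, seed = 1)
ph  <- carve_tunnel(make_lattice_phantom(spec), radius = 1.0,
                    refill_fraction = 0.3)
morphometry_report(ph$grid, ph$tunnel_truth)
#>    bvtv tb_th tb_sp  tb_n volume   mgv
#> 1   0.3 0.101 0.132  4.30   12.6    82
```

The carved cylinder (r = 1 mm, L = 4 mm) measures 12.6 mm³ (analytic:
π·1²·4 ≈ 12.57); 30 % seeded refill yields BV/TV 0.300 exactly, the
scattered single-voxel refill reads ~1 voxel (0.1 mm) thick, and the mGV of
82 is the expected mixture 0.7·40 + 0.3·180.

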