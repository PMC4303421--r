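# stackops

Operator-based image and signal stack processing in R, with a
rotation-invariant Local Binary Pattern (LBP) texture operator and a
deterministic pipeline that recovers cell-proliferation phases from
phase-contrast time-lapse microscopy.

## Who this is for

Researchers who need scriptable, reproducible batch processing of
heterogeneous microscopy images ("stacks" whose items may differ in size
and sample model), together with the 1-D signal tools required to turn
per-frame statistics into biological quantities.  The package grew out of
three needs:

1. **An operator framework** — every algorithm is an *operator* with a
   descriptor (unique name, source arity, typed parameters with valid
   ranges), a validator, and an algorithm body.  Operators are registered
   once and then driven uniformly: validated, executed on single items, on
   stacks (serial FIFO or parallel with order restored), previewed, or
   run against disk-cached ("virtual") items that are materialized on
   demand.
2. **Texture description** — dense LBP codes with circular bilinear
   sampling, rotation invariance, cell-wise descriptor histograms.
3. **Time-lapse confluence analysis** — recovering when suspended cells
   adhere, when proliferation fills the field, and when the last
   unoccupied spot closes into a monolayer.

## The statistics at the core

**Local Binary Patterns.** For a center pixel with intensity `I_c` and `P`
neighbours sampled on a circle of radius `R` (bilinear interpolation at
off-grid positions),

    LBP_{P,R} = sum_{p=0}^{P-1} s_p 2^p ,   s_p = 1 if I_c >= I_p else 0 .

On an 8-neighbourhood the code ranges over 0–255.  The rotation-invariant
code is the minimum over all circular bit rotations,

    LBP^ri_{P,R} = min { ror(LBP_{P,R}, i) | i = 0..P-1 } ,

which collapses the 256 8-bit codes into 36 classes.  Per-cell histograms
of the codes, concatenated over a `C x C` partition of the image, form the
texture descriptor.  (The sign convention above gives the tie to the
center; the common inverted convention is available via a flag.)

**Phase detection.**  Frames are histogram-normalized, consecutive
absolute difference images `J_j = |I_{j+1} - I_j|` are formed, and the
histogram statistics energy `sum p_i^2`, entropy `-sum p_i log2 p_i`,
skewness and (non-excess) kurtosis of each `J_j` are tracked as signals.
Activity declines while cells adhere and grows while they proliferate, so
each statistic rises to a maximum at the phase I/II boundary and falls to
a minimum at the phase II/III boundary (entropy mirrored).  After median
filtering, the first prominent maximum and the first prominent minimum
after it are located per signal and combined as mean ± standard error.
The monolayer frame is found by region-growing the unoccupied spot in
every original frame and taking the first index at which the area signal
reaches and keeps its minimum.

## Worked example

```r
library(stackops)

# A synthetic 120-frame proliferation video (8-bit, 128 x 96, 5 min/frame)
# with known phase boundaries at frames 20 / 60 / 100 and one corrupted
# frame; the generator returns the ground truth alongside the frames.
tl <- generate_timelapse(n_frames = 120, width = 128, height = 96,
                         truth = timelapse_truth(20, 60, 100,
                                                 artifact_frames = 30L),
                         noise_sigma = 4, seed = 7)

report <- analyze_timelapse(tl$frames, phase_config(spot_seed = tl$spot_seed))
report
#> Time-lapse proliferation analysis
#>   artifact frames excluded : 30
#>   phase I/II boundary      : frame 18.3 +/- 0.3 (t1 = 92 +/- 2 min)
#>   phase II/III boundary    : frame 58.0 +/- 0.0
#>   phase II length          : t2 = 198 +/- 2 min
#>   monolayer frame          : 100 (t123 = 500 min)
#>   adhesion to monolayer    : t23 = 408 min
```

The corrupted frame is flagged and excluded; the adhesion boundary is
recovered within ~2 frames of the ground truth (frame 20 → `t1` ≈ 100
min), the confluence boundary within 2 frames of frame 60, and the
monolayer frame exactly (frame 100, i.e. `t123` = 500 min; `t23 = t123 -
t1` is the time from adhesion to full monolayer).

The texture operator runs through the same framework:

```r
img <- generate_image("random", 64, 64, 8, seed = 7)
res <- lbp_transform(img, lbp_params(P = 8, R = 1), rotation_invariance = TRUE)
res
#> <lbp_result P=8 R=1 C=1 (ri); descriptor length 256>
length(unique(as.vector(res$codes)))
#> [1] 36
```

A command-line interface wraps the same functions
(`exec/stackops`): `run <operator>`, `lbp`, `phases`, `generate`, `info`.
For example:

```sh
stackops generate timelapse --frames 120 --boundaries 20,60,100 --seed 7 --out frames/
stackops phases --input frames/ --interval 5 --seed-point 48,64 --out report.json
```

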