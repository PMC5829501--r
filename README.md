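# pcmhalo

Quantification of pericentriolar material (PCM) disassembly from fluorescence
time-lapse movies of early *C. elegans* embryos.

During mitotic exit the micron-scale PCM that surrounds each centriole is
rapidly dismantled. Live imaging of a GFP-labelled scaffold protein captures
this as two bright, diffraction-blurred foci (the anterior and posterior
centrosomes of the one-cell embryo) whose integrated fluorescence rises to an
anaphase peak and then decays within minutes. `pcmhalo` implements the
annulus-background quantification used to measure that process, the kinetics
layer that turns per-frame masses into disassembly rates and persistent-mass
fractions, a two-channel ratiometric immunofluorescence analysis, and a
ground-truthed synthetic movie generator that makes the whole pipeline
testable without raw microscopy data.

## The method

For each movie (a T×Z×Y×X stack, e.g. z-stacks acquired every 10 s):

1. **Ingest** — z-stacks are collapsed into SUM projections, the movie is
   split at a user-supplied boundary to isolate the anterior and posterior
   centrosomes, and only frames at/after the annotated nuclear envelope
   breakdown (NEBD) frame are kept, with times re-expressed as seconds
   post-NEBD.
2. **Quantify** — on the first frame a Gaussian blur (σ = 1 px) is applied
   and the maximum-intensity pixel taken as the centrosome centre. A
   band-shaped region between an inner circle (radius 7 px, encompassing the
   PCM signal) and an outer circle (radius 10 px) yields the local background
   mean and standard deviation, and the segmentation threshold

   `threshold = mean_bg + 3 · stdev_bg`

   is fixed there and applied to every frame. Per frame, the ROI is the
   seed-connected component of suprathreshold pixels, and the PCM mass proxy
   is the integrated signal intensity

   `mass = (mean_ROI − threshold) · area_ROI = Σ_ROI (pixel − threshold)`.

   When the two centrosomes cannot be resolved (merged mode), the band-shaped
   region is created with bigger radii and every mass is divided by two.
3. **Kinetics** — each curve is normalized by its own maximum, aligned by
   NEBD or by disassembly onset (the smoothed-curve peak), and summarised by
   a linear peak-to-half-maximum disassembly rate, percent rate reductions
   between conditions, and the trailing-window persistent-mass fraction.
4. **Ratio** — for two-channel immunofluorescence, the ROI is segmented on
   the total-scaffold channel and both channels are integrated over the same
   pixel set (each with its own annulus threshold); ratios are normalized to
   the interphase mean and stages compared with Welch's unpaired t-test.

The simulator renders Gaussian foci whose total above-background counts
follow a programmed kinetic profile (logistic growth, anaphase peak ~275 s
post-NEBD, exponential decay to a residual plateau), with four
genetic-condition presets, cortex-directed centrosome drift, and a standard
Poisson + read-noise + offset camera model. Every render carries a
ground-truth table, so conservation, invariance and parameter-recovery
properties are all checkable.

## Worked example

```r
library(pcmhalo)

sim    <- render_movie(condition_preset("wild_type"), seed = 7)
proj   <- crop_post_nebd(sum_project(sim))
halves <- split_hemispheres(proj)
fq     <- quantify_movie(halves$anterior)
fq[26:29, c("frame", "time_s", "seed_y", "seed_x", "area_roi", "integrated_mass")]
#>   frame time_s seed_y seed_x area_roi integrated_mass
#> 1    26    250     51     58      117          85173.
#> 2    27    260     50     58      122          88946.
#> 3    28    270     50     58      120          92856.
#> 4    29    280     50     58      118          86221.

curve <- as_mass_curve(fq, "anterior", "wild_type")
detect_onset(curve)$t_onset_s          # 270  (s post-NEBD; anaphase peak)
disassembly_rate(curve)
#> <rate_estimate> linear fit: -0.01197 per s over [270, 320] s (n = 6, R2 = 0.992)
persistence_fraction(curve)            # 0    (wild type disassembles fully)

ph <- quantify_movie(split_hemispheres(crop_post_nebd(sum_project(
        render_movie(condition_preset("phosphatase_depleted"), seed = 7))))$anterior)
rate_reduction(disassembly_rate(curve), disassembly_rate(as_mass_curve(ph)))
#> 57.1
```

The quantified masses track the simulator's ground truth (92,856 counts·px at
the 270 s peak vs a programmed peak of 1e5, measured through a noisy camera
and an adaptive threshold); the phosphatase-depletion preset, whose decay
constant is 0.46× wild type, is recovered as a ~57% rate reduction in this
single embryo pair.

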