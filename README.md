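# confinemetrics

Quantification of organelle polarity and pericellular collagenolysis in
confined tumor-cell migration.

## What this package is for

Cancer cells invading dense 3D collagen are mechanically limited by their
nucleus. One adaptive response is *digest-on-demand* proteolysis: the
storage endosomes carrying the collagenase MT1-MMP, together with the
centrosome, polarize **in front of the nucleus** relative to the direction
of movement, and collagen degradation focalizes there to widen the pores
the nucleus must pass. `confinemetrics` provides, for researchers
quantifying this kind of experiment from multi-channel time-lapse
fluorescence microscopy:

- nucleus segmentation, nearest-neighbour tracking and per-frame
  kinematics (speed, direction, persistence);
- Laplacian-of-Gaussian + marker-controlled-watershed endosome detection;
- conversion of endosome positions into a per-frame **nucleus-velocity
  polar frame** (0° = direction of movement, endosomes at the rear = 180°),
  15° rose histograms, and the front-quadrant fraction;
- **Rao's spacing test** of circular uniformity with a Monte-Carlo null:
  sorted circular gaps `T_i`, `λ = 360/n`, `U = ½ Σ|T_i − λ|`,
  `P = (1 + #{U* ≥ U}) / (B + 1)`;
- degradation-spot counting and the **degradation index** (spots per
  cell, control mean normalized to 100);
- normalized back/center/front **line-scan profiles** of cleaved-collagen
  signal;
- nuclear-shape morphometrics (circularity, solidity, lobe count,
  normal/deformed classification), centrosome–nucleus distance and
  ahead-of-nucleus scoring, Tks5 invadopodia area (with the < 8 px
  exclusion), transwell invasion index (signal beyond 30 µm), and laser
  ablation displacement;
- a ground-truthed **synthetic microscopy generator** emulating all of
  the above, used by the test suite to validate every stage end to end.

## Worked example

Simulate a confined control movie (nucleus performing a persistent random
walk; endosome angles drawn from a von Mises distribution calibrated so
that half fall within 45° of the movement direction), then run the full
pipeline — segment, track, detect, assign, pool — and test uniformity:

```r
library(confinemetrics)

p <- scene_params(seed = 7)          # confined control regime
movie <- render_movie(generate_scene(p))
movie$stack
#> ImageStack [30 x 2 x 384 x 384] (T,C,Y,X)
#>   pixel size: 0.2 um/px; frame interval: 5 min
#>   channels: nucleus, endosomes

res <- quantify_endosome_polarity(movie$stack)
res$distribution
#> Angular distribution: 522 endosomes from 1 cells
#>   front-quadrant fraction (|angle| < 45 deg): 0.487

rao_spacing_test(res$distribution$angles, mc_replicates = 9999, seed = 7)
#> Rao's spacing test: U = 164.425 deg (lambda = 0.690), n = 522
#>   Monte-Carlo P = 0.0001 (9999 replicates)
```

The recovered front-quadrant fraction (0.487) matches the generator's
calibrated 0.50 within sampling error, and the spacing test rejects
uniformity at the smallest P-value its 9,999-replicate null can resolve —
the polarized-control readout. `plot_rose(res$distribution)` draws the
rose histogram.

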