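# vdiemg

Channel augmentation and separability analysis for multichannel
surface-EMG (sEMG) gesture recognition.

Myoelectric prosthetic hands and gesture interfaces classify short
windows of forearm sEMG into intended hand movements. Recognition
accuracy rises with the number of electrode channels, but every extra
electrode costs hardware, space and donning effort. `vdiemg`
implements a data-level alternative — **virtual-dimension increase
(VDI)** — that manufactures extra channels from the ones already
recorded, together with a statistic — **SFV, the separability of
feature vectors** — that predicts recognition quality from the feature
set alone, before any classifier is trained. It is aimed at
researchers in myoelectric control who want to study channel-reduction
trade-offs, and it ships a gesture-conditioned synthetic sEMG
generator so every experiment in the package runs without human
recordings.

## The method

A raw analysis window is an m × n sample matrix **S** (m time samples,
default 200 at 1 kHz; n physical channels, one per muscle). For every
unordered pair of physical channels (i, j), VDI appends the virtual
channel

&nbsp;&nbsp;&nbsp;&nbsp;S<sub>k</sub> = | S<sub>i</sub>² − S<sub>j</sub>² |&nbsp;&nbsp;(elementwise),

the pointwise contrast in activity intensity between muscles i and j.
The augmented window [S, S<sub>k</sub>, …] has n + n(n−1)/2 columns.
Because interference shared by nearby electrodes (line noise,
reference drift, crosstalk) contributes the same power to both
channels, the squared difference largely cancels it — the virtual
channel carries cleaner between-muscle contrast than either channel
alone.

From each column three features are extracted — the population
standard deviation of the rectified signal, the RMS, and the mean
power frequency of the periodogram — then min–max normalized to
[0, 1] (fitted on training data). For a labeled, normalized feature
set with K classes, class means x̄ᵏ and per-class population standard
deviations sᵏ, the separability statistic is

&nbsp;&nbsp;&nbsp;&nbsp;SFV = D / c,

where D is the mean Euclidean distance between class-mean vectors over
all unordered class pairs (interclass dispersion) and c is the grand
mean of all per-class, per-feature standard deviations (intraclass
dispersion). Larger SFV ⇒ tighter, farther-apart class clusters ⇒
higher expected recognition accuracy. Classification itself uses a
single-hidden-layer back-propagation network (2I + 1 logistic hidden
units for I features, softmax output).

## Worked example

Simulate the five-gesture task (thumbs up, "V", "OK", fist, open hand)
on four forearm muscles and compare recognition with and without
virtual channels, three replicate seeds, 150 windows per gesture,
2:1 train/test split:

```r
library(vdiemg)
cfg <- experiment_config(n_per_gesture = 150, n_seeds = 3, seed = 42)
compare_vdi(cfg)
#> Before/after virtual-dimension increase (4 channels, 3 seeds)
#>        arm n_seeds mean_accuracy sd_accuracy mean_sfv sd_sfv
#>  augmented       3        0.7493     0.02274    4.742 0.1083
#>      plain       3        0.6213     0.02810    2.891 0.0645
#> mean delta (augmented - plain): accuracy +0.1280, SFV +1.8510
```

Adding the six virtual channels raises mean test accuracy from 0.62
to 0.75 and mean SFV from 2.9 to 4.7 on the same raw windows — the
classifier and the separability statistic agree that the augmented
feature set is easier to separate. A single arm exposes the full
decomposition:

```r
arm <- run_arm(cfg, augment = TRUE, seed = 7)
arm$sfv
#> SFV decomposition (K = 5 classes, I = 30 features)
#>   interclass dispersion D = 0.651698
#>   intraclass dispersion c = 0.136684
#>   SFV = D/c = 4.76793
arm$report
#> Recognition accuracy: 0.7640 on 250 test windows
```

`channel_sweep()` repeats the paired comparison at 2, 3 and 4
electrodes and `subsample_study()` reruns it on random subsamples of
60–150 windows per gesture, where accuracy estimates grow noisy while
SFV stays comparatively steady.

A thin command-line front end (`inst/cli/vdiemg.R`) exposes the verbs
`simulate`, `augment`, `features`, `sfv`, `train-eval`, `compare` and
`subsample` over delimited-text and JSON artifacts.

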