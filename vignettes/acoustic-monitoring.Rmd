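---
title: "Methods: detecting bee flight buzzes and inferring pollination services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting bee flight buzzes and inferring pollination services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The measurement problem

A foraging bumble bee radiates a *flight buzz*: a harmonic series produced
by thoracic/wing oscillation, with energy at integer multiples of the
wing-beat frequency. That fundamental — the *characteristic frequency* —
sits between roughly 120 and 400 Hz and decreases with body size and tongue
length, the two functional traits that most influence pollination
efficiency. `beebuzz` turns these facts into a monitoring chain: detect and
count buzzes in long recordings (buzz density, buzzes/h), extract per-buzz
characteristic frequencies, regress frequency on traits, and relate buzz
density to the seed set that pollination ultimately produces.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generators do and do not emulate.

# The detection pipeline

Detection is a computational auditory scene analysis (CASA) procedure with
four stages, run on overlapping chunks of the recording.

**Spectrogram and noise profile.** Chunks are analyzed with a Hamming STFT,
`fft_size = 1024`, `hop = 256`. At the 11.025 kHz rate typical of field
recorders this yields time–frequency bins of about 10.8 Hz × 23 ms — fine
enough to separate harmonics 120 Hz apart, coarse enough that a 0.3 s buzz
spans a dozen frames. Times are reported at window centers, frequencies at
bin centers, intervals are half-open. A per-bin noise profile is subtracted
(magnitude spectral subtraction floored at zero, with no over-subtraction
factor); by default the profile is the per-bin *median* magnitude of the
chunk, which tracks the noise floor as long as buzzes occupy a minority of
frames. A fixed profile or an explicit quiet segment can be supplied
instead.

**Focal templates.** For each frame, candidate fundamentals on a grid
(120–400 Hz in steps of one frequency bin) are scored by how many of their
first 5 harmonics are *present*; the best candidate (ties toward the lower
fundamental) is accepted when at least 3 harmonics are present, and only
then does the frame contribute its harmonic-stack bins (± 1 bin of
tolerance) to the retained set. Presence of a harmonic requires a bin
within tolerance of the harmonic position that

1. exceeds `magnitude_threshold = 2` times the noise profile,
2. exceeds a dynamic-range floor `rel_floor = 0.01` of the frame's maximum
   magnitude, and
3. is a local spectral maximum.

Criteria 2 and 3 exist because criterion 1 alone is degenerate when the
noise profile is very small: a Hamming window leaks energy everywhere
(sidelobes at −43 dB, i.e. ~0.007 of the mainlobe), so with a near-zero
profile every candidate would find "energy" at all of its harmonics. The
floor is set just above the sidelobe level; the local-maximum test stops
the mainlobe skirt of one harmonic from impersonating a neighbor. Both
guards were chosen from the window's known leakage geometry, not fitted to
data. Thresholding is applied to the noise-subtracted spectrogram against
a multiple of the profile; on white noise this brings the per-frame false
acceptance rate to roughly 10⁻⁴, versus order one if raw magnitudes were
thresholded.

**Spectral clustering.** Retained bins get a Gaussian affinity
`exp(-(Δframe²/(2σ_t²) + Δbin²/(2σ_f²)))` with `σ_t = 5` frames (~0.12 s)
and `σ_f = 2` bins (~22 Hz) — scales chosen so that bins within one buzz
cohere while buzzes a second apart do not interact. Clustering follows the
standard normalized-cut relaxation: k-means on the eigenvectors with the
smallest eigenvalues of the symmetric normalized Laplacian
I − D^{−1/2} A D^{−1/2}, rows normalized to unit length. A literal variant
that takes the smallest eigenvectors of the affinity matrix itself is kept
behind `method = "affinity"` for fidelity experiments; it is usually
degenerate (those eigenvectors are noise-like), so the Laplacian form is
the default and the documented behavior. `k = 3` so that simultaneous
buzzes can land in separate clusters; k-means uses a fixed seed with 10
restarts (best within-cluster sum of squares wins) and Lloyd iterations,
which tolerate the heavily duplicated rows a tight embedding produces.
When every embedded point coincides (one tight blob), the blob is split
deterministically into k balanced groups rather than calling k-means on
indistinguishable points.

**Gates and event shaping.** A cluster is a *prospective* buzz when its
point density — member bins per spanned frame — is at least 1.0 (at least
one harmonic point per frame on average; both gates are inclusive). Its
per-frame point counts are then convolved with a 20-element moving-average
kernel (entries 1/20, "same" alignment) into a one-dimensional *smashed
cluster* vector; the cluster is recorded as a buzz when the peak reaches
1.0, i.e. one point per frame sustained across a 20-frame (~0.46 s) window.
The kernel entries are uniform because only the kernel length is inherent
to the method; a uniform kernel makes the 1.0 threshold interpretable. The
convolution is computed by exact integer moving sums — an FFT convolution
leaves 1 − 10⁻¹⁶ artifacts exactly at the inclusive threshold.

Event boundaries are the cluster's point-bearing frames (runs separated by
more than the merge gap split into separate events), *not* the region where
the smashed score exceeds 0.5: the 20-frame kernel smears onsets by about
±0.23 s at this frame rate, which would defeat sub-0.1 s event timing,
while occupied-frame boundaries land within a frame or two of the true
onset. The smashed vector is used only as the acceptance gate. Remaining
shaping: recordings are processed in 3 s chunks with 0.5 s overlap (bounding
the affinity matrix; any buzz up to 0.5 s is wholly contained in some
chunk), events overlapping by more than half of the shorter one or closer
than 0.1 s are merged (this also collapses one buzz split across the k = 3
clusters), and events shorter than 0.05 s are dropped. Each event's
characteristic frequency is the 120–400 Hz peak of its averaged, smoothed
spectrum at detection resolution (~10.8 Hz bins). Detection thresholds are
all noise-relative, so the event set is invariant under uniform amplitude
scaling.

# Characteristic frequency

Per-buzz measurements use the averaged Hamming power spectrum at
`fft_size = 8192` (1.35 Hz bins at 11.025 kHz), noise-profile subtraction,
a centered 3-bin sliding average (edge bins average their available
neighbors, so constants pass through unchanged and edges are not biased
downward), and the band peak in 120–400 Hz with ties broken toward the
lower frequency. An all-zero band returns a distinct "no peak" value
rather than an error. Peaks are reported at bin resolution by default;
parabolic interpolation is available but off, since bin-level peaks are the
conventional report. An octave-error guard reports f₀/2 instead of f₀ when
the magnitude at half the picked frequency (inside the band) exceeds 0.5 ×
the peak — harmonic series can have weak fundamentals; the 0.5 ratio is
this package's choice. The default band is configurable because queens of
the largest species approach the 120 Hz edge.

# Trait models

The mixed model is `f0 ~ trait` with a per-bee random intercept, fitted by
REML (`nlme`); per-buzz frequencies enter as repeated measures because the
random effect is defined at the bee level (a per-bee-mean mode exists for
sensitivity checks). REML is the conventional criterion for reported
variance components. The marginal r² follows Nakagawa–Schielzeth:
var(Xβ) / (var(Xβ) + σ²_bee + σ²_resid). F-tests use containment
denominator degrees of freedom as `nlme` defines them; with 28 bees and a
between-bee covariate that is F(1, 26). Published analyses of comparable
designs sometimes print other denominators (e.g. F(1, 16)), which reflects
a different df convention, not a different model; we report containment df
and do not tune to match. When the response is exactly collinear with the
trait (the noiseless limit used in tests), the REML optimizer has nothing
to estimate and fails; the fit then falls back to the ordinary regression
it degenerates to, with zero variance components and marginal r² = 1.

The tongue-length ANCOVA (`f0 ~ tongue + wing` + bee random intercept)
reports type III marginal F-tests, asking whether tongue length explains
frequency beyond body size. The literature synthesis collapses multiple
published values per species × caste by sample-size-weighted means, then
fits ordinary least squares of log(frequency) on tongue length — the log
transform addresses the skew of across-species frequency distributions.
The exotic back-transformed forms sometimes printed for such curves are
displayed, not fitted; the model is the log-linear one. Inverse prediction
(trait from frequency) is the algebraic inversion of the fixed-effect
line, flagged when it extrapolates beyond the fitted trait range.

# Survey statistics

Analyses run on plot means. Acoustic-vs-manual and acoustic-vs-visual
count comparisons use the Pearson correlation with t-based p-values
(df = n − 2), one-tailed for the directional hypothesis of a positive
relationship. The exclusion analysis takes, for every plot × species cell,
the difference in mean seeds per plant between open and caged
inflorescences, and tests the mean difference against zero with a
one-sample, one-tailed t-test (df = cells − 1; with 3 plots and 2 species,
t₅). The seed-set ANCOVA is a linear model of plot-mean seeds on buzz
density with species as covariate (optional interaction), type III tests
under sum-to-zero contrasts. With three plots these tests are legitimately
low-powered; outputs carry a `low_n` flag, no multiple-testing correction
is applied, and an exactly saturated (zero-residual) fit returns NA
F-statistics rather than failing.

# Synthetic data: what it emulates

The generators encode the study conditions the analyses assume, and those
defaults are fixed: plot buzz rate 417.3 buzzes/h; the wing-length line
f₀ = 259.2 − 7.57·wing over wing lengths 8–16 mm (tongue-length line
238.2 − 7.96·tongue over 5–14 mm), bee random-intercept SD 5 Hz, residual
SD 10 Hz, 28 bees × 5 buzzes; seed-set records over 3 plots × 2 species ×
2 treatments with a mean open-minus-caged bee contribution of 3.89
seeds/plant (realized as a per-plot density slope so that the across-plot
mean effect equals 3.89 at the default densities 0.5×, 1×, 1.5× the field
rate), caged baseline 2 seeds, cell noise SD 1 seed; audio SNR 20 dB over
white noise. Buzzes are harmonic stacks with 1/h amplitude ladders (a
geometric decay is available), raised-cosine attack/decay over 10% of the
duration, ~1 Hz random-walk jitter on the fundamental in soundscapes, and
durations 0.3–0.7 s separated by at least 1 s. Visual survey counts are a
binomial thinning (p = 0.5) of acoustic counts, reproducing the roughly
2:1 buzz-to-visual ratio that arises because buzz counts accumulate over
repeat flights of the same forager.

What the generators do **not** emulate: colored field noise (wind, birds),
MP3 codec artifacts, microphone directivity, overlapping simultaneous
buzzes on one microphone, and pollination (sonication) buzzes — the
detector carries a per-event `call` field but always labels events
"flight". Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical structure, not field performance
under every nuisance the field provides.

# Problem sizes and reproducibility

All simulations are seeded and bit-reproducible. The test suite uses the
study-scale designs throughout: 200-replicate recovery loops for the trait
lines, 500 replicates for the exclusion effect, a 200-buzz soundscape at
the field rate (~29 min of audio) for detector recall/precision, and
exhaustive normalized-cut enumeration on instances of at most 8 bins as
the independent clustering oracle. Power checks of the open-treatment
seed-set ANCOVA use halved cell noise (SD 0.5): at the field design of
three plots the F(1, 3) test has only ~75% power at the default noise, a
real limitation of three-plot designs rather than of the estimator, so the
inferential machinery is verified at a signal-to-noise where its decisions
are determined by correctness rather than by power.

# Known limitations

- The acceptance band of the focal template is sharp only to one frequency
  bin (~10.8 Hz): sweeps show acceptance from ~114 to ~405 Hz, the
  quantization of harmonic positions onto bins.
- Detector event timing is accurate to a frame or two (~±0.05 s); the
  envelope attack of a quiet buzz can delay the first accepted frame.
- One bee audible on two microphones is counted twice; per-plot counts sum
  microphones, consistent with buzz counts exceeding visual counts.
- With only three plots, seed-set inference is reported but flagged low-n;
  confidence in landscape-scale conclusions should come from more plots,
  not from this package's p-values.
- The command-line wrapper exposes the default configurations through
  flags; non-default detector or scenario settings are meant to be driven
  programmatically through `detector_config()` and `scenario_config()`.
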