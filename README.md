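# beebuzz

Passive acoustic monitoring of bumble bee activity and the pollination
services it predicts.

Bees in flight radiate a harmonic buzz whose fundamental — the
**characteristic frequency**, equal to the wing-beat frequency — lies between
roughly 120 and 400 Hz. Counting those buzzes in long field recordings gives
a cheap, non-invasive proxy for pollinator activity (`buzz density`, buzzes
per hour), and because the characteristic frequency falls with body size and
tongue length, the same signal carries information about pollinator
functional traits. This package provides the full chain, for pollination
ecologists and anyone building insect soundscape monitors:

1. **Detection** — a computational auditory scene analysis (CASA) pipeline.
   For a spectrogram magnitude matrix *M*(t, f), harmonic *focal templates*
   retain time–frequency bins lying on a stack {h·f₀ : h = 1…5} of a
   candidate fundamental f₀ ∈ [120, 400] Hz (a candidate is accepted in a
   frame when ≥ 3 harmonics exceed 2× the noise profile). Retained bins are
   grouped by normalized spectral clustering — k-means on the eigenvectors
   with the smallest eigenvalues of the symmetric normalized Laplacian
   I − D^{−1/2} A D^{−1/2} of the Gaussian affinity
   A_ij = exp(−Δt²/2σ_t² − Δf²/2σ_f²), with k = 3. A cluster is reported as
   a buzz when its point density is ≥ 1.0 per spanned frame **and** the peak
   of its "smashed cluster" vector (per-frame point counts convolved with a
   20-element moving-average kernel) reaches 1.0.
2. **Characteristic frequency** — Hamming-windowed average power spectrum
   (FFT 8192), noise-profile subtraction, a 3-bin sliding average, and
   band-limited peak picking.
3. **Trait inference** — mixed-effects regression of per-buzz frequency on
   wing or tongue length with a per-bee random intercept
   (f₀ = β₀ + β₁·trait + b_bee + ε, REML), reporting the marginal r²
   (Nakagawa–Schielzeth); a type III mixed ANCOVA of tongue length with wing
   length as covariate; and a log-linear literature synthesis
   log f₀ = a + b·tongue over sample-size-weighted species × caste means.
4. **Pollination services** — one-tailed exclusion t-test on plot-level
   open-minus-caged seed set, and an ANCOVA of plot-mean seeds per plant on
   buzz density with plant species as covariate.
5. **Synthetic data** — generators for harmonic buzzes, seeded soundscapes
   with ground-truth event tables, trait-structured bee populations and
   plot-level survey/seed-set tables, so every stage is testable without
   field recordings.

## Worked example

Synthesize a one-minute soundscape with seven buzzes, detect them, and fit
the trait model to a simulated bee population:

```r
library(beebuzz)

cfg <- scenario_config(seed = 42)
scene <- synth_soundscape(cfg, duration_h = 60 / 3600, n_buzzes = 7)
events <- detect_buzzes(scene$recording)
events
#> 7 buzz event(s) in 60.0 s of audio
#>    source_id  start   end    f0 peak_score density   call
#> 1 soundscape  9.961 10.46 204.6       4.50   3.000 flight
#> 2 soundscape 12.438 12.90 172.3       7.75   9.118 flight
#> 3 soundscape 19.288 19.87 172.3       9.00   9.000 flight
#> 4 soundscape 26.649 27.18 183.0       5.80   5.800 flight
#> 5 soundscape 29.172 29.80 150.7       9.00   8.792 flight
#> 6 soundscape 43.173 43.68 140.0       5.70   6.000 flight
#> 7 soundscape 56.486 57.16 172.3       3.00   3.000 flight
buzz_density(events)
#> [1] 420
```

All seven planted buzzes are found (onsets within ±0.1 s of truth), each
event carrying its characteristic frequency (detection bins are ~10.8 Hz
wide) and the two gate scores, both ≥ 1.0 by construction. 7 events in a
minute is 420 buzzes/h — the order of magnitude seen over flowering alpine
clover.

```r
set.seed(1)
bees <- synth_bee_population(28, 5)   # 28 bees x 5 buzzes each
fit <- fit_freq_trait(bees, "wing_length")
summary(fit)
#> Mixed-model regression: f0 ~ wing_length (random intercept per bee)
#>   f0 = 273.9 -8.721 * wing_length  (Hz, trait in mm)
#>   marginal r2 = 0.803, F(1, 26) = 351.08, p = 1.11e-16
#>   variance components: bee 15.57 Hz^2, residual 86.38 Hz^2
#>   28 bees, 140 buzzes; trait range 8.11-15.94 mm

predict_trait_from_frequency(fit, c(150, 185))
#>    f0    trait extrapolated
#> 1 150 14.20204        FALSE
#> 2 185 10.18880        FALSE
```

One simulated draw of the study (generating line 259.2 − 7.57·wing) gives a
fitted slope of −8.7 Hz/mm; across 200 replicates the mean estimate is
unbiased (see the acceptance report below). The inverse prediction turns an
observed 150 Hz buzz into a ~14 mm (large-bodied queen) wing-length
estimate.

```r
set.seed(1)
tabs <- synth_survey_seeds(scenario_config())
tt <- exclusion_ttest(tabs$seeds)
#> exclusion: mean diff = 4.24 seeds/plant, t(5) = 4.39, one-tailed p = 0.0035
```

Caging flowers against bumble bees costs about four seeds per plant in this
draw; the one-tailed t-test on the six plot × species differences detects
the loss.

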