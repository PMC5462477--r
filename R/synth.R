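#' Scenario configuration for the synthetic generators
#'
#' Default constants describe the study conditions the analyses assume:
#' plot-level buzz rate 417.3 buzzes/h; wing-length trait line
#' \code{f0 = 259.2 - 7.57 * wing} (Hz, mm) with bee random-intercept SD 5 Hz
#' and residual SD 10 Hz over 28 bees x 5 buzzes; seed-set model with a mean
#' open-minus-caged bee contribution of 3.89 seeds per plant across plots and
#' cell noise SD 1; SNR 20 dB over white background noise. All overridable.
#'
#' @param plots number of survey plots.
#' @param buzz_rate buzzes per hour per plot.
#' @param snr_db buzz-to-noise RMS ratio in dB.
#' @param sample_rate audio sample rate in Hz.
#' @param trait_intercept,trait_slope generating trait line (Hz, Hz/mm).
#' @param trait_range uniform range of the generating trait (mm).
#' @param bee_sd,resid_sd bee random-intercept and residual SDs (Hz).
#' @param n_bees,n_buzzes_per_bee bee pool dimensions.
#' @param seed_baseline caged (bee-free) mean seeds per plant.
#' @param open_caged_effect mean bee contribution in seeds per plant across
#'   plots; the per-plot effect is \code{density_slope * density}.
#' @param density_slope seeds per plant per (buzz/h); \code{NULL} (default)
#'   derives it as \code{open_caged_effect / buzz_rate} so the across-plot
#'   mean effect equals \code{open_caged_effect}.
#' @param species_offsets additive species effects (seeds) on the open
#'   treatment, one per plant species.
#' @param seed_noise_sd per-cell noise SD of plot-mean seeds.
#' @param noise_rms background-noise amplitude RMS (audio scale).
#' @param min_gap_s minimum silent gap between consecutive buzzes.
#' @param buzz_dur range of buzz durations in seconds.
#' @param thinning probability a buzz-generating visit is also counted
#'   visually (visual counts as binomial thinning of acoustic activity).
#' @param seed optional RNG seed applied by the generators for full
#'   reproducibility.
#' @return A list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(plots = 3L, buzz_rate = 417.3, snr_db = 20,
                            sample_rate = 11025,
                            trait_intercept = 259.2, trait_slope = -7.57,
                            trait_range = c(8, 16), bee_sd = 5,
                            resid_sd = 10, n_bees = 28L,
                            n_buzzes_per_bee = 5L,
                            seed_baseline = 2, open_caged_effect = 3.89,
                            density_slope = NULL,
                            species_offsets = c(0, 0), seed_noise_sd = 1,
                            noise_rms = 0.01, min_gap_s = 1.0,
                            buzz_dur = c(0.3, 0.7), thinning = 0.5,
                            seed = NULL) {
  stopifnot(plots >= 1L, buzz_rate >= 0, noise_rms > 0,
            thinning >= 0, thinning <= 1)
  if (is.null(density_slope)) density_slope <- open_caged_effect / buzz_rate
  structure(as.list(environment()), class = "scenario_config")
}

#' Synthesize one harmonic flight buzz
#'
#' A flight buzz is a harmonic series with energy at integer multiples of
#' the wing-beat frequency. Harmonic h gets amplitude \code{amps[h]}
#' (default \code{1/h}); a raised-cosine attack/decay envelope and an
#' optional random-walk jitter on the fundamental make the tone buzz-like.
#' The waveform is RMS-normalized to \code{rms}.
#'
#' @param f0 fundamental (wing-beat) frequency in Hz.
#' @param duration seconds (> 0).
#' @param sample_rate Hz.
#' @param n_harmonics number of harmonics (default 5); requires
#'   \code{f0 * n_harmonics < sample_rate / 2}.
#' @param amps per-harmonic amplitudes; default \code{1 / h}.
#' @param harmonic_decay if given, overrides \code{amps} with
#'   \code{harmonic_decay^(h-1)}.
#' @param f0_jitter_sd SD in Hz of the fundamental's slow random-walk drift
#'   over the buzz (0 = none).
#' @param attack_frac fraction of the duration used by each of the attack
#'   and decay ramps.
#' @param rms target RMS amplitude.
#' @return A \code{\link{recording}}.
#' @export
synth_buzz <- function(f0, duration = 0.5, sample_rate = 11025,
                       n_harmonics = 5L, amps = NULL, harmonic_decay = NULL,
                       f0_jitter_sd = 0, attack_frac = 0.1, rms = 0.1) {
  stopifnot(f0 > 0, duration > 0)
  if (f0 * n_harmonics >= sample_rate / 2)
    stop("aliasing: f0 * n_harmonics = ", f0 * n_harmonics,
         " Hz exceeds the Nyquist frequency ", sample_rate / 2, " Hz",
         call. = FALSE)
  n <- max(2L, round(duration * sample_rate))
  if (is.null(amps))
    amps <- if (!is.null(harmonic_decay)) harmonic_decay^(seq_len(n_harmonics) - 1)
            else 1 / seq_len(n_harmonics)
  stopifnot(length(amps) == n_harmonics)
  f_inst <- rep(f0, n)
  if (f0_jitter_sd > 0) {
    walk <- cumsum(stats::rnorm(n, 0, f0_jitter_sd / sqrt(n)))
    f_inst <- f0 + walk - mean(walk)
  }
  phase <- 2 * pi * cumsum(f_inst) / sample_rate
  x <- numeric(n)
  for (h in seq_len(n_harmonics)) x <- x + amps[h] * sin(h * phase)
  ## raised-cosine attack/decay envelope
  na <- max(1L, round(attack_frac * n))
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(na) / na))
  env[seq_len(na)] <- ramp
  env[n - seq_len(na) + 1L] <- ramp
  x <- x * env
  x <- x * rms / sqrt(mean(x^2))
  recording(x, sample_rate, source_id = sprintf("synth_buzz_%gHz", f0))
}

#' Simulate a bee population with trait-driven buzz frequencies
#'
#' Traits are drawn uniformly from \code{trait_range}; each bee gets a
#' random intercept (SD \code{bee_sd}) and each of its buzzes an independent
#' residual (SD \code{resid_sd}) around the generating line
#' \code{f0 = intercept + slope * trait}. The second trait is drawn
#' independently (its range defaulting to tongue lengths 5-14 mm when the
#' generating trait is wing length, and wing lengths 8-16 mm otherwise).
#'
#' @param n_bees number of bees.
#' @param n_buzzes buzzes recorded per bee.
#' @param intercept,slope generating line (Hz, Hz/mm).
#' @param trait name of the generating trait column.
#' @param trait_range uniform range for the generating trait (mm).
#' @param other_range uniform range for the other trait (mm).
#' @param bee_sd,resid_sd random-intercept and residual SDs (Hz).
#' @return Data frame with one row per buzz: \code{bee_id}, \code{species},
#'   \code{caste}, \code{wing_length}, \code{tongue_length}, \code{f0}, plus
#'   the per-bee truth columns \code{bee_intercept}.
#' @export
synth_bee_population <- function(n_bees = 28L, n_buzzes = 5L,
                                 intercept = 259.2, slope = -7.57,
                                 trait = c("wing_length", "tongue_length"),
                                 trait_range = c(8, 16),
                                 other_range = NULL,
                                 bee_sd = 5, resid_sd = 10) {
  trait <- match.arg(trait)
  stopifnot(n_bees >= 1L, n_buzzes >= 1L)
  if (is.null(other_range))
    other_range <- if (trait == "wing_length") c(5, 14) else c(8, 16)
  tr <- stats::runif(n_bees, trait_range[1L], trait_range[2L])
  other <- stats::runif(n_bees, other_range[1L], other_range[2L])
  b <- stats::rnorm(n_bees, 0, bee_sd)
  species <- rep(c("Bombus balteatus", "Bombus sylvicola"),
                 length.out = n_bees)
  caste <- ifelse(tr >= stats::median(tr), "queen", "worker")
  d <- data.frame(
    bee_id = rep(sprintf("bee%02d", seq_len(n_bees)), each = n_buzzes),
    species = rep(species, each = n_buzzes),
    caste = rep(caste, each = n_buzzes),
    stringsAsFactors = FALSE)
  d[[trait]] <- rep(tr, each = n_buzzes)
  d[[setdiff(c("wing_length", "tongue_length"), trait)]] <-
    rep(other, each = n_buzzes)
  d$bee_intercept <- rep(b, each = n_buzzes)
  d$f0 <- intercept + slope * d[[trait]] + d$bee_intercept +
    stats::rnorm(nrow(d), 0, resid_sd)
  d
}

## Place n intervals of the given durations uniformly in [0, total_s] with at
## least min_gap between them (stick-breaking over the free time).
place_onsets <- function(n, durations, total_s, min_gap) {
  if (n == 0L) return(numeric(0))
  free <- total_s - sum(durations) - (n - 1) * min_gap
  if (free < 0)
    stop("cannot place ", n, " buzzes with min gap ", min_gap,
         " s in ", total_s, " s", call. = FALSE)
  cuts <- sort(stats::runif(n, 0, free))
  gaps <- diff(c(0, cuts))
  onsets <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    t <- t + gaps[i]
    onsets[i] <- t
    t <- t + durations[i] + min_gap
  }
  onsets
}

#' Synthesize a soundscape with known buzz ground truth
#'
#' Buzz count follows a Poisson draw at the configured rate (or is fixed via
#' \code{n_buzzes}); onsets are uniform subject to a minimum silent gap;
#' each buzz's fundamental is generated from the configured trait model via
#' a simulated bee pool; white background noise sets the SNR. Every inserted
#' buzz appears exactly once in the returned truth table.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @param duration_h recording length in hours.
#' @param n_buzzes fixed buzz count; \code{NULL} (default) draws
#'   Poisson(\code{buzz_rate * duration_h}).
#' @return List with \code{recording} and \code{truth} (data frame
#'   \code{onset}, \code{end}, \code{duration}, \code{f0}).
#' @export
synth_soundscape <- function(cfg = scenario_config(), duration_h,
                             n_buzzes = NULL) {
  stopifnot(inherits(cfg, "scenario_config"), duration_h > 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  total_s <- duration_h * 3600
  n <- if (is.null(n_buzzes)) stats::rpois(1L, cfg$buzz_rate * duration_h)
       else as.integer(n_buzzes)
  n_samp <- round(total_s * cfg$sample_rate)
  noise <- stats::rnorm(n_samp, 0, cfg$noise_rms)
  if (n == 0L) {
    return(list(recording = recording(noise, cfg$sample_rate, "soundscape"),
                truth = data.frame(onset = numeric(0), end = numeric(0),
                                   duration = numeric(0), f0 = numeric(0))))
  }
  durs <- stats::runif(n, cfg$buzz_dur[1L], cfg$buzz_dur[2L])
  onsets <- place_onsets(n, durs, total_s, cfg$min_gap_s)
  pool <- synth_bee_population(cfg$n_bees, cfg$n_buzzes_per_bee,
                               intercept = cfg$trait_intercept,
                               slope = cfg$trait_slope,
                               trait_range = cfg$trait_range,
                               bee_sd = cfg$bee_sd, resid_sd = cfg$resid_sd)
  f0s <- sample(pool$f0, n, replace = TRUE)
  buzz_rms <- cfg$noise_rms * 10^(cfg$snr_db / 20)
  x <- noise
  for (i in seq_len(n)) {
    b <- synth_buzz(f0s[i], durs[i], cfg$sample_rate,
                    f0_jitter_sd = 1, rms = buzz_rms)
    i0 <- round(onsets[i] * cfg$sample_rate) + 1L
    idx <- i0:min(n_samp, i0 + length(b$samples) - 1L)
    x[idx] <- x[idx] + b$samples[seq_along(idx)]
  }
  list(recording = recording(x, cfg$sample_rate, "soundscape"),
       truth = data.frame(onset = onsets, end = onsets + durs,
                          duration = durs, f0 = f0s))
}

#' Synthesize plot surveys and seed-set records
#'
#' Per plot: acoustic buzz counts are Poisson at the plot's buzz rate;
#' visual counts are a binomial thinning of the acoustic activity (the field
#' gap between buzz and visual counts comes from repeat flights of one
#' forager and spatially missed bees). Plot-mean seeds per plant: caged
#' cells get \code{seed_baseline + noise}; open cells additionally get
#' \code{density_slope * density + species offset}, so the across-plot mean
#' bee contribution equals \code{open_caged_effect} at the default
#' densities.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @param densities per-plot nominal buzz densities (buzzes/h); default
#'   \code{buzz_rate * c(0.5, 1, 1.5)} scaled to the number of plots.
#' @param recording_hours acoustic survey duration per plot.
#' @return List with \code{survey} (per-plot data frame: \code{plot_id},
#'   \code{elevation}, \code{acoustic_buzzes}, \code{visual_bees},
#'   \code{recording_hours}, \code{observation_hours}, \code{density}) and
#'   \code{seeds} (plot x species x treatment records with plot-mean
#'   \code{seeds}).
#' @export
synth_survey_seeds <- function(cfg = scenario_config(), densities = NULL,
                               recording_hours = 6) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$plots >= 2L)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- cfg$plots
  if (is.null(densities))
    densities <- cfg$buzz_rate * seq(0.5, 1.5, length.out = p)
  plot_id <- sprintf("plot%d", seq_len(p))
  acoustic <- stats::rpois(p, densities * recording_hours)
  visual <- stats::rbinom(p, acoustic, cfg$thinning)
  survey <- data.frame(
    plot_id = plot_id,
    elevation = seq(3659, 3735, length.out = p),
    acoustic_buzzes = acoustic, visual_bees = visual,
    recording_hours = recording_hours,
    observation_hours = recording_hours / 4,
    density = acoustic / recording_hours,
    stringsAsFactors = FALSE)
  species <- c("Trifolium dasyphyllum", "Trifolium parryi")
  grid <- expand.grid(plot_id = plot_id, species = species,
                      treatment = c("open", "caged"),
                      stringsAsFactors = FALSE)
  grid$density <- densities[match(grid$plot_id, plot_id)]
  off <- stats::setNames(rep_len(cfg$species_offsets, length(species)),
                         species)
  mu <- ifelse(grid$treatment == "open",
               cfg$seed_baseline + cfg$density_slope * grid$density +
                 off[grid$species],
               cfg$seed_baseline)
  grid$seeds <- pmax(0, mu + stats::rnorm(nrow(grid), 0, cfg$seed_noise_sd))
  list(survey = survey,
       seeds = grid[, c("plot_id", "species", "treatment", "seeds")])
}
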