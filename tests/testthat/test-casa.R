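zero_noise <- function(spec) rep(0, ncol(spec$magnitudes))

test_that("focal template retains harmonic stacks and nothing else", {
  sr <- 11025
  binw <- sr / 1024
  f0 <- 120 + 8 * binw          # on the candidate grid (~206 Hz)
  spec <- stft_spectrogram(synth_buzz(f0, 0.5, sr), 1024L, 256L)
  foc <- apply_focal_template(spec, zero_noise(spec))
  expect_gt(length(foc$frame), 0)
  ## every retained bin lies within 1 bin of some harmonic of the fundamental
  harmonic_bins <- round(f0 * (1:5) / binw) + 1L
  dist <- sapply(foc$bin, function(b) min(abs(b - harmonic_bins)))
  expect_true(all(dist <= 1))
  ## brute-force scan oracle: recompute acceptance frame by frame
  eligible <- function(f) {
    m <- spec$magnitudes[f, ]
    ok <- m >= 0.01 * max(m) & m > 0
    peak <- c(TRUE, diff(m) >= 0) & c(m[-length(m)] >= m[-1], TRUE)
    which(ok & peak)
  }
  for (f in unique(foc$frame)) {
    el <- eligible(f)
    n_present <- sum(sapply(harmonic_bins, function(hb)
      any(abs(el - hb) <= 1)))
    expect_gte(n_present, 3)
  }
})

test_that("silence and non-harmonic tones are pushed to the background", {
  silent <- recording(rep(0, 11025), 11025)
  spec <- stft_spectrogram(silent, 1024L, 256L)
  expect_length(apply_focal_template(spec, zero_noise(spec))$frame, 0)

  ## pure 1 kHz tone: fundamental outside 120-400 Hz and no harmonic partners
  tone <- recording(sin(2 * pi * 1000 * seq_len(11025) / 11025), 11025)
  spec2 <- stft_spectrogram(tone, 1024L, 256L)
  expect_length(apply_focal_template(spec2, zero_noise(spec2))$frame, 0)
})

test_that("affinity matrix matches the closed-form Gaussian kernel", {
  foc <- structure(list(frame = c(1L, 6L, 1L, 3L, 9L),
                        bin = c(10L, 10L, 12L, 11L, 30L),
                        n_frames = 9L, n_bins = 40L),
                   class = "focused_spectrogram")
  A <- build_affinity(foc, sigma_t = 5, sigma_f = 2)
  expect_true(isSymmetric(A))
  expect_equal(diag(A), rep(1, 5))
  expect_true(all(A > 0 & A <= 1))
  ## two bins at (frame distance sigma_t, same bin): exp(-1/2)
  expect_equal(A[1, 2], exp(-0.5), tolerance = 1e-12)
  ## element-by-element hand evaluation
  for (i in 1:5) for (j in 1:5) {
    expect_equal(A[i, j],
                 exp(-((foc$frame[i] - foc$frame[j])^2 / 50 +
                         (foc$bin[i] - foc$bin[j])^2 / 8)),
                 tolerance = 1e-12)
  }
})

test_that("spectral clustering recovers block structure and partitions", {
  ## two well-separated groups
  A <- matrix(1e-8, 6, 6)
  A[1:3, 1:3] <- 0.9; A[4:6, 4:6] <- 0.9
  diag(A) <- 1
  lab <- spectral_cluster(A, k = 2L, seed = 0L)
  expect_true(same_partition(lab, c(1, 1, 1, 2, 2, 2)))

  ## labels always form a partition: every point exactly one label
  lab3 <- spectral_cluster(A, k = 3L, seed = 0L)
  expect_length(lab3, 6L)
  expect_equal(length(unique(lab3)), 3L)

  ## degenerate k >= n: each point its own cluster
  expect_equal(spectral_cluster(A[1:3, 1:3], k = 5L), 1:3)

  ## determinism under the seed, without touching the global RNG
  set.seed(99); before <- .Random.seed
  l1 <- spectral_cluster(A, k = 2L, seed = 7L)
  expect_identical(.Random.seed, before)
  expect_identical(l1, spectral_cluster(A, k = 2L, seed = 7L))
})

test_that("spectral clustering agrees with exhaustive normalized cut", {
  set.seed(55)
  for (trial in 1:8) {
    ## structured instances: 2-3 groups of 2-3 points with within-group
    ## affinity near 1 and cross affinity near 0 plus jitter
    k <- sample(2:3, 1)
    sizes <- sample(2:3, k, replace = TRUE)
    n <- sum(sizes)
    g <- rep(seq_len(k), sizes)
    A <- matrix(runif(n * n, 0.001, 0.05), n, n)
    A[outer(g, g, `==`)] <- runif(sum(outer(g, g, `==`)), 0.85, 1)
    A <- (A + t(A)) / 2; diag(A) <- 1
    oracle <- ncut_bruteforce(A, k)
    lab <- spectral_cluster(A, k = k, seed = 0L)
    expect_true(same_partition(lab[order(g)], oracle$labels[order(g)]),
                info = sprintf("trial %d", trial))
  }
})

test_that("cluster density is points per spanned frame with inclusive gate", {
  cl10 <- list(frame = 1:10, bin = rep(5L, 10))
  expect_equal(cluster_density(cl10)$density, 1.0)
  expect_true(cluster_density(cl10)$prospective)   # >= is inclusive

  cl5 <- list(frame = c(1, 3, 5, 7, 10), bin = rep(5L, 5))
  expect_equal(cluster_density(cl5)$density, 0.5)
  expect_false(cluster_density(cl5)$prospective)

  cl50 <- list(frame = rep(1:10, each = 5), bin = rep(1:5, 10))
  expect_equal(cluster_density(cl50)$density, 5.0)
  expect_error(cluster_density(list(frame = integer(0), bin = integer(0))),
               "empty")
})

test_that("smashed cluster scores follow the 20-element kernel arithmetic", {
  ## sustained cluster: >= 1 point in each of 25 consecutive frames
  sust <- list(frame = 1:25, bin = rep(3L, 25))
  sm <- smash_cluster(sust)
  expect_gte(sm$peak, 1.0)
  expect_true(sm$buzz)

  ## single isolated point: peak 1/20
  one <- smash_cluster(list(frame = 5L, bin = 2L))
  expect_equal(one$peak, 1 / 20)
  expect_false(one$buzz)

  ## 3 points/frame over 10 frames inside a 40-frame span: peak 30/20
  ## 3/frame over frames 11-20 inside a 1-40 span; the best 20-frame window
  ## (frames 1-20) also catches the stray point at frame 1
  spread <- list(frame = c(rep(11:20, each = 3), 1L, 40L),
                 bin = rep(1L, 32))
  expect_equal(smash_cluster(spread)$peak, 31 / 20)
  tight <- list(frame = rep(11:20, each = 3), bin = rep(1:3, 10))
  expect_equal(smash_cluster(tight)$peak, 30 / 20)
})
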