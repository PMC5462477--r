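## Independent oracles used across the suite. These are deliberately naive
## (brute force / closed form) and share no code with the implementation.

## Magnitude of the windowed DFT of one frame, computed term by term.
direct_dft_mag <- function(frame, window = "hamming") {
  n <- length(frame)
  k <- seq(0, n - 1)
  w <- switch(window,
              hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
              hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
              rect = rep(1, n))
  xw <- frame * w
  sapply(0:(n %/% 2), function(bin) {
    Mod(sum(xw * exp(-2i * pi * bin * k / n)))
  })
}

## Exhaustive minimum normalized cut over all assignments of n points into
## exactly k non-empty groups. Returns canonical labels.
ncut_value <- function(A, labels) {
  total <- sum(A)
  val <- 0
  for (g in unique(labels)) {
    inside <- labels == g
    vol <- sum(A[inside, , drop = FALSE])
    cut <- sum(A[inside, !inside, drop = FALSE])
    val <- val + cut / vol
  }
  val
}

ncut_bruteforce <- function(A, k) {
  n <- nrow(A)
  stopifnot(k <= n, n <= 8)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- NULL; best_val <- Inf
  for (i in seq_len(nrow(grid))) {
    lab <- grid[i, ]
    if (length(unique(lab)) != k) next
    v <- ncut_value(A, lab)
    if (v < best_val - 1e-12) { best_val <- v; best <- lab }
  }
  list(labels = best, value = best_val)
}

## TRUE when two labelings define the same partition (up to renaming).
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

## Greedy matching of detected events to truth intervals by temporal overlap.
## Returns counts used for recall/precision.
match_events <- function(events, truth, min_frac = 0.3) {
  used <- rep(FALSE, nrow(events))
  hits <- 0L
  for (i in seq_len(nrow(truth))) {
    if (!nrow(events)) break
    ov <- pmin(events$end, truth$end[i]) - pmax(events$start, truth$onset[i])
    frac <- ov / truth$duration[i]
    j <- which(!used & frac >= min_frac)
    if (length(j)) { hits <- hits + 1L; used[j[1L]] <- TRUE }
  }
  list(true_pos = hits, false_neg = nrow(truth) - hits,
       false_pos = sum(!used))
}

## White noise recording helper.
noise_recording <- function(seconds, sample_rate = 11025, rms = 0.01) {
  recording(rnorm(round(seconds * sample_rate), 0, rms), sample_rate,
            "noise")
}
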