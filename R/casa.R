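#' Focal-template configuration
#'
#' A focal template promotes time-frequency bins that sit in harmonic
#' relation to a candidate fundamental (a "harmonic stack") and pushes
#' everything else to the background. A frame contributes retained bins only
#' if its best candidate has at least \code{accept_min_harmonics} harmonics
#' present.
#'
#' A harmonic counts as present when some bin within \code{harmonic_tol} bins
#' of the harmonic's position (i) exceeds \code{magnitude_threshold} times
#' the noise profile at that bin, (ii) exceeds \code{rel_floor} times the
#' frame's maximum magnitude, and (iii) is a local spectral maximum. Guards
#' (ii) and (iii) stop windowing sidelobes (Hamming: -43 dB, i.e. ~0.007 of
#' the mainlobe) and skirts of neighboring harmonics from being counted as
#' harmonic energy, which matters most when the noise profile is near zero.
#'
#' @param f0_lo,f0_hi candidate fundamental range in Hz (default 120-400, the
#'   first-harmonic range of bumble bee flight buzzes).
#' @param f0_step candidate grid step in Hz; \code{NULL} (default) means one
#'   frequency bin of the spectrogram the template is applied to.
#' @param n_harmonics harmonics per stack (default 5).
#' @param harmonic_tol allowed mismatch in bins around each harmonic
#'   (default 1).
#' @param accept_min_harmonics harmonics required to accept a candidate
#'   (default 3).
#' @param magnitude_threshold multiple of the noise profile a bin must exceed
#'   (default 2).
#' @param rel_floor dynamic-range floor as a fraction of the frame's maximum
#'   magnitude (default 0.01, above the Hamming sidelobe level).
#' @return A list of class \code{"focal_template_config"}.
#' @export
focal_template_config <- function(f0_lo = 120, f0_hi = 400, f0_step = NULL,
                                  n_harmonics = 5L, harmonic_tol = 1L,
                                  accept_min_harmonics = 3L,
                                  magnitude_threshold = 2,
                                  rel_floor = 0.01) {
  stopifnot(f0_lo > 0, f0_hi >= f0_lo, n_harmonics >= 1L,
            accept_min_harmonics >= 1L,
            accept_min_harmonics <= n_harmonics,
            magnitude_threshold > 0, harmonic_tol >= 0L, rel_floor >= 0)
  structure(list(f0_lo = f0_lo, f0_hi = f0_hi, f0_step = f0_step,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_tol = as.integer(harmonic_tol),
                 accept_min_harmonics = as.integer(accept_min_harmonics),
                 magnitude_threshold = magnitude_threshold,
                 rel_floor = rel_floor),
            class = "focal_template_config")
}

#' Apply a harmonic focal template to a spectrogram
#'
#' Per frame, scores every candidate fundamental by the number of present
#' harmonics (see \code{\link{focal_template_config}} for the presence
#' criteria); the best candidate (most harmonics, ties toward the lower
#' fundamental) contributes its harmonic-stack bins to the retained set iff
#' at least \code{accept_min_harmonics} harmonics are present. Frames with no
#' accepted candidate contribute nothing. The spectrogram should already be
#' noise-subtracted; \code{noise} is the profile the threshold is scaled by.
#'
#' @param spec a \code{"buzz_spectrogram"} (noise-subtracted).
#' @param noise per-bin noise profile aligned with \code{spec$bin_freqs}.
#' @param cfg a \code{\link{focal_template_config}}.
#' @return An object of class \code{"focused_spectrogram"}: parallel vectors
#'   \code{frame}, \code{bin} (1-based indices), \code{magnitude}, per-frame
#'   accepted fundamentals in \code{frame_f0} (\code{NA} where rejected), and
#'   the parent axes.
#' @export
apply_focal_template <- function(spec, noise, cfg = focal_template_config()) {
  stopifnot(inherits(spec, "buzz_spectrogram"),
            inherits(cfg, "focal_template_config"))
  M <- spec$magnitudes
  n_frames <- nrow(M); n_bins <- ncol(M)
  if (length(noise) != n_bins)
    stop("noise profile length does not match spectrogram bins", call. = FALSE)
  binw <- spec$bin_freqs[2L] - spec$bin_freqs[1L]
  step <- if (is.null(cfg$f0_step)) binw else cfg$f0_step
  grid <- seq(cfg$f0_lo, cfg$f0_hi, by = step)

  ## bin-wise eligibility: above scaled noise, above dynamic-range floor,
  ## and a local spectral maximum
  frame_max <- apply(M, 1L, max)
  above_noise <- sweep(M, 2L, cfg$magnitude_threshold * noise, `>`)
  above_floor <- M >= cfg$rel_floor * frame_max & M > 0
  pass <- above_noise & above_floor
  left  <- cbind(M[, 1L], M[, -n_bins, drop = FALSE])
  right <- cbind(M[, -1L, drop = FALSE], M[, n_bins])
  is_peak <- M >= left & M >= right
  eligible <- pass & is_peak

  tol <- cfg$harmonic_tol
  ## harmonic windows per candidate: list over candidates of (harmonic x cols)
  win_cols <- lapply(grid, function(f0) {
    centers <- round(seq_len(cfg$n_harmonics) * f0 / binw) + 1L
    lapply(centers, function(ctr) {
      cols <- (ctr - tol):(ctr + tol)
      cols[cols >= 1L & cols <= n_bins]
    })
  })

  ## per-frame harmonic counts per candidate
  counts <- matrix(0L, n_frames, length(grid))
  present <- vector("list", length(grid))
  for (ci in seq_along(grid)) {
    pres <- matrix(FALSE, n_frames, cfg$n_harmonics)
    for (h in seq_len(cfg$n_harmonics)) {
      cols <- win_cols[[ci]][[h]]
      if (length(cols))
        pres[, h] <- rowSums(eligible[, cols, drop = FALSE]) > 0L
    }
    present[[ci]] <- pres
    counts[, ci] <- rowSums(pres)
  }

  best <- max.col(counts, ties.method = "first")  # lower f0 wins ties
  best_n <- counts[cbind(seq_len(n_frames), best)]
  accepted <- best_n >= cfg$accept_min_harmonics

  frames <- integer(0); bins <- integer(0)
  frame_f0 <- rep(NA_real_, n_frames)
  for (f in which(accepted)) {
    ci <- best[f]
    frame_f0[f] <- grid[ci]
    keep <- integer(0)
    for (h in which(present[[ci]][f, ])) {
      cols <- win_cols[[ci]][[h]]
      keep <- c(keep, cols[pass[f, cols]])
    }
    keep <- unique(keep)
    frames <- c(frames, rep.int(f, length(keep)))
    bins <- c(bins, keep)
  }
  structure(list(frame = frames, bin = bins,
                 magnitude = M[cbind(frames, bins)],
                 frame_f0 = frame_f0,
                 frame_times = spec$frame_times, bin_freqs = spec$bin_freqs,
                 n_frames = n_frames, n_bins = n_bins),
            class = "focused_spectrogram")
}

#' @export
print.focused_spectrogram <- function(x, ...) {
  cat(sprintf("Focused spectrogram: %d retained bins in %d of %d frames\n",
              length(x$frame), length(unique(x$frame)), x$n_frames))
  invisible(x)
}

#' Gaussian affinity matrix over retained time-frequency bins
#'
#' Similarity between retained bins i and j is
#' \code{exp(-(dframe^2 / (2 sigma_t^2) + dbin^2 / (2 sigma_f^2)))}:
#' symmetric, in (0, 1], with unit diagonal.
#'
#' @param focused a \code{"focused_spectrogram"} with at least one retained
#'   bin.
#' @param sigma_t time scale in frames (default 5).
#' @param sigma_f frequency scale in bins (default 2).
#' @return A dense numeric matrix.
#' @export
build_affinity <- function(focused, sigma_t = 5, sigma_f = 2) {
  stopifnot(inherits(focused, "focused_spectrogram"))
  n <- length(focused$frame)
  if (n == 0L)
    stop("nothing to cluster: focused spectrogram has no retained bins",
         call. = FALSE)
  df <- outer(focused$frame, focused$frame, `-`)
  db <- outer(focused$bin, focused$bin, `-`)
  exp(-(df^2 / (2 * sigma_t^2) + db^2 / (2 * sigma_f^2)))
}

## Evaluate an expression with a private, restored RNG stream so detection
## never perturbs a caller's simulation seed.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Spectral clustering of an affinity matrix
#'
#' Standard normalized spectral clustering: k-means on the eigenvectors with
#' the smallest eigenvalues of the symmetric normalized Laplacian
#' \code{I - D^{-1/2} A D^{-1/2}} (rows normalized to unit length before
#' k-means). \code{method = "affinity"} instead takes the eigenvectors of the
#' affinity matrix itself with the smallest eigenvalues -- a literal variant
#' kept for fidelity experiments; it is usually degenerate and not the
#' default.
#'
#' @param affinity symmetric affinity matrix.
#' @param k number of clusters (default 3, allowing several simultaneous
#'   buzzes to land in separate clusters).
#' @param seed integer seed for the k-means restarts; clustering is
#'   deterministic given the seed and does not disturb the global RNG.
#' @param method \code{"laplacian"} (default) or \code{"affinity"}.
#' @param nstart k-means restarts (default 10; best inertia wins).
#' @return Integer cluster labels, one per row of \code{affinity}. When
#'   \code{k >= nrow(affinity)} each point gets its own label (degenerate
#'   case).
#' @export
spectral_cluster <- function(affinity, k = 3L, seed = 0L,
                             method = c("laplacian", "affinity"),
                             nstart = 10L) {
  method <- match.arg(method)
  n <- nrow(affinity)
  stopifnot(n == ncol(affinity), k >= 1L)
  if (k >= n) return(seq_len(n))
  emb <- if (method == "laplacian") {
    d <- rowSums(affinity)
    s <- 1 / sqrt(d)
    L <- diag(n) - (s * affinity) * rep(s, each = n)
    eg <- eigen(L, symmetric = TRUE)
    U <- eg$vectors[, n:(n - k + 1L), drop = FALSE]  # smallest eigenvalues
    len <- sqrt(rowSums(U^2))
    U / pmax(len, .Machine$double.eps)
  } else {
    eg <- eigen(affinity, symmetric = TRUE)
    eg$vectors[, n:(n - k + 1L), drop = FALSE]
  }
  n_distinct <- nrow(unique(round(emb, 10)))
  if (n_distinct < k) {
    ## all points effectively coincide in the embedding (single tight blob):
    ## split deterministically into k balanced groups by row order
    return(as.integer(cut(seq_len(n), breaks = k, labels = FALSE)))
  }
  ## Lloyd iterations avoid Quick-TRANSfer stalls on tight spectral
  ## embeddings; restarts that momentarily lose a center are expected with
  ## heavily duplicated rows, and the best-inertia restart still wins
  km <- with_private_seed(seed, withCallingHandlers(
    stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 100L,
                  algorithm = "Lloyd"),
    warning = function(w) {
      ## ties on duplicated rows can also make Lloyd two-cycle forever;
      ## the returned partition is still valid and deterministic
      if (grepl("empty cluster|Quick-TRANSfer|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  km$cluster
}

## Internal cluster container: member bins of one spectral cluster.
tf_cluster <- function(frames, bins, frame_times = NULL) {
  stopifnot(length(frames) == length(bins))
  structure(list(frame = as.integer(frames), bin = as.integer(bins),
                 frame_times = frame_times,
                 span = if (length(frames)) range(frames) else c(NA, NA)),
            class = "tf_cluster")
}

#' Point density of a time-frequency cluster
#'
#' Number of member time-frequency points divided by the number of frames the
#' cluster spans (first to last member frame, inclusive). A cluster with
#' density >= 1.0 -- at least one harmonic point per spanned frame on average
#' -- is flagged a prospective buzz.
#'
#' @param cluster a cluster (list with integer \code{frame} members, e.g.
#'   built by \code{\link{detect_buzzes}} internals) -- must be non-empty.
#' @return A list with \code{density} and logical \code{prospective}.
#' @export
cluster_density <- function(cluster) {
  if (length(cluster$frame) == 0L)
    stop("density of an empty cluster is undefined", call. = FALSE)
  span <- diff(range(cluster$frame)) + 1L
  d <- length(cluster$frame) / span
  list(density = d, prospective = d >= 1.0)
}

#' Smash a cluster into a one-dimensional time score
#'
#' Member points are summed across frequency into per-frame counts over the
#' cluster's span, then convolved ("same" alignment) with a
#' \code{kernel_len}-element moving-average kernel (entries
#' \code{1/kernel_len}). The peak of this "smashed cluster" vector gates
#' buzz acceptance: a peak >= 1.0 means at least one harmonic point per frame
#' sustained across a 20-frame window, which suppresses sporadic noise
#' clusters.
#'
#' @param cluster a non-empty cluster (as in \code{\link{cluster_density}}).
#' @param kernel_len convolution length in frames (default 20).
#' @return A list with \code{scores} (per spanned frame), \code{peak}, and
#'   logical \code{buzz} (\code{peak >= 1.0}).
#' @export
smash_cluster <- function(cluster, kernel_len = 20L) {
  if (length(cluster$frame) == 0L)
    stop("cannot smash an empty cluster", call. = FALSE)
  span <- range(cluster$frame)
  counts <- tabulate(cluster$frame - span[1L] + 1L,
                     nbins = span[2L] - span[1L] + 1L)
  ## full convolution with the uniform kernel via exact integer moving sums
  ## (an FFT convolution would blur the inclusive >= 1.0 gate with round-off)
  n <- length(counts)
  cs <- c(0L, cumsum(counts))
  p <- seq_len(n + kernel_len - 1L)
  sums <- cs[pmin(n, p) + 1L] - cs[pmax(0L, p - kernel_len) + 1L]
  full <- sums / kernel_len
  off <- (kernel_len - 1L) %/% 2L
  scores <- full[(off + 1L):(off + n)]
  peak <- max(full)  # kernel may overhang a short span; peak over full support
  list(scores = scores, peak = peak, buzz = peak >= 1.0)
}
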