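## Validate / normalize the long per-buzz bee table used by the trait models:
## one row per buzz with bee_id, wing_length, tongue_length, f0.
check_bee_table <- function(bees) {
  need <- c("bee_id", "f0")
  miss <- setdiff(need, names(bees))
  if (length(miss))
    stop("bee table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bees
}

#' Mixed-model regression of characteristic frequency on a trait
#'
#' Fits \code{f0 = b0 + b1 * trait} with a per-bee random intercept by REML
#' (\code{nlme::lme}); per-buzz frequencies are repeated measures on each
#' bee. Reports the marginal r-squared (Nakagawa-Schielzeth): the fraction of
#' variance explained by the fixed effects alone,
#' \code{var(Xb) / (var(Xb) + random-intercept variance + residual
#' variance)}.
#'
#' @param bees data frame with one row per buzz: \code{bee_id}, \code{f0}
#'   (Hz), and the trait column (\code{wing_length} or \code{tongue_length},
#'   mm).
#' @param trait \code{"wing_length"} or \code{"tongue_length"}.
#' @param aggregate \code{"buzz"} (default, repeated measures) or
#'   \code{"bee"} (collapse to per-bee mean frequency first; sensitivity
#'   mode).
#' @return An object of class \code{"trait_fit"}: intercept (Hz), slope
#'   (Hz/mm), variance components, marginal r2, F/df/p for the trait term
#'   (containment denominator df), the trait range, and the underlying
#'   \code{lme} fit.
#' @export
fit_freq_trait <- function(bees, trait = c("wing_length", "tongue_length"),
                           aggregate = c("buzz", "bee")) {
  trait <- match.arg(trait)
  aggregate <- match.arg(aggregate)
  bees <- check_bee_table(bees)
  if (!trait %in% names(bees))
    stop("bee table lacks column: ", trait, call. = FALSE)
  d <- data.frame(bee_id = factor(bees$bee_id), f0 = bees$f0,
                  trait = bees[[trait]])
  d <- d[complete.cases(d), , drop = FALSE]
  if (length(unique(d$bee_id)) < 3L)
    stop("need at least 3 bees", call. = FALSE)
  if (length(unique(d$trait)) < 2L)
    stop("no trait variance: '", trait, "' is constant", call. = FALSE)
  if (aggregate == "bee")
    d <- aggregate(cbind(f0, trait) ~ bee_id, data = d, FUN = mean)

  ## an exactly collinear (noise-free) response breaks the REML optimizer;
  ## in that limit the mixed model degenerates to the ordinary regression
  ols <- stats::lm(f0 ~ trait, data = d)
  if (stats::sigma(ols) < 1e-8 * max(1, stats::sd(d$f0))) {
    an <- suppressWarnings(stats::anova(ols))  # perfect fit is the point here
    return(structure(list(
      trait = trait, aggregate = aggregate,
      intercept = unname(coef(ols)[1L]), slope = unname(coef(ols)[2L]),
      random_intercept_var = 0, residual_var = stats::sigma(ols)^2,
      marginal_r2 = 1,
      F = an["trait", "F value"],
      df = c(num = 1, den = stats::df.residual(ols)),
      p = an["trait", "Pr(>F)"],
      trait_range = range(d$trait),
      n_bees = length(unique(d$bee_id)), n_obs = nrow(d),
      model = ols), class = "trait_fit"))
  }
  fit <- tryCatch(
    nlme::lme(f0 ~ trait, random = ~ 1 | bee_id, data = d, method = "REML"),
    error = function(e)
      nlme::lme(f0 ~ trait, random = ~ 1 | bee_id, data = d,
                method = "REML",
                control = nlme::lmeControl(opt = "optim")))
  beta <- nlme::fixef(fit)
  vc <- nlme::VarCorr(fit)
  tau2 <- as.numeric(vc["(Intercept)", "Variance"])
  sigma2 <- as.numeric(vc["Residual", "Variance"])
  lp <- beta[1L] + beta[2L] * d$trait
  var_f <- stats::var(lp)
  r2m <- var_f / (var_f + tau2 + sigma2)
  an <- nlme::anova.lme(fit, type = "marginal")
  structure(list(
    trait = trait, aggregate = aggregate,
    intercept = unname(beta[1L]), slope = unname(beta[2L]),
    random_intercept_var = tau2, residual_var = sigma2,
    marginal_r2 = r2m,
    F = an["trait", "F-value"],
    df = c(num = an["trait", "numDF"], den = an["trait", "denDF"]),
    p = an["trait", "p-value"],
    trait_range = range(d$trait),
    n_bees = length(unique(d$bee_id)), n_obs = nrow(d),
    model = fit),
    class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("Mixed-model regression: f0 ~ %s (random intercept per bee)\n",
              x$trait))
  cat(sprintf("  f0 = %.1f %+.3f * %s  (Hz, trait in mm)\n",
              x$intercept, x$slope, x$trait))
  cat(sprintf("  marginal r2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$marginal_r2, x$df["num"], x$df["den"], x$F, x$p))
  invisible(x)
}

#' @export
summary.trait_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  variance components: bee %.2f Hz^2, residual %.2f Hz^2\n",
              object$random_intercept_var, object$residual_var))
  cat(sprintf("  %d bees, %d buzzes; trait range %.2f-%.2f mm\n",
              object$n_bees, object$n_obs,
              object$trait_range[1L], object$trait_range[2L]))
  invisible(object)
}

#' @export
coef.trait_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict characteristic frequency from a trait value
#'
#' @param object a \code{"trait_fit"}.
#' @param newdata numeric trait values (mm) or a data frame with the trait
#'   column.
#' @param ... unused.
#' @return Predicted frequencies (Hz) from the fixed effects.
#' @export
predict.trait_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata[[object$trait]] else
    as.numeric(newdata)
  object$intercept + object$slope * x
}

#' @export
plot.trait_fit <- function(x, ...) {
  d <- x$model$data
  plot(d$trait, d$f0, xlab = paste(x$trait, "(mm)"),
       ylab = "Characteristic frequency (Hz)", ...)
  abline(x$intercept, x$slope, col = "red", lwd = 2)
  invisible(x)
}

#' Invert a trait fit: estimate a trait from a frequency
#'
#' The monitoring use of the trait lines: given an observed characteristic
#' frequency, \code{(f0 - intercept) / slope} estimates the trait. Estimates
#' outside the fitted trait range are flagged as extrapolation.
#'
#' @param fit a \code{"trait_fit"}.
#' @param f0 frequencies in Hz.
#' @return Data frame with \code{f0}, \code{trait} (mm), and logical
#'   \code{extrapolated}.
#' @export
predict_trait_from_frequency <- function(fit, f0) {
  stopifnot(inherits(fit, "trait_fit"))
  if (fit$slope == 0)
    stop("trait fit has zero slope: inverse is undefined", call. = FALSE)
  est <- (f0 - fit$intercept) / fit$slope
  data.frame(f0 = f0, trait = est,
             extrapolated = est < fit$trait_range[1L] |
               est > fit$trait_range[2L])
}

#' Tongue-length effect with wing length as covariate (mixed ANCOVA)
#'
#' Tests whether the tongue-length/frequency relationship is an artifact of
#' correlated body size: \code{f0 ~ tongue_length + wing_length} with a
#' per-bee random intercept, type III (marginal) F tests under sum-to-zero
#' conventions.
#'
#' @param bees per-buzz data frame with \code{bee_id}, \code{f0},
#'   \code{wing_length}, \code{tongue_length}.
#' @return Data frame of per-term \code{F}, \code{num_df}, \code{den_df},
#'   \code{p}, with the \code{lme} fit in attribute \code{"model"}.
#' @export
ancova_tongue_with_wing <- function(bees) {
  bees <- check_bee_table(bees)
  d <- data.frame(bee_id = factor(bees$bee_id), f0 = bees$f0,
                  tongue_length = bees$tongue_length,
                  wing_length = bees$wing_length)
  d <- d[complete.cases(d), , drop = FALSE]
  for (v in c("tongue_length", "wing_length"))
    if (length(unique(d[[v]])) < 2L)
      stop("no trait variance: '", v, "' is constant", call. = FALSE)
  if (abs(stats::cor(d$tongue_length, d$wing_length)) > 1 - 1e-10)
    stop("tongue and wing length are exactly collinear: rank-deficient ",
         "design", call. = FALSE)
  fit <- nlme::lme(f0 ~ tongue_length + wing_length, random = ~ 1 | bee_id,
                   data = d, method = "REML")
  an <- nlme::anova.lme(fit, type = "marginal")
  out <- data.frame(term = rownames(an), F = an[, "F-value"],
                    num_df = an[, "numDF"], den_df = an[, "denDF"],
                    p = an[, "p-value"], row.names = NULL)
  attr(out, "model") <- fit
  out
}

#' Weighted mean
#'
#' Sample-size-weighted mean, \code{sum(w * v) / sum(w)}, used to collapse
#' multiple published measurements of one species x caste into one value.
#' Invariant to rescaling all weights by a constant.
#'
#' @param values numeric measurements.
#' @param weights positive weights (sample sizes), same length.
#' @return The weighted mean.
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) == 0L) stop("no values to average", call. = FALSE)
  if (length(weights) != length(values))
    stop("values and weights differ in length", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  stats::weighted.mean(values, weights)
}

#' Collapse literature records to one row per species and caste
#'
#' Where a species x caste combination has several published frequency or
#' tongue-length values, each is replaced by its sample-size-weighted mean.
#'
#' @param entries data frame with \code{species}, \code{caste},
#'   \code{freq_hz}, \code{tongue_mm}, and optional \code{freq_n},
#'   \code{tongue_n} sample sizes (missing sizes count as 1).
#' @return Collapsed data frame, one row per species x caste.
#' @export
collapse_literature <- function(entries) {
  need <- c("species", "caste", "freq_hz", "tongue_mm")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("literature table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fn <- if ("freq_n" %in% names(entries)) entries$freq_n else
    rep(1, nrow(entries))
  tn <- if ("tongue_n" %in% names(entries)) entries$tongue_n else
    rep(1, nrow(entries))
  fn[is.na(fn)] <- 1; tn[is.na(tn)] <- 1
  key <- interaction(entries$species, entries$caste, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    i <- key == k
    data.frame(species = entries$species[i][1L],
               caste = entries$caste[i][1L],
               freq_hz = weighted_mean(entries$freq_hz[i], fn[i]),
               tongue_mm = weighted_mean(entries$tongue_mm[i], tn[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Log-linear literature model of frequency on tongue length
#'
#' Ordinary least squares of \code{log(freq_hz)} on \code{tongue_mm} over the
#' collapsed literature records (frequency distributions across species are
#' skewed, hence the log transform). The back-transformed curve is
#' \code{freq = exp(intercept + rate * tongue)}.
#'
#' @param entries literature data frame (see
#'   \code{\link{collapse_literature}}); collapsing is applied first.
#' @return An object of class \code{"lit_fit"}: \code{intercept} and
#'   \code{rate} on the log scale, \code{r2}, \code{F}, \code{df}, \code{p},
#'   the collapsed data, and the \code{lm} fit.
#' @export
fit_literature_model <- function(entries) {
  d <- collapse_literature(entries)
  if (nrow(d) < 3L)
    stop("need at least 3 collapsed species x caste records", call. = FALSE)
  if (any(d$freq_hz <= 0))
    stop("nonpositive frequency: log transform undefined", call. = FALSE)
  if (length(unique(d$tongue_mm)) < 2L)
    stop("tongue length is constant: rank-deficient design", call. = FALSE)
  fit <- stats::lm(log(freq_hz) ~ tongue_mm, data = d)
  sm <- suppressWarnings(summary(fit))  # noiseless input fits perfectly
  fstat <- sm$fstatistic
  structure(list(
    intercept = unname(coef(fit)[1L]), rate = unname(coef(fit)[2L]),
    r2 = sm$r.squared, F = unname(fstat[1L]),
    df = c(num = unname(fstat[2L]), den = unname(fstat[3L])),
    p = stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
    data = d, model = fit),
    class = "lit_fit")
}

#' @export
print.lit_fit <- function(x, ...) {
  cat("Literature synthesis: log(freq) ~ tongue length (OLS)\n")
  cat(sprintf("  freq = exp(%.3f %+.4f * tongue)  (Hz, tongue in mm)\n",
              x$intercept, x$rate))
  cat(sprintf("  r2 = %.3f, F(%d, %d) = %.2f, p = %.3g; n = %d records\n",
              x$r2, x$df["num"], x$df["den"], x$F, unname(x$p), nrow(x$data)))
  invisible(x)
}

#' @export
coef.lit_fit <- function(object, ...) {
  c(intercept = object$intercept, rate = object$rate)
}

#' @export
predict.lit_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$tongue_mm else as.numeric(newdata)
  exp(object$intercept + object$rate * x)
}
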