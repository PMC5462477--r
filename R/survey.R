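#' Correlation between two per-plot count vectors
#'
#' Pearson correlation with its t-based p-value (\code{df = n - 2}); the
#' one-tailed option tests for a positive relationship, as used when
#' validating automated buzz counts against manual annotations and visual
#' surveys. With only a handful of plots the p-value is flagged low-n.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param tail \code{"one"} (positive association) or \code{"two"}.
#' @return List with \code{r}, \code{df}, \code{p}, \code{tail},
#'   \code{low_n} (fewer than 5 pairs).
#' @export
correlate_counts <- function(x, y, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 plots", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = if (tail == "one") "greater"
                                      else "two.sided")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, tail = tail, low_n = length(x) < 5L)
}

## Collapse raw seed-set records to one mean per plot x species x treatment
## cell (analyses run on plot means).
seedset_cells <- function(records) {
  need <- c("plot_id", "species", "treatment", "seeds")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("seed-set table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(records$seeds < 0))
    stop("seed counts must be nonnegative", call. = FALSE)
  aggregate(seeds ~ plot_id + species + treatment, data = records,
            FUN = mean)
}

#' Pollinator-exclusion t-test on seed set
#'
#' For every plot x species cell, the difference in mean seeds per plant
#' between inflorescences left open to bumble bees and those caged to
#' exclude them; then a one-sample t-test of whether the mean difference
#' exceeds zero (one-tailed, \code{df = cells - 1}). A positive difference
#' measures the bees' pollination service.
#'
#' @param records data frame of seed-set records with \code{plot_id},
#'   \code{species}, \code{treatment} (\code{"open"}/\code{"caged"}), and
#'   \code{seeds} (seeds per plant; multiple rows per cell are averaged
#'   first).
#' @return List with \code{mean_difference}, \code{t}, \code{df}, one-tailed
#'   \code{p}, the per-cell \code{differences}, and \code{low_n} flag.
#' @export
exclusion_ttest <- function(records) {
  cells <- seedset_cells(records)
  wide <- merge(cells[cells$treatment == "open",
                      c("plot_id", "species", "seeds")],
                cells[cells$treatment == "caged",
                      c("plot_id", "species", "seeds")],
                by = c("plot_id", "species"), suffixes = c("_open", "_caged"),
                all = TRUE)
  if (any(is.na(wide$seeds_open)) || any(is.na(wide$seeds_caged)))
    stop("incomplete pairing: some plot x species cell lacks an open or ",
         "caged mean", call. = FALSE)
  diffs <- wide$seeds_open - wide$seeds_caged
  if (stats::sd(diffs) == 0) {
    t <- if (mean(diffs) == 0) 0 else Inf * sign(mean(diffs))
    p <- if (t == 0) 0.5 else if (t > 0) 0 else 1
    return(list(mean_difference = mean(diffs), t = t,
                df = length(diffs) - 1L, p = p, differences = diffs,
                low_n = length(diffs) < 10L))
  }
  tt <- stats::t.test(diffs, mu = 0, alternative = "greater")
  list(mean_difference = mean(diffs), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, differences = diffs,
       low_n = length(diffs) < 10L)
}

#' Seed set as a function of buzz density (ANCOVA)
#'
#' Linear model of plot-mean seeds per plant on acoustic buzz density with
#' plant species as covariate, optionally with the density x species
#' interaction (equal accrual curves across species imply a negligible
#' interaction). Type III tests with sum-to-zero contrasts. Run on the open
#' treatment this asks whether bee activity predicts pollination services;
#' on the caged treatment it is the negative control.
#'
#' @param records seed-set records (see \code{\link{exclusion_ttest}}).
#' @param density named numeric vector of buzz density (buzzes/h) per plot;
#'   names are plot ids (or a data frame with \code{plot_id},
#'   \code{density}).
#' @param treatment which treatment to model (\code{"open"} or
#'   \code{"caged"}).
#' @param interaction include density x species (default \code{FALSE}).
#' @return List with \code{terms} (per-term type III F, df, p),
#'   \code{coefficients}, \code{density_slope}, the fitted \code{lm} in
#'   \code{model}, and \code{low_n} flag.
#' @export
seedset_ancova <- function(records, density,
                           treatment = c("open", "caged"),
                           interaction = FALSE) {
  treatment <- match.arg(treatment)
  cells <- seedset_cells(records)
  cells <- cells[cells$treatment == treatment, , drop = FALSE]
  if (is.data.frame(density))
    density <- stats::setNames(density$density, density$plot_id)
  cells$density <- density[as.character(cells$plot_id)]
  if (any(is.na(cells$density)))
    stop("buzz density missing for some plot", call. = FALSE)
  cells$species <- factor(cells$species)
  form <- if (interaction) seeds ~ density * species else
    seeds ~ density + species
  n_par <- 2L + (nlevels(cells$species) - 1L) * (1L + interaction)
  if (nrow(cells) <= n_par)
    stop("fewer observations (", nrow(cells), ") than model parameters (",
         n_par + 1L, "): rank-deficient fit", call. = FALSE)
  fit <- stats::lm(form, data = cells,
                   contrasts = list(species = "contr.sum"))
  ## an exact (zero-residual) fit leaves the F ratios undefined
  a3 <- tryCatch(car::Anova(fit, type = 3), error = function(e) NULL)
  terms <- if (is.null(a3)) {
    tn <- attr(stats::terms(form), "term.labels")
    data.frame(term = tn, F = NA_real_, num_df = NA_real_,
               den_df = stats::df.residual(fit), p = NA_real_)
  } else {
    keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
    data.frame(term = rownames(a3)[keep],
               F = a3[keep, "F value"],
               num_df = a3[keep, "Df"],
               den_df = stats::df.residual(fit),
               p = a3[keep, "Pr(>F)"], row.names = NULL)
  }
  list(terms = terms, coefficients = coef(fit),
       density_slope = unname(coef(fit)["density"]),
       treatment = treatment, model = fit, low_n = nrow(cells) < 10L)
}
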