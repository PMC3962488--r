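#' Fit the 2+1 pairing model to a vial-structured progeny table
#'
#' The main entry point of the package: estimates the frequencies of the
#' three pairing configurations (L: X-Y1, M: X-Y2, N: Y1-Y2) from scored
#' progeny counts by the method of moments
#' ([estimate_mixture_moments()]) on the pooled class frequencies, with
#' vial-bootstrap percentile intervals when the table has two or more
#' vials.
#'
#' The estimator assumes all six zygote classes are equally viable; the
#' mixture and per-class viabilities are jointly unidentifiable from six
#' frequencies, so no joint fit is attempted. Instead the fit reports the
#' complementary-pair frequency differences (f_X - f_12, f_X1 - f_2,
#' f_X2 - f_1), which are zero in expectation under any mixture with unit
#' viability and therefore diagnose differential viability.
#'
#' @param counts A vial-counts data frame with the six canonical class
#'   columns (see [read_vial_counts()] or [simulate_xyy_vials()]).
#' @param boot Number of bootstrap replicates for the component intervals;
#'   0 (or a single-vial table) disables the bootstrap.
#' @param level Interval level for the bootstrap (default 0.95).
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class `"pairing_fit"` with components `mixture`
#'   (the point estimate), `estimate` (the full `"mixture_estimate"`),
#'   `observed` (pooled class frequencies), `fitted` (model frequencies at
#'   the estimate), `viability_diagnostic`, `summary` (a
#'   [summarize_cross()] result), `counts` and `call`. Supports `print`,
#'   `summary`, `coef`, `confint`, `predict`, `residuals`, `simulate` and
#'   `plot`.
#' @examples
#' tab <- simulate_xyy_vials(pairing_mixture(0.2, 0.3, 0.5),
#'                           design = vial_design(n_vials = 10), seed = 7)
#' fit <- pairing_fit(tab, boot = 200, seed = 7)
#' coef(fit)
#' confint(fit)
#' @export
pairing_fit <- function(counts, boot = 1000, level = 0.95, seed = 1) {
  cls <- .count_columns(counts)
  if (!identical(cls, gamete_classes))
    stop("pairing_fit needs the six-class XYY table", call. = FALSE)
  smry <- summarize_cross(counts)
  observed <- smry$pooled_pct / 100
  est <- if (boot > 0 && nrow(counts) >= 2)
    estimate_mixture_bootstrap(counts, n_boot = boot, level = level,
                               seed = seed)
  else estimate_mixture_moments(observed)
  fitted <- zygote_distribution(est$point)
  diag <- c(`X-12` = observed[["X"]] - observed[["12"]],
            `X1-2` = observed[["X1"]] - observed[["2"]],
            `X2-1` = observed[["X2"]] - observed[["1"]])
  structure(list(mixture = est$point, estimate = est, observed = observed,
                 fitted = fitted, viability_diagnostic = diag,
                 summary = smry, counts = counts, call = match.call()),
            class = "pairing_fit")
}

#' @export
print.pairing_fit <- function(x, digits = 3, ...) {
  cat("2+1 pairing model fit (method of moments, unit viability assumed)\n")
  cat("Call: "); print(x$call)
  cat("\nConfiguration frequencies:\n")
  print(round(unclass(x$mixture), digits))
  if (isTRUE(x$estimate$projected))
    cat("  (raw estimate outside the simplex; projected)\n")
  invisible(x)
}

#' @export
coef.pairing_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$mixture), c("L", "M", "N"))
}

#' @export
confint.pairing_fit <- function(object, parm, level, ...) {
  if (is.null(object$estimate$interval))
    stop("fit has no bootstrap intervals; refit with boot > 0 and >= 2 vials",
         call. = FALSE)
  ci <- object$estimate$interval
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.pairing_fit <- function(object, ...) object$fitted

#' Residual class frequencies of a pairing fit
#'
#' Observed minus fitted pooled class frequencies (proportions). Large
#' residuals concentrated on one member of a complementary pair indicate
#' differential zygote viability rather than pairing bias.
#' @param object A [pairing_fit()] object.
#' @param ... Unused.
#' @export
residuals.pairing_fit <- function(object, ...) {
  object$observed - object$fitted
}

#' @export
summary.pairing_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.pairing_fit")
}

#' @export
print.summary.pairing_fit <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$estimate$interval)) {
    cat(sprintf("\n%g%% bootstrap percentile intervals (%d replicates):\n",
                100 * f$estimate$level, f$estimate$n_boot))
    print(round(f$estimate$interval, digits))
  }
  cat("\nObserved vs fitted class frequencies:\n")
  print(round(rbind(observed = f$observed, fitted = f$fitted,
                    residual = f$observed - f$fitted), digits))
  cat("\nComplementary-pair differences (viability diagnostic; ~0 under",
      "unit viability):\n")
  print(round(f$viability_diagnostic, digits))
  cat(sprintf("\n%d vials, %d flies; %%female %.1f, %%aneuploid %.1f\n",
              f$summary$n_vials, f$summary$n_flies,
              f$summary$percent_female, f$summary$percent_aneuploid))
  invisible(x)
}

#' Simulate progeny tables from a fitted pairing model
#'
#' Draws new vial-count tables at the fitted mixture, reusing the observed
#' design (number of vials, mean and SD of vial sizes).
#'
#' @param object A [pairing_fit()] object.
#' @param nsim Number of tables to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` vial-counts data frames.
#' @export
simulate.pairing_fit <- function(object, nsim = 1, seed = 1, ...) {
  s <- object$summary
  design <- vial_design(
    n_vials = s$n_vials,
    mean_vial_size = s$mean_flies_per_vial,
    size_dispersion = if (is.na(s$sd_flies_per_vial)) 0 else s$sd_flies_per_vial
  )
  lapply(seq_len(nsim), function(i)
    simulate_xyy_vials(object$mixture, design = design, seed = seed + i - 1))
}

#' @export
plot.pairing_fit <- function(x, ...) {
  h <- rbind(observed = 100 * x$observed, fitted = 100 * x$fitted)
  graphics::barplot(h, beside = TRUE, legend.text = rownames(h),
                    ylab = "class frequency (%)",
                    xlab = "progeny class", ...)
  invisible(x)
}
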