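.control_classes <- c("normal_female", "exceptional_female",
                      "exceptional_male", "normal_male")

.count_columns <- function(counts) {
  if (all(gamete_classes %in% names(counts))) gamete_classes
  else if (all(.control_classes %in% names(counts))) .control_classes
  else stop("count table must carry the six canonical XYY class columns (",
            paste(gamete_classes, collapse = ", "),
            ") or the four control-cross columns", call. = FALSE)
}

#' Summarize a progeny-count table
#'
#' Computes the standard cross summary from a vial-structured count table:
#' pooled class frequencies from the summed counts (integer arithmetic,
#' never an average of ratios), per-vial mean and SD of the class
#' frequencies treating each vial as an independent subpopulation
#' (`n - 1` denominator), the sex ratio, and the aneuploid fraction.
#'
#' For six-class XYY tables, females come from X-bearing sperm (classes X,
#' X1, X2) and aneuploids are the XXY females plus XYY males (classes X1,
#' X2 and 12). For four-class control tables, aneuploids are the
#' exceptional females plus exceptional males.
#'
#' @param counts A data frame of per-vial counts: either the six canonical
#'   XYY class columns or the four control-cross columns
#'   (`normal_female`, `exceptional_female`, `exceptional_male`,
#'   `normal_male`).
#' @return A list of class `"cross_summary"`: `pooled_pct` (named class
#'   frequencies, %), `vial_mean_pct`, `vial_sd_pct` (NA-filled and flagged
#'   via `sd_defined = FALSE` for a single vial), `percent_female`,
#'   `percent_aneuploid`, `n_vials`, `n_flies`, `mean_flies_per_vial`,
#'   `sd_flies_per_vial`.
#' @examples
#' tab <- data.frame(normal_female = 2228, exceptional_female = 9,
#'                   exceptional_male = 10, normal_male = 1944)
#' summarize_cross(tab)  # 53.4% female, 0.5% aneuploid
#' @export
summarize_cross <- function(counts) {
  cls <- .count_columns(counts)
  if (nrow(counts) < 1L) stop("empty count table", call. = FALSE)
  m <- as.matrix(counts[, cls, drop = FALSE])
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers", call. = FALSE)
  pooled <- colSums(m)
  total <- sum(pooled)
  if (total == 0) stop("no flies in table", call. = FALSE)
  freq <- sweep(m, 1, rowSums(m), "/")
  n_vials <- nrow(m)
  female_cls <- if (identical(cls, gamete_classes)) c("X", "X1", "X2")
                else c("normal_female", "exceptional_female")
  aneu_cls <- if (identical(cls, gamete_classes)) c("X1", "X2", "12")
              else c("exceptional_female", "exceptional_male")
  structure(list(
    classes = cls,
    pooled_pct = 100 * pooled / total,
    vial_mean_pct = 100 * colMeans(freq),
    vial_sd_pct = if (n_vials >= 2) 100 * apply(freq, 2, stats::sd)
                  else stats::setNames(rep(NA_real_, length(cls)), cls),
    sd_defined = n_vials >= 2,
    percent_female = 100 * sum(pooled[female_cls]) / total,
    percent_aneuploid = 100 * sum(pooled[aneu_cls]) / total,
    n_vials = n_vials,
    n_flies = total,
    mean_flies_per_vial = mean(rowSums(m)),
    sd_flies_per_vial = if (n_vials >= 2) stats::sd(rowSums(m)) else NA_real_
  ), class = "cross_summary")
}

#' @export
print.cross_summary <- function(x, digits = 1, ...) {
  cat(sprintf("Cross summary: %d flies in %d vial(s)\n", x$n_flies, x$n_vials))
  cat(sprintf("  %% female: %.1f   %% aneuploid: %.1f\n",
              x$percent_female, x$percent_aneuploid))
  tab <- rbind(pooled = x$pooled_pct, `vial mean` = x$vial_mean_pct,
               `vial SD` = x$vial_sd_pct)
  print(round(tab, digits), ...)
  invisible(x)
}

#' Method-of-moments estimate of the pairing mixture
#'
#' Inverts the linear map from (pL, pM, pN) to the six expected class
#' frequencies under unit viability: each configuration suppresses one
#' complementary class pair, so
#' \eqn{p_L = 1 - 2(f_{X1} + f_2)}, \eqn{p_M = 1 - 2(f_{X2} + f_1)},
#' \eqn{p_N = 1 - 2(f_X + f_{12})}. Sampling noise (or differential
#' viability, which this estimator assumes absent) can push components
#' outside [0, 1]; such estimates are clipped to the simplex and flagged.
#'
#' @param freqs Six class frequencies (proportions) in canonical order or
#'   named by the canonical labels; must sum to 1 within `1e-6`.
#' @return A list of class `"mixture_estimate"`: `point` (a
#'   [pairing_mixture()]), `raw` (the unprojected solution), `projected`
#'   (logical), `method = "moments"`, and `assumes_unit_viability = TRUE`.
#' @examples
#' estimate_mixture_moments(rep(1/6, 6))                  # (1/3, 1/3, 1/3)
#' f <- zygote_distribution(pairing_mixture(0.5, 0.3, 0.2))
#' estimate_mixture_moments(f)$point                      # exact round trip
#' @export
estimate_mixture_moments <- function(freqs) {
  if (!is.null(names(freqs))) {
    if (!setequal(names(freqs), gamete_classes))
      stop("frequency names must be the six canonical class labels",
           call. = FALSE)
    freqs <- freqs[gamete_classes]
  }
  freqs <- as.numeric(freqs)
  if (length(freqs) != 6L || anyNA(freqs) || any(freqs < 0))
    stop("need six nonnegative class frequencies", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("class frequencies must sum to 1 (got ", format(sum(freqs)), ")",
         call. = FALSE)
  f <- stats::setNames(freqs, gamete_classes)
  raw <- c(L = 1 - 2 * (f[["X1"]] + f[["2"]]),
           M = 1 - 2 * (f[["X2"]] + f[["1"]]),
           N = 1 - 2 * (f[["X"]] + f[["12"]]))
  projected <- any(raw < 0) || any(raw > 1)
  p <- pmax(raw, 0)
  p <- p / sum(p)
  structure(list(point = pairing_mixture(p), raw = raw,
                 projected = projected, method = "moments",
                 assumes_unit_viability = TRUE),
            class = "mixture_estimate")
}

#' Vial-bootstrap confidence intervals for the pairing mixture
#'
#' Resamples vials with replacement, recomputes the pooled class
#' frequencies and the moments estimate, and reports percentile intervals
#' per mixture component.
#'
#' @param counts Vial-counts data frame with the six canonical class
#'   columns and at least two vials.
#' @param n_boot Bootstrap replicates (a warning below 100).
#' @param level Two-sided interval level (default 0.95).
#' @param seed Integer seed.
#' @return A `"mixture_estimate"` as from [estimate_mixture_moments()],
#'   with an `interval` matrix (rows L, M, N; columns `lower`, `upper`),
#'   `level`, `n_boot` and `method = "bootstrap"`.
#' @export
estimate_mixture_bootstrap <- function(counts, n_boot = 1000, level = 0.95,
                                       seed) {
  cls <- .count_columns(counts)
  if (!identical(cls, gamete_classes))
    stop("mixture estimation needs the six-class XYY table", call. = FALSE)
  m <- as.matrix(counts[, gamete_classes, drop = FALSE])
  if (nrow(m) < 2L)
    stop("bootstrap needs at least two vials", call. = FALSE)
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  point <- estimate_mixture_moments(colSums(m) / sum(m))
  set.seed(.substream(seed, "bootstrap"))
  draws <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(m), replace = TRUE)
    pooled <- colSums(m[idx, , drop = FALSE])
    as.numeric(estimate_mixture_moments(pooled / sum(pooled))$point)
  }, numeric(3))
  alpha <- 1 - level
  interval <- t(apply(draws, 1, stats::quantile,
                      probs = c(alpha / 2, 1 - alpha / 2), names = FALSE))
  dimnames(interval) <- list(c("L", "M", "N"), c("lower", "upper"))
  point$interval <- interval
  point$level <- level
  point$n_boot <- n_boot
  point$method <- "bootstrap"
  point
}

#' @export
print.mixture_estimate <- function(x, digits = 3, ...) {
  cat("Pairing-configuration mixture estimate (", x$method, ")\n", sep = "")
  cat("  assumes unit viability of all six zygote classes\n")
  est <- round(unclass(x$point), digits)
  if (!is.null(x$interval)) {
    tab <- cbind(estimate = est, round(x$interval, digits))
    print(tab, ...)
    cat(sprintf("  %g%% percentile intervals from %d vial bootstraps\n",
                100 * x$level, x$n_boot))
  } else {
    print(est, ...)
  }
  if (isTRUE(x$projected))
    cat("  note: raw solution fell outside the simplex and was projected\n")
  invisible(x)
}

#' Nondisjunction rate with exact binomial interval
#'
#' The exceptional-progeny rate of a control cross, as a percentage, with a
#' Clopper-Pearson 95% interval.
#'
#' @param exceptional Number of exceptional progeny, or a one-row four-class
#'   control-cross data frame.
#' @param total Total progeny (ignored when a data frame is given).
#' @param level Interval level (default 0.95).
#' @return List with `rate_pct`, `lower_pct`, `upper_pct`, `exceptional`,
#'   `total`, `level`.
#' @examples
#' nondisjunction_rate(5, 8220)   # 0.06%
#' @export
nondisjunction_rate <- function(exceptional, total = NULL, level = 0.95) {
  if (is.data.frame(exceptional)) {
    cls <- .count_columns(exceptional)
    if (!identical(cls, .control_classes))
      stop("expected a four-class control-cross table", call. = FALSE)
    sums <- colSums(exceptional[, cls])
    total <- sum(sums)
    exceptional <- sums[["exceptional_female"]] + sums[["exceptional_male"]]
  }
  if (is.null(total) || total <= 0) stop("total must be positive", call. = FALSE)
  ci <- stats::binom.test(exceptional, total, conf.level = level)$conf.int
  list(rate_pct = 100 * exceptional / total,
       lower_pct = 100 * ci[1], upper_pct = 100 * ci[2],
       exceptional = exceptional, total = total, level = level)
}

#' Correlation of complementary class frequencies across vials
#'
#' Each pairing configuration produces two complementary sperm classes in
#' equal expected frequency (X with 12, X1 with 2, X2 with 1). If the
#' between-vial spread were driven by vial-to-vial variation in the pairing
#' mixture, complementary classes would co-vary positively; under pure
#' multinomial sampling with fixed probabilities their frequencies are
#' instead weakly negatively correlated (Cov(f_i, f_j) = -p_i p_j / n).
#'
#' @param counts Vial-counts data frame with the six canonical columns and
#'   at least three vials.
#' @return Named numeric vector of the three product-moment correlations
#'   (`X:12`, `X1:2`, `X2:1`); a pair with zero variance in either member
#'   is returned as `NA` with attribute `undefined` naming it.
#' @export
complementary_covariance <- function(counts) {
  cls <- .count_columns(counts)
  if (!identical(cls, gamete_classes))
    stop("complementary pairs are defined for the six-class table",
         call. = FALSE)
  m <- as.matrix(counts[, gamete_classes, drop = FALSE])
  if (nrow(m) < 3L) stop("need at least three vials", call. = FALSE)
  freq <- sweep(m, 1, rowSums(m), "/")
  pairs <- list(`X:12` = c("X", "12"), `X1:2` = c("X1", "2"),
                `X2:1` = c("X2", "1"))
  out <- vapply(pairs, function(pr) {
    a <- freq[, pr[1]]; b <- freq[, pr[2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
  }, numeric(1))
  undef <- names(out)[is.na(out)]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}
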