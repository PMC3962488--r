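#' Summary statistics of one group of vials
#'
#' @param mean,sd Mean and SD of a class frequency across vials (any
#'   consistent unit; percent or proportion).
#' @param n Number of vials (>= 2 for interval computation).
#' @return List of class `"group_stats"`.
#' @export
group_stats <- function(mean, sd, n) {
  stopifnot(sd >= 0, n >= 1)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_stats")
}

#' Interval for a difference of group means
#'
#' The noninformative-prior posterior interval for the difference of two
#' normal means with unequal variances, computed as the Welch t interval
#' (Behrens-Fisher approximation): center `mean_a - mean_b`, scale
#' `sqrt(sd_a^2/n_a + sd_b^2/n_b)`, Welch-Satterthwaite degrees of freedom,
#' two-sided at the stated level. A level of 0.975 therefore uses the
#' 0.9875 t quantile. Exclusion of zero from the interval is the
#' significance criterion.
#'
#' @param a,b [group_stats()] objects (or lists with `mean`, `sd`, `n`).
#' @param level Two-sided interval level (default 0.975).
#' @return List of class `"interval_estimate"`: `center`, `lower`, `upper`,
#'   `level`, `df`, `excludes_zero`.
#' @examples
#' diff_mean_interval(group_stats(0.218, 0.015, 3),
#'                    group_stats(0.161, 0.016, 3))
#' @export
diff_mean_interval <- function(a, b, level = 0.975) {
  stopifnot(level > 0, level < 1)
  if (a$n < 2 || b$n < 2)
    stop("interval computation needs n >= 2 in both groups", call. = FALSE)
  center <- a$mean - b$mean
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  scale <- sqrt(va + vb)
  if (scale == 0) {
    # degenerate: no spread; the interval collapses onto the center
    out <- list(center = center, lower = center, upper = center,
                level = level, df = Inf, excludes_zero = center != 0)
    return(structure(out, class = "interval_estimate"))
  }
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  q <- stats::qt(1 - (1 - level) / 2, df)
  lower <- center - q * scale
  upper <- center + q * scale
  structure(list(center = center, lower = lower, upper = upper,
                 level = level, df = df,
                 excludes_zero = lower > 0 || upper < 0),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%g%% interval for difference of means: [%.*f, %.*f]\n",
              100 * x$level, digits, x$lower, digits, x$upper))
  cat(sprintf("  center %.*f, Welch df %.2f, excludes zero: %s\n",
              digits, x$center, x$df, x$excludes_zero))
  invisible(x)
}

#' Pairwise scan of replicate and transfer-time subsets
#'
#' Runs [diff_mean_interval()] for every within-partition pair of subsets:
#' the three sire-replicate pairs (vials 1/2/3) and the three transfer-time
#' pairs (vials 0.1/0.2/0.3), for each progeny class and each chromosome
#' set, and reports which comparisons exclude zero. With two chromosome
#' sets and six classes this is 72 comparisons; no multiple-testing
#' correction is applied (none is part of the analysis).
#'
#' @param table3 Long-format data frame with columns `y1`, `y2`, `subset`,
#'   `n`, `class`, `mean`, `sd`, as returned by
#'   `xyy_fixture("table3")`. The pooled `"123"` rows are ignored.
#' @param level Interval level (default 0.975).
#' @return A list with `n_significant`, `significant` (data frame of the
#'   flagged comparisons) and `results` (all comparisons with center,
#'   bounds and flags).
#' @examples
#' scan <- pairwise_subset_scan(xyy_fixture("table3"))
#' scan$n_significant   # 1
#' @export
pairwise_subset_scan <- function(table3, level = 0.975) {
  needed <- c("y1", "y2", "subset", "n", "class", "mean", "sd")
  if (!all(needed %in% names(table3)))
    stop("table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  partitions <- list(sire = c("1", "2", "3"), time = c("0.1", "0.2", "0.3"))
  sets <- unique(table3[, c("y1", "y2")])
  classes <- unique(table3$class)
  rows <- list()
  for (s in seq_len(nrow(sets))) {
    sub <- table3[table3$y1 == sets$y1[s] & table3$y2 == sets$y2[s], ]
    for (cl in classes) {
      cl_rows <- sub[sub$class == cl, ]
      for (part in names(partitions)) {
        members <- partitions[[part]]
        cells <- cl_rows[match(members, cl_rows$subset), ]
        if (anyNA(cells$mean))
          stop("missing cell: set ", sets$y1[s], "/", sets$y2[s],
               ", class ", cl, ", partition ", part, call. = FALSE)
        pair_idx <- utils::combn(3, 2)
        for (k in seq_len(ncol(pair_idx))) {
          i <- pair_idx[1, k]; j <- pair_idx[2, k]
          iv <- diff_mean_interval(
            group_stats(cells$mean[i], cells$sd[i], cells$n[i]),
            group_stats(cells$mean[j], cells$sd[j], cells$n[j]),
            level = level)
          rows[[length(rows) + 1L]] <- data.frame(
            y1 = sets$y1[s], y2 = sets$y2[s], class = cl,
            partition = part,
            subset_a = members[i], subset_b = members[j],
            center = iv$center, lower = iv$lower, upper = iv$upper,
            excludes_zero = iv$excludes_zero)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  sig <- results[results$excludes_zero, , drop = FALSE]
  list(n_significant = nrow(sig), significant = sig, results = results)
}

#' Ordinary least-squares regression of class frequency on copy number
#'
#' Fits frequency = intercept + slope * copy number by least squares and
#' reports the squared product-moment correlation, mirroring the
#' spreadsheet SLOPE/INTERCEPT/CORREL workflow used for this analysis.
#'
#' @param rdna_fraction Relative rDNA copy numbers (%), the abscissa.
#' @param frequency Class frequencies (%), the ordinate.
#' @return List of class `"frequency_regression"`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @examples
#' frequency_regression(c(46, 55, 76, 100), c(1, 1.2, 1.4, 2))
#' @export
frequency_regression <- function(rdna_fraction, frequency) {
  x <- as.numeric(rdna_fraction); y <- as.numeric(frequency)
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least three (copy number, frequency) pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("copy number (abscissa) is constant; slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(x)),
            class = "frequency_regression")
}

#' @export
print.frequency_regression <- function(x, digits = 4, ...) {
  cat(sprintf("y = %.*f x + %.*f   (R^2 = %.3f, n = %d)\n",
              digits, x$slope, digits, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Vials per group needed to distinguish two class frequencies
#'
#' The detectability criterion used for the power analysis: the number of
#' vials per group at which the two-sided t test at level `alpha` (with a
#' fixed, large df for the quantile) would just separate the two group
#' means given their SDs,
#' \deqn{n = \lceil t^2_{1-\alpha/2, df} (sd_a^2 + sd_b^2) /
#'       (mean_a - mean_b)^2 \rceil.}
#' Separate variances are summed (Welch-style); there is no power term
#' beyond the alpha threshold.
#'
#' @param a,b [group_stats()] objects (the `n` fields are not used) or
#'   lists with `mean` and `sd`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param df Degrees of freedom for the t quantile (default 1000,
#'   effectively normal).
#' @return Integer number of vials per group.
#' @examples
#' required_sample_size(group_stats(17.8, 6.8, 32),
#'                      group_stats(16.0, 5.6, 25))   # ~90 vials
#' @export
required_sample_size <- function(a, b, alpha = 0.05, df = 1000) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  delta <- a$mean - b$mean
  if (delta == 0)
    stop("group means are equal; required sample size is unbounded",
         call. = FALSE)
  q <- stats::qt(1 - alpha / 2, df)
  n <- ceiling(q^2 * (a$sd^2 + b$sd^2) / delta^2)
  max(1L, as.integer(n))
}
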