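#' Replicate threshold-cycle set for one sample
#'
#' Paired Ct values — rDNA target amplicon and multicopy tRNA normalizer —
#' from replicate qPCR reactions on one DNA sample.
#'
#' @param ct_target,ct_normalizer Numeric vectors of equal length, positive
#'   threshold cycles.
#' @param label Sample label.
#' @return List of class `"ct_replicates"` with a `delta_ct` component
#'   (target minus normalizer, per replicate). A warning is raised below
#'   three replicates (the assay runs triplicate or more).
#' @export
ct_replicates <- function(ct_target, ct_normalizer, label = "sample") {
  if (length(ct_target) != length(ct_normalizer) || length(ct_target) == 0)
    stop("need equal, nonzero numbers of target and normalizer Cts",
         call. = FALSE)
  if (any(ct_target <= 0) || any(ct_normalizer <= 0))
    stop("Ct values must be positive", call. = FALSE)
  if (length(ct_target) < 3)
    warning("fewer than 3 replicates for sample '", label, "'")
  structure(list(label = label, ct_target = ct_target,
                 ct_normalizer = ct_normalizer,
                 delta_ct = ct_target - ct_normalizer),
            class = "ct_replicates")
}

.as_ct_replicates <- function(x, which = NULL) {
  if (inherits(x, "ct_replicates")) return(x)
  if (is.data.frame(x)) {
    if (!is.null(which) && "sample" %in% names(x))
      x <- x[x$sample == which, ]
    return(ct_replicates(x$ct_target, x$ct_normalizer,
                         label = if (is.null(which)) "sample" else which))
  }
  stop("expected a ct_replicates object or a Ct data frame", call. = FALSE)
}

#' Pool two standard errors
#'
#' Root-sum-of-squares pooling, used to fold the reference sample's
#' replicate SEM into each measurement's SEM on the delta-Ct scale.
#'
#' @param sample_sem,reference_sem Nonnegative standard errors (same scale).
#' @return `sqrt(sample_sem^2 + reference_sem^2)`.
#' @examples
#' pool_sem(3, 4)  # 5
#' @export
pool_sem <- function(sample_sem, reference_sem) {
  stopifnot(sample_sem >= 0, reference_sem >= 0)
  sqrt(sample_sem^2 + reference_sem^2)
}

#' Relative rDNA copy number by delta-delta-Ct
#'
#' For each replicate, delta-Ct = Ct(target) - Ct(normalizer); the
#' delta-delta-Ct is the difference of the sample and reference mean
#' delta-Cts, and the relative copy number is `2^(-ddCt) * 100%`
#' (amplification efficiency taken as 100%). The SEM is the
#' root-sum-of-squares pool of both replicate-set SEMs on the delta-Ct
#' scale, transferred to the percent scale by the delta method
#' (`ln 2 * fraction * sem_ddct`). A constant added to every Ct (a plate
#' offset) cancels exactly.
#'
#' @param sample,reference [ct_replicates()] objects, or the long-format
#'   data frame from [simulate_qpcr()] (in which case `reference` may be
#'   omitted and both sets are extracted from its `sample` column).
#' @return List of class `"copy_number_measurement"`: `relative_pct`,
#'   `sem_pct`, `ddct`, `sem_ddct`, `n_replicates` (sample replicates).
#' @examples
#' cts <- simulate_qpcr(true_fraction = 0.46, ct_noise_sd = 0.2,
#'                      n_replicates = 11, seed = 3)
#' relative_copy_number(cts)   # close to 46%
#' @export
relative_copy_number <- function(sample, reference = NULL) {
  if (is.data.frame(sample) && is.null(reference)) {
    reference <- .as_ct_replicates(sample, "reference")
    sample <- .as_ct_replicates(sample, "sample")
  } else {
    sample <- .as_ct_replicates(sample)
    reference <- .as_ct_replicates(reference)
  }
  mean_dct_s <- mean(sample$delta_ct)
  mean_dct_r <- mean(reference$delta_ct)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  ddct <- mean_dct_s - mean_dct_r
  sem_ddct <- pool_sem(sem(sample$delta_ct), sem(reference$delta_ct))
  fraction_pct <- 100 * 2^(-ddct)
  structure(list(relative_pct = fraction_pct,
                 sem_pct = log(2) * fraction_pct * sem_ddct,
                 ddct = ddct, sem_ddct = sem_ddct,
                 n_replicates = length(sample$delta_ct)),
            class = "copy_number_measurement")
}

#' @export
print.copy_number_measurement <- function(x, ...) {
  cat(sprintf("Relative rDNA copy number: %.1f%% (pooled SEM %.1f%%, n = %d)\n",
              x$relative_pct, x$sem_pct, x$n_replicates))
  invisible(x)
}

#' Read a long-format Ct table
#'
#' Expects columns `sample`, `replicate`, `amplicon` (values `"target"`
#' and `"normalizer"`) and `ct`, and reshapes to the wide per-replicate
#' layout consumed by [relative_copy_number()].
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return Data frame with columns `sample`, `replicate`, `ct_target`,
#'   `ct_normalizer`.
#' @export
read_ct_table <- function(path) {
  tab <- .read_delim(path)
  needed <- c("sample", "replicate", "amplicon", "ct")
  if (!all(needed %in% names(tab)))
    stop("Ct table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$amplicon), c("target", "normalizer"))
  if (length(bad))
    stop("unknown amplicon label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  wide <- stats::reshape(tab, direction = "wide",
                         idvar = c("sample", "replicate"),
                         timevar = "amplicon", v.names = "ct")
  names(wide)[names(wide) == "ct.target"] <- "ct_target"
  names(wide)[names(wide) == "ct.normalizer"] <- "ct_normalizer"
  rownames(wide) <- NULL
  wide
}
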