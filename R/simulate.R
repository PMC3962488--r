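# Deterministic substream seeds: one global seed, per-generator offsets, so
# that e.g. vial-size draws do not shift the class-count stream.
.substream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2011L + h %% 100003L
}

#' Experimental design of a vial-structured cross
#'
#' Describes how progeny counts are spread over replicate vials: the number
#' of vials, the mean and spread of flies per vial, and an optional
#' between-vial overdispersion of the class frequencies.
#'
#' @param n_vials Number of replicate vials (>= 1).
#' @param mean_vial_size Mean flies per vial. Default 105, a typical vial of
#'   these crosses.
#' @param size_dispersion SD of flies per vial. Sizes are drawn from a
#'   negative-binomial-shaped integer distribution matching this mean and SD
#'   (vials are overdispersed relative to Poisson); values at or below the
#'   Poisson SD fall back to Poisson. Default 44.
#' @param overdispersion_concentration Either `"none"` (pure multinomial
#'   counts within each vial) or a positive Dirichlet concentration
#'   \eqn{\kappa}: each vial's class probabilities are drawn from a
#'   Dirichlet with mean equal to the model distribution and concentration
#'   \eqn{\kappa}, so the between-vial variance of a class frequency is
#'   \eqn{p(1-p)(n+\kappa)/(n(1+\kappa))} for vial size \eqn{n}. Smaller
#'   \eqn{\kappa} means more spread.
#' @return A list of class `"vial_design"`.
#' @export
vial_design <- function(n_vials = 32, mean_vial_size = 105,
                        size_dispersion = 44,
                        overdispersion_concentration = "none") {
  stopifnot(n_vials >= 1, mean_vial_size >= 1, size_dispersion >= 0)
  od <- overdispersion_concentration
  if (!(identical(od, "none") || (is.numeric(od) && od > 0)))
    stop("overdispersion_concentration must be 'none' or a positive number",
         call. = FALSE)
  structure(list(n_vials = as.integer(n_vials),
                 mean_vial_size = mean_vial_size,
                 size_dispersion = size_dispersion,
                 overdispersion_concentration = od),
            class = "vial_design")
}

.draw_vial_sizes <- function(n, mu, sigma) {
  draw <- if (sigma^2 > mu) {
    size <- mu^2 / (sigma^2 - mu)  # NB: var = mu + mu^2/size
    function(k) stats::rnbinom(k, size = size, mu = mu)
  } else {
    function(k) stats::rpois(k, mu)
  }
  sizes <- draw(n)
  while (any(sizes == 0L)) {                      # empty vials are redrawn
    zero <- sizes == 0L
    sizes[zero] <- draw(sum(zero))
  }
  sizes
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate vial-structured progeny counts from an XYY cross
#'
#' The generative twin of the scored-cross tables: per-vial multinomial
#' counts over the six progeny classes, with class probabilities given by
#' [zygote_distribution()] and, optionally, Dirichlet between-vial
#' overdispersion.
#'
#' @param mixture A [pairing_mixture()].
#' @param viability A [viability_vector()].
#' @param design A [vial_design()].
#' @param seed Integer seed; the same seed reproduces the table bit for bit.
#' @param y1,y2 Chromosome identity labels recorded in the metadata columns.
#' @param rdna_fraction Relative rDNA copy number (%) of Y2, metadata only.
#' @return A vial-counts data frame: one row per vial, the six canonical
#'   class-count columns, and metadata columns `y1`, `y2`, `rdna_fraction`,
#'   `sire_id`, `transfer_index`.
#' @examples
#' simulate_xyy_vials(pairing_mixture(1/3, 1/3, 1/3),
#'                    design = vial_design(n_vials = 4), seed = 1)
#' @export
simulate_xyy_vials <- function(mixture, viability = viability_vector(),
                               design = vial_design(), seed,
                               y1 = "B", y2 = "10B", rdna_fraction = 100) {
  stopifnot(inherits(design, "vial_design"))
  p <- zygote_distribution(mixture, viability)
  set.seed(.substream(seed, "xyy_vials"))
  sizes <- .draw_vial_sizes(design$n_vials, design$mean_vial_size,
                            design$size_dispersion)
  kappa <- design$overdispersion_concentration
  counts <- t(vapply(sizes, function(n) {
    pv <- if (identical(kappa, "none")) p else .rdirichlet(kappa * p)
    as.integer(stats::rmultinom(1, n, pv))
  }, integer(6)))
  colnames(counts) <- gamete_classes
  out <- data.frame(counts, check.names = FALSE)
  out$y1 <- y1
  out$y2 <- y2
  out$rdna_fraction <- rdna_fraction
  out$sire_id <- seq_len(design$n_vials)
  out$transfer_index <- 1L
  out
}

#' Simulate a four-class control cross
#'
#' XX females by XY males: progeny are normal females, exceptional (XXY)
#' females, exceptional (X0-like) males and normal males. Exceptional flies
#' arise binomially at the given nondisjunction/loss rate and are split
#' evenly between the sexes (the assay cannot distinguish loss from
#' nondisjunction, so neither does the simulator); normal flies split 1:1.
#'
#' @param ndj_rate Per-fly probability of an exceptional progeny class.
#' @param n_total Total progeny scored.
#' @param seed Integer seed.
#' @return One-row data frame with columns `normal_female`,
#'   `exceptional_female`, `exceptional_male`, `normal_male`.
#' @examples
#' simulate_control_cross(ndj_rate = 0.005, n_total = 5000, seed = 1)
#' @export
simulate_control_cross <- function(ndj_rate, n_total, seed) {
  stopifnot(ndj_rate >= 0, ndj_rate <= 1, n_total >= 0)
  set.seed(.substream(seed, "control_cross"))
  n_exc <- stats::rbinom(1, n_total, ndj_rate)
  exc_f <- stats::rbinom(1, n_exc, 0.5)
  n_norm <- n_total - n_exc
  norm_f <- stats::rbinom(1, n_norm, 0.5)
  data.frame(normal_female = norm_f,
             exceptional_female = exc_f,
             exceptional_male = n_exc - exc_f,
             normal_male = n_norm - norm_f)
}

#' Simulate replicate qPCR threshold cycles
#'
#' Generates replicate Ct pairs (rDNA target, multicopy tRNA normalizer) for
#' a sample of relative rDNA abundance `true_fraction` and for the reference
#' genotype (abundance 1). Ct values follow
#' \eqn{Ct = b - \log(\mathrm{template})/\log(1+E)} plus Gaussian cycle
#' noise, with efficiency \eqn{E} shared by both amplicons; at \eqn{E = 1}
#' each template doubling lowers Ct by one cycle.
#'
#' @param true_fraction Relative rDNA copy number of the sample
#'   (1 = reference).
#' @param amplification_efficiency Per-cycle efficiency in (0, 1].
#' @param ct_noise_sd SD of the Gaussian cycle noise.
#' @param n_replicates Replicates per sample (the assay runs triplicates or
#'   more; fewer than 3 draws a warning downstream, not here).
#' @param seed Integer seed.
#' @param baseline_target,baseline_normalizer Reference-template Ct
#'   baselines (cycles); they cancel in the delta-delta-Ct analysis.
#' @return Long-format data frame with columns `sample`
#'   (`"sample"`/`"reference"`), `replicate`, `ct_target`, `ct_normalizer`.
#' @examples
#' simulate_qpcr(true_fraction = 0.46, ct_noise_sd = 0.2,
#'               n_replicates = 5, seed = 1)
#' @export
simulate_qpcr <- function(true_fraction, amplification_efficiency = 1,
                          ct_noise_sd = 0.2, n_replicates = 3, seed,
                          baseline_target = 14, baseline_normalizer = 22) {
  stopifnot(true_fraction > 0,
            amplification_efficiency > 0, amplification_efficiency <= 1,
            ct_noise_sd >= 0, n_replicates >= 1)
  set.seed(.substream(seed, "qpcr"))
  slope <- 1 / log2(1 + amplification_efficiency)  # cycles per template log2
  one <- function(label, fraction) {
    data.frame(
      sample = label,
      replicate = seq_len(n_replicates),
      ct_target = baseline_target - slope * log2(fraction) +
        stats::rnorm(n_replicates, 0, ct_noise_sd),
      ct_normalizer = baseline_normalizer +
        stats::rnorm(n_replicates, 0, ct_noise_sd)
    )
  }
  rbind(one("sample", true_fraction), one("reference", 1))
}
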