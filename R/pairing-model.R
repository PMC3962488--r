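#' @keywords internal
"_PACKAGE"

#' Canonical sperm/progeny class labels
#'
#' The six sperm sex-chromosome karyotypes an XYY (here X/Y1/Y2) male can
#' produce under 2+1 pairing, in the fixed order used for all tables and
#' serialization: `"X"`, `"12"`, `"X1"`, `"2"`, `"X2"`, `"1"`. The digit
#' labels name the Y chromosomes: `1` is the full-length Y, `2` the Y whose
#' rDNA array is under evaluation; `"12"` sperm carry both Ys, `"X2"` sperm
#' carry the X and Y2, and so on. Nullo-XY sperm are not modelled.
#'
#' @format Character vector of length 6.
#' @export
gamete_classes <- c("X", "12", "X1", "2", "X2", "1")

# chromosome content of each sperm class (columns: X, Y1, Y2 carried)
.class_chromosomes <- matrix(
  c(1L, 0L, 0L,
    0L, 1L, 1L,
    1L, 1L, 0L,
    0L, 0L, 1L,
    1L, 0L, 1L,
    0L, 1L, 0L),
  nrow = 6, byrow = TRUE,
  dimnames = list(gamete_classes, c("X", "Y1", "Y2"))
)

#' Pairing configurations of the 2+1 model
#'
#' Three sex chromosomes must resolve to two poles at meiosis I. Under the
#' 2+1 model two of them pair and disjoin faithfully while the third
#' segregates at random: configuration `L` pairs X with Y1, `M` pairs X with
#' Y2, and `N` pairs the two Y chromosomes, leaving the X unpaired.
#'
#' @param label One of `"L"`, `"M"`, `"N"`.
#' @return A list with elements `label`, `paired` (character vector of the
#'   two disjoining chromosomes) and `unpaired` (the randomly segregating
#'   chromosome).
#' @examples
#' pairing_configuration("L")
#' @export
pairing_configuration <- function(label) {
  pairs <- list(L = c("X", "Y1"), M = c("X", "Y2"), N = c("Y1", "Y2"))
  if (length(label) != 1L || !label %in% names(pairs))
    stop("unknown pairing configuration: must be one of 'L', 'M', 'N'",
         call. = FALSE)
  paired <- pairs[[label]]
  list(label = label, paired = paired,
       unpaired = setdiff(c("X", "Y1", "Y2"), paired))
}

#' Construct and validate a pairing-configuration mixture
#'
#' A point (pL, pM, pN) on the probability simplex giving the frequencies of
#' the three 2+1 pairing configurations in a population of meioses.
#' Components within `1e-9` of the simplex are renormalized; larger
#' deviations are rejected.
#'
#' @param pL,pM,pN Frequencies of the L, M and N configurations. `pM` and
#'   `pN` may be omitted if `pL` is a numeric vector of length 3.
#' @return A named numeric vector of class `"pairing_mixture"` summing to 1.
#' @examples
#' pairing_mixture(1/3, 1/3, 1/3)
#' pairing_mixture(c(0.5, 0.3, 0.2))
#' @export
pairing_mixture <- function(pL, pM = NULL, pN = NULL) {
  p <- if (is.null(pM)) as.numeric(pL) else c(pL, pM, pN)
  if (length(p) != 3L || anyNA(p))
    stop("a pairing mixture needs three non-missing components", call. = FALSE)
  if (any(p < -1e-9) || any(p > 1 + 1e-9) || abs(sum(p) - 1) > 1e-9)
    stop("mixture components must lie in [0,1] and sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  p <- pmin(pmax(p, 0), 1)
  p <- p / sum(p)
  structure(stats::setNames(p, c("L", "M", "N")), class = "pairing_mixture")
}

#' Construct and validate a zygote-class viability vector
#'
#' Relative viabilities of the six zygote classes (an X-bearing egg
#' fertilized by each sperm class), acting multiplicatively on the class
#' probabilities before renormalization. Canonicalized so that the largest
#' viability is 1.
#'
#' @param v Nonnegative numeric vector of length 6, optionally named by the
#'   canonical class labels; at least one entry must be positive. The
#'   default is unit viability for every class.
#' @return Named numeric vector of class `"viability_vector"` with max 1.
#' @examples
#' viability_vector()                      # all classes fully viable
#' viability_vector(c(X = 1, `12` = 0.6, X1 = 1, `2` = 1, X2 = 1, `1` = 1))
#' @export
viability_vector <- function(v = rep(1, 6)) {
  if (!is.null(names(v))) {
    if (!setequal(names(v), gamete_classes))
      stop("viability names must be the six canonical class labels",
           call. = FALSE)
    v <- v[gamete_classes]
  }
  v <- as.numeric(v)
  if (length(v) != 6L || anyNA(v) || any(v < 0))
    stop("viability must be six nonnegative values", call. = FALSE)
  if (all(v == 0))
    stop("at least one class must be viable", call. = FALSE)
  structure(stats::setNames(v / max(v), gamete_classes),
            class = "viability_vector")
}

#' Sperm-class distribution of one pairing configuration
#'
#' The paired chromosomes disjoin to opposite poles; the unpaired chromosome
#' joins either pole with probability 1/2. Each configuration therefore
#' yields exactly four equiprobable sperm karyotypes; the two classes in
#' which the paired chromosomes would co-occur (or both be absent) have
#' probability zero.
#'
#' @param config A configuration label (`"L"`, `"M"`, `"N"`) or the result
#'   of [pairing_configuration()].
#' @return Named numeric vector over the six canonical classes, summing to 1
#'   with support on exactly four classes.
#' @examples
#' gamete_distribution("L")  # X, 12, X2, 1 each 1/4
#' @export
gamete_distribution <- function(config) {
  if (is.character(config)) config <- pairing_configuration(config)
  chrom <- .class_chromosomes
  # a sperm class is reachable iff it carries exactly one of the paired pair
  n_paired <- rowSums(chrom[, config$paired, drop = FALSE])
  p <- ifelse(n_paired == 1L, 0.25, 0)
  stats::setNames(p, gamete_classes)
}

#' Zygote-class distribution under a pairing mixture
#'
#' Mixes the three configuration-specific sperm distributions by their
#' frequencies, then applies multiplicative viability weights and
#' renormalizes. With unit viability the complementary class pairs are
#' equal: P(X) = P(12) = (pL+pM)/4, P(X1) = P(2) = (pM+pN)/4,
#' P(X2) = P(1) = (pL+pN)/4.
#'
#' @param mixture A [pairing_mixture()] (or coercible vector of length 3).
#' @param viability A [viability_vector()] (or coercible vector of length 6).
#' @return Named probability vector over the six canonical zygote classes.
#' @examples
#' zygote_distribution(pairing_mixture(1/3, 1/3, 1/3))   # all 1/6
#' zygote_distribution(pairing_mixture(1, 0, 0))         # X1, 2 absent
#' @export
zygote_distribution <- function(mixture, viability = viability_vector()) {
  mixture <- if (inherits(mixture, "pairing_mixture")) mixture else
    pairing_mixture(mixture)
  viability <- if (inherits(viability, "viability_vector")) viability else
    viability_vector(viability)
  raw <- mixture[["L"]] * gamete_distribution("L") +
    mixture[["M"]] * gamete_distribution("M") +
    mixture[["N"]] * gamete_distribution("N")
  w <- raw * unclass(viability)
  total <- sum(w)
  if (total <= 0)
    stop("no viable zygote class under this mixture and viability",
         call. = FALSE)
  w / total
}

#' Expected fraction of female progeny
#'
#' Progeny arise from X-bearing eggs; daughters come from X-bearing sperm
#' (classes X, X1, X2). Because every configuration sends the X to each pole
#' with probability 1/2, the sex ratio is exactly 1:1 for every mixture when
#' viability is uniform — deviations therefore diagnose differential
#' viability, not pairing bias.
#'
#' @inheritParams zygote_distribution
#' @return The expected female fraction (0 to 1).
#' @examples
#' expected_sex_ratio(pairing_mixture(0.7, 0.2, 0.1))  # 0.5
#' @export
expected_sex_ratio <- function(mixture, viability = viability_vector()) {
  z <- zygote_distribution(mixture, viability)
  sum(z[c("X", "X1", "X2")])
}

#' Marker constitution of the sex chromosomes
#'
#' The X carries the recessive yellow (y) and white (w) mutations, so
#' XX daughters from unmarked sperm are yellow-bodied and white-eyed.
#' Y1 (the full-length Y) is either the Bar-marked chromosome or the
#' ROMA chromosome, whose P-element carries y+ and w+ subject to
#' position-effect variegation. Y2 (the rDNA-deletion series) carries a
#' fully expressed y+.
#'
#' @param y1 `"Bar"` for the Bar-marked Y1 or `"variegating"` for the
#'   variegating y+ w+ Y1.
#' @return A list of per-chromosome marker descriptions, class
#'   `"marker_table"`.
#' @export
marker_table <- function(y1 = c("Bar", "variegating")) {
  y1 <- match.arg(y1)
  structure(list(
    X  = list(body = "y", eye_color = "w", eye_shape = "wild-type"),
    Y1 = if (y1 == "Bar")
      list(body = NULL, eye_color = NULL, eye_shape = "Bar")
    else
      list(body = "y+ (variegating)", eye_color = "w+", eye_shape = "wild-type"),
    Y2 = list(body = "y+", eye_color = NULL, eye_shape = NULL),
    y1_type = y1
  ), class = "marker_table")
}

#' Render a sperm class as an observable progeny phenotype
#'
#' Deterministically maps a zygote (the given sperm class plus an X-bearing
#' egg) to its visible phenotype under a marker table. Sex follows X dose
#' (two or more X chromosomes: female). The X1 class is only distinguishable
#' from a hypothetical X12 class when Y1 carries the variegating marker;
#' the `ambiguous` flag records this.
#'
#' @param gamete One of the canonical class labels.
#' @param markers A [marker_table()].
#' @return A list with `sex`, `body_color`, `eye_color`, `eye_shape` and
#'   `ambiguous`.
#' @examples
#' phenotype_of("X", marker_table("Bar"))   # yellow-bodied white-eyed female
#' phenotype_of("1", marker_table("Bar"))   # Bar-eyed male
#' @export
phenotype_of <- function(gamete, markers = marker_table()) {
  if (!gamete %in% gamete_classes)
    stop("unknown gamete class: ", gamete, call. = FALSE)
  carries <- .class_chromosomes[gamete, ]
  has_y1 <- carries[["Y1"]] == 1L
  has_y2 <- carries[["Y2"]] == 1L
  # zygote = sperm + X egg, so X dose is carries["X"] + 1
  sex <- if (carries[["X"]] + 1L >= 2L) "female" else "male"
  variegating <- markers$y1_type == "variegating"
  body <- if (has_y2) "y+"
    else if (has_y1 && variegating) "y+ (variegating)"
    else "y"
  eye_color <- if (has_y1 && variegating) "w+" else "w"
  eye_shape <- if (has_y1 && !variegating) "Bar" else "wild-type"
  # X1 vs X12 sperm give the same non-variegating phenotype unless the y+ on
  # Y1 variegates and betrays the extra chromosome
  ambiguous <- gamete == "X1" && !variegating
  list(sex = sex, body_color = body, eye_color = eye_color,
       eye_shape = eye_shape, ambiguous = ambiguous)
}
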