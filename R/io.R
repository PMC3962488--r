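# sniff comma vs tab from the header line
.read_delim <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' Read a vial-structured progeny-count table
#'
#' Reads a comma- or tab-delimited file with one row per vial, the six
#' canonical class-count columns (or the four control-cross columns) and
#' any metadata columns, validating that every count is a nonnegative
#' integer. Offending cells are named in the error.
#'
#' @param path Path to the delimited file.
#' @return A validated data frame of vial counts.
#' @export
read_vial_counts <- function(path) {
  tab <- .read_delim(path)
  cls <- .count_columns(tab)
  for (cl in cls) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("invalid count in column '", cl, "', row(s) ",
           paste(bad, collapse = ", "),
           ": counts must be nonnegative integers", call. = FALSE)
    tab[[cl]] <- as.integer(v)
  }
  tab
}

#' Write a vial-counts table
#'
#' @param counts Data frame as produced by [simulate_xyy_vials()] or
#'   [read_vial_counts()].
#' @param path Output path; written as CSV so that
#'   [read_vial_counts()] round-trips it exactly.
#' @export
write_vial_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged data tables from the XYY pairing study
#'
#' The four printed data tables of the study, shipped as plain-text
#' fixtures:
#' \describe{
#'   \item{`table1`}{Control crosses (XY sires): normal and exceptional
#'     progeny counts per Y chromosome.}
#'   \item{`table2`}{XYY cross summaries for 11 chromosome combinations:
#'     pooled, per-vial mean and per-vial SD rows of the six class
#'     frequencies (%), plus %female, %aneuploid and vial counts.}
#'   \item{`table3`}{Per-class mean/SD of class frequencies (proportions)
#'     for the sire-replicate subsets (1, 2, 3), transfer-time subsets
#'     (0.1, 0.2, 0.3) and the pooled set (123), for the ROMA/10B and
#'     ROMA/473 chromosome sets.}
#'   \item{`table4`}{Relative rDNA copy number (% of the 10B reference)
#'     with pooled SEM per chromosome.}
#' }
#'
#' @param which One of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return The fixture as a data frame (class-frequency columns keep their
#'   canonical nonsyntactic names).
#' @examples
#' head(xyy_fixture("table1"))
#' @export
xyy_fixture <- function(which = c("table1", "table2", "table3", "table4")) {
  which <- match.arg(which)
  file <- c(table1 = "table1_control_crosses.csv",
            table2 = "table2_xyy_crosses.csv",
            table3 = "table3_subset_stats.csv",
            table4 = "table4_copy_number.csv")[[which]]
  path <- system.file("extdata", file, package = "xyypair", mustWork = TRUE)
  tab <- .read_delim(path)
  if (which == "table3") tab$subset <- as.character(tab$subset)
  tab
}

#' Read and validate a run configuration
#'
#' A YAML or JSON file with top-level keys `seed`, `output_dir`, `analysis`
#' (`level`, `alpha`, `df`, `n_boot`) and `simulation` (`mixture`,
#' `viability`, `vial_design`). Unknown keys at any level are rejected;
#' missing keys fall back to defaults.
#'
#' @param path Path to the configuration file (`.yaml`/`.yml` or `.json`).
#' @return A validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  check_keys(cfg, c("seed", "output_dir", "analysis", "simulation"), "top level")
  check_keys(cfg$analysis, c("level", "alpha", "df", "n_boot"), "analysis")
  check_keys(cfg$simulation, c("mixture", "viability", "vial_design"),
             "simulation")
  check_keys(cfg$simulation$vial_design,
             c("n_vials", "mean_vial_size", "size_dispersion",
               "overdispersion_concentration"), "simulation$vial_design")
  out <- list(
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    output_dir = if (is.null(cfg$output_dir)) "." else cfg$output_dir,
    analysis = list(
      level = cfg$analysis$level %||% 0.975,
      alpha = cfg$analysis$alpha %||% 0.05,
      df = cfg$analysis$df %||% 1000,
      n_boot = cfg$analysis$n_boot %||% 1000),
    simulation = list(
      mixture = pairing_mixture(cfg$simulation$mixture %||% rep(1 / 3, 3)),
      viability = viability_vector(cfg$simulation$viability %||% rep(1, 6)),
      vial_design = do.call(vial_design,
                            cfg$simulation$vial_design %||% list()))
  )
  structure(out, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recompute the study's fixture-based results
#'
#' Runs every analysis the packaged tables support: control-cross
#' summaries, the female nondisjunction rate, pairing-mixture moments
#' estimates for all 11 XYY crosses, the 72-comparison subset scan, the 12
#' class-frequency-on-copy-number regressions, and the required sample
#' sizes to distinguish the B/10B and B/473 crosses per class.
#'
#' @param level Interval level for the subset scan (default 0.975).
#' @param alpha,df Parameters of the required-sample-size calculation.
#' @return A list with elements `control_summaries`, `ndj_rate`,
#'   `mixture_estimates`, `subset_scan`, `regressions`,
#'   `required_sample_sizes`.
#' @examples
#' rep <- reproduce_paper()
#' rep$subset_scan$n_significant
#' rep$required_sample_sizes
#' @export
reproduce_paper <- function(level = 0.975, alpha = 0.05, df = 1000) {
  t1 <- xyy_fixture("table1")
  t2 <- xyy_fixture("table2")
  t3 <- xyy_fixture("table3")
  t4 <- xyy_fixture("table4")

  control <- lapply(seq_len(nrow(t1)), function(i)
    summarize_cross(t1[i, .control_classes]))
  names(control) <- t1$y_chromosome

  pooled <- t2[t2$row_type == "pooled", ]
  mixtures <- lapply(seq_len(nrow(pooled)), function(i) {
    f <- as.numeric(pooled[i, gamete_classes]) / 100
    estimate_mixture_moments(f / sum(f))
  })
  names(mixtures) <- paste(pooled$y1, pooled$y2, sep = "/")

  regressions <- list()
  copy_number <- stats::setNames(t4$mean_pct, t4$chromosome)
  for (y1 in unique(pooled$y1)) {
    rows <- pooled[pooled$y1 == y1, ]
    x <- copy_number[as.character(rows$y2)]
    for (cl in gamete_classes) {
      regressions[[paste(y1, cl, sep = ":")]] <-
        frequency_regression(x, rows[[cl]])
    }
  }

  means <- t2[t2$row_type == "vial_mean", ]
  sds <- t2[t2$row_type == "vial_sd", ]
  pick <- function(tbl, y2) tbl[tbl$y1 == "B" & tbl$y2 == y2, ]
  sizes <- vapply(gamete_classes, function(cl) {
    a <- group_stats(pick(means, "10B")[[cl]], pick(sds, "10B")[[cl]], 32)
    b <- group_stats(pick(means, "473")[[cl]], pick(sds, "473")[[cl]], 25)
    required_sample_size(a, b, alpha = alpha, df = df)
  }, integer(1))

  list(control_summaries = control,
       ndj_rate = nondisjunction_rate(5, 8220),
       mixture_estimates = mixtures,
       subset_scan = pairwise_subset_scan(t3, level = level),
       regressions = regressions,
       required_sample_sizes = sizes)
}
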