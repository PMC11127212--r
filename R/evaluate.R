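# QC analytics: inter-day precision (%RSD), accuracy versus reference CCS
# sets, matrix effects, per-class m/z-CCS power trendlines and adduct CCS
# shifts.

#' Inter-day CCS precision (%RSD)
#'
#' Per-compound relative standard deviation of replicate CCS measurements,
#' using the sample standard deviation (n - 1 denominator) as appropriate
#' for small replicate designs (e.g. triplicate inter-day runs).
#'
#' @param replicates A data frame with columns `compound` and `ccs`, one row
#'   per replicate measurement; every compound needs >= 2 replicates.
#' @return A `precision_report` tibble with columns `compound`, `n`,
#'   `mean_ccs`, `sd_ccs`, `rsd_pct`, carrying the worst-case %RSD in
#'   attribute `worst_rsd_pct` (also via [worst_rsd()]).
#' @export
#' @examples
#' interday_rsd(tibble::tibble(
#'   compound = rep(c("a", "b"), each = 3),
#'   ccs = c(99, 100, 101, 150, 150.5, 149.5)
#' ))
interday_rsd <- function(replicates) {
  stopifnot(all(c("compound", "ccs") %in% names(replicates)))
  out <- replicates |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ccs = mean(.data$ccs),
      sd_ccs = stats::sd(.data$ccs),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    stop("every compound needs >= 2 replicates; offending: ",
         paste(out$compound[out$n < 2], collapse = ", "), call. = FALSE)
  }
  if (any(out$mean_ccs <= 0)) {
    stop("non-positive mean CCS", call. = FALSE)
  }
  out$rsd_pct <- 100 * out$sd_ccs / out$mean_ccs
  out <- tibble::as_tibble(out)
  attr(out, "worst_rsd_pct") <- max(out$rsd_pct)
  class(out) <- c("precision_report", class(out))
  out
}

#' @rdname interday_rsd
#' @param report A `precision_report`.
#' @export
worst_rsd <- function(report) {
  attr(report, "worst_rsd_pct")
}

#' CCS accuracy against a reference set
#'
#' Per-ion CCS deviations of measured values against a named reference
#' source (literature drift-tube CCS, literature traveling-wave CCS,
#' machine-learning predictions, ...). Ions present on only one side are
#' listed, not scored. The `within` fraction uses an inclusive threshold: a
#' deviation of exactly +/- `threshold_pct` counts as within.
#'
#' @param measured,reference Data frames with columns `ion` and `ccs`.
#' @param source Label for the reference source.
#' @param threshold_pct Deviation threshold, % (inclusive).
#' @return An `accuracy_report` list: `per_ion` (deviation tibble),
#'   `fraction_within`, `max_abs_pct`, `threshold_pct`, `source`,
#'   `unmatched_measured`, `unmatched_reference`.
#' @export
accuracy_vs_reference <- function(measured, reference,
                                  source = "reference",
                                  threshold_pct = 2) {
  stopifnot(all(c("ion", "ccs") %in% names(measured)),
            all(c("ion", "ccs") %in% names(reference)))
  shared <- dplyr::inner_join(
    dplyr::rename(measured, measured_ccs = "ccs"),
    dplyr::rename(reference, reference_ccs = "ccs"),
    by = "ion"
  )
  if (nrow(shared) == 0) stop("no shared ions between measured and reference",
                              call. = FALSE)
  dev <- delta_ccs(shared$measured_ccs, shared$reference_ccs)
  per_ion <- dplyr::bind_cols(tibble::tibble(ion = shared$ion), dev)
  structure(
    list(
      per_ion = per_ion,
      fraction_within = mean(abs(per_ion$delta_pct) <= threshold_pct),
      max_abs_pct = max(abs(per_ion$delta_pct)),
      threshold_pct = threshold_pct,
      source = source,
      unmatched_measured = setdiff(measured$ion, reference$ion),
      unmatched_reference = setdiff(reference$ion, measured$ion)
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("CCS accuracy vs %s: %d shared ion(s)\n", x$source,
              nrow(x$per_ion)))
  cat(sprintf("  within +/- %g%%: %.1f%%; max |delta| %.2f%%\n",
              x$threshold_pct, 100 * x$fraction_within, x$max_abs_pct))
  n_un <- length(x$unmatched_measured) + length(x$unmatched_reference)
  if (n_un > 0) cat(sprintf("  %d unmatched ion(s) not scored\n", n_un))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.accuracy_report <- function(x, ...) {
  x$per_ion
}

#' @exportS3Method generics::glance
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(
    source = x$source, n_ions = nrow(x$per_ion),
    fraction_within = x$fraction_within,
    threshold_pct = x$threshold_pct, max_abs_pct = x$max_abs_pct
  )
}

#' Matrix effect on CCS measurements
#'
#' Compares CCS values of compounds spiked into a biological matrix against
#' the same compounds in neat solvent; a matrix-independent method shows
#' small deviations.
#'
#' @param neat,matrix Data frames with columns `compound` and `ccs`.
#' @param threshold_pct Deviation threshold, % (inclusive).
#' @return An `accuracy_report` (deviations of matrix versus neat).
#' @export
matrix_effect_report <- function(neat, matrix, threshold_pct = 2) {
  stopifnot(all(c("compound", "ccs") %in% names(neat)),
            all(c("compound", "ccs") %in% names(matrix)))
  accuracy_vs_reference(
    dplyr::rename(matrix, ion = "compound"),
    dplyr::rename(neat, ion = "compound"),
    source = "neat solvent", threshold_pct = threshold_pct
  )
}

#' Per-class m/z-CCS power trendlines
#'
#' Fits the conformational-space trendline `ccs = a * mz^b` by ordinary
#' least squares of `log(ccs)` on `log(mz)`; the goodness of fit `r2` is
#' reported in the log-log space of the linear fit (the `r2_space` column
#' records this convention). An `"all"` fit over every ion is always
#' returned; with `per_class = TRUE`, one fit per `class_label` with at
#' least `min_points` ions is added (smaller classes are skipped with a
#' message). A zero-variance response yields `b = 0`, `r2 = 1` and a
#' `zero_variance` flag instead of an error, so batch runs survive
#' degenerate classes.
#'
#' @param ions A data frame with columns `mz`, `ccs` and (for per-class
#'   fits) `class_label`.
#' @param per_class Also fit each chemical class?
#' @param min_points Minimum ions per reported fit.
#' @return A `trendline_fits` tibble: `class_label`, `a`, `b`, `r2`,
#'   `r2_space`, `n_points`, `zero_variance`; the input ions are attached as
#'   attribute `ions` for plotting.
#' @export
#' @examples
#' ions <- tibble::tibble(mz = c(100, 400, 900), ccs = c(110, 220, 330))
#' fit_class_trendlines(ions, per_class = FALSE)
fit_class_trendlines <- function(ions, per_class = TRUE, min_points = 3) {
  stopifnot(all(c("mz", "ccs") %in% names(ions)),
            all(ions$mz > 0), all(ions$ccs > 0))
  fit_one <- function(df, label) {
    if (nrow(df) < min_points) {
      message("skipping trendline for '", label, "': fewer than ",
              min_points, " ions")
      return(NULL)
    }
    x <- log(df$mz)
    y <- log(df$ccs)
    if (stats::var(y) == 0) {
      return(tibble::tibble(
        class_label = label, a = exp(y[1]), b = 0, r2 = 1,
        r2_space = "log-log", n_points = nrow(df), zero_variance = TRUE
      ))
    }
    fit <- stats::lm(y ~ x)
    # summary.lm warns on numerically perfect fits; those are legitimate here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    tibble::tibble(
      class_label = label,
      a = exp(unname(stats::coef(fit)[1])),
      b = unname(stats::coef(fit)[2]),
      r2 = r2,
      r2_space = "log-log",
      n_points = nrow(df),
      zero_variance = FALSE
    )
  }
  fits <- list(fit_one(ions, "all"))
  if (per_class) {
    if (!"class_label" %in% names(ions)) {
      stop("`ions` needs a `class_label` column when `per_class = TRUE`",
           call. = FALSE)
    }
    for (cl in sort(unique(ions$class_label))) {
      fits <- c(fits, list(fit_one(ions[ions$class_label == cl, ], cl)))
    }
  }
  out <- dplyr::bind_rows(fits)
  attr(out, "ions") <- tibble::as_tibble(ions)
  class(out) <- c("trendline_fits", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.trendline_fits <- function(object, ...) {
  ions <- attr(object, "ions")
  has_class <- "class_label" %in% names(ions) &&
    any(object$class_label != "all")
  p <- if (has_class) {
    ggplot2::ggplot(ions, ggplot2::aes(.data$mz, .data$ccs,
                                       colour = .data$class_label))
  } else {
    ggplot2::ggplot(ions, ggplot2::aes(.data$mz, .data$ccs))
  }
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    grid <- seq(min(ions$mz), max(ions$mz), length.out = 200)
    tibble::tibble(class_label = object$class_label[i], mz = grid,
                   ccs = object$a[i] * grid^object$b[i])
  }))
  main <- curves[curves$class_label == "all", ]
  p +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = main, colour = "black",
                       linewidth = 0.8) +
    ggplot2::labs(x = "m/z", y = expression(CCS ~ (ring(A)^2)),
                  colour = "super class")
}

#' CCS shift between two adducts of the same compounds
#'
#' Pairs library entries that carry CCS values for both adducts and reports
#' the mean and sample SD of `ccs(adduct_a) - ccs(adduct_b)` (e.g. sodiated
#' versus protonated ions, where the larger charge carrier enlarges the
#' collision cross-section).
#'
#' @param library A library tibble.
#' @param adduct_a,adduct_b Adduct names; the shift is `a - b`.
#' @return A one-row tibble: `pair`, `n_pairs`, `mean_shift`, `sd_shift`
#'   (`NA` for a single pair).
#' @export
adduct_shift_stats <- function(library, adduct_a, adduct_b) {
  with_ccs <- library[!is.na(library$ccs), ]
  a <- with_ccs[with_ccs$adduct == adduct_a, c("hmdb_id", "ccs")]
  b <- with_ccs[with_ccs$adduct == adduct_b, c("hmdb_id", "ccs")]
  pairs <- dplyr::inner_join(a, b, by = "hmdb_id",
                             suffix = c("_a", "_b"))
  if (nrow(pairs) == 0) {
    stop("no compound carries CCS values for both ", adduct_a, " and ",
         adduct_b, call. = FALSE)
  }
  diffs <- pairs$ccs_a - pairs$ccs_b
  tibble::tibble(
    pair = paste(adduct_a, "vs", adduct_b),
    n_pairs = nrow(pairs),
    mean_shift = mean(diffs),
    sd_shift = if (length(diffs) >= 2) stats::sd(diffs) else NA_real_
  )
}
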