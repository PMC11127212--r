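# Traveling-wave CCS calibration: EDC drift-time correction, reduced-mass
# CCS normalization, power-law fit, lock-CCS correction and CCS deviations.

#' EDC-corrected drift time
#'
#' Subtracts the m/z-dependent post-mobility flight-time term from a measured
#' drift time: `t' = t - c * sqrt(mz) / 1000`. The enhanced-duty-cycle (EDC)
#' coefficient `c` is instrument-specific and has no meaningful default; it
#' must come from the acquisition configuration.
#'
#' @param drift_time Measured drift time(s), ms.
#' @param mz m/z of the ion(s).
#' @param edc_coefficient EDC delay coefficient (dimensionless).
#' @return Corrected drift time(s), ms.
#' @export
corrected_drift_time <- function(drift_time, mz, edc_coefficient) {
  if (any(drift_time <= 0)) stop("`drift_time` must be > 0", call. = FALSE)
  out <- drift_time - edc_coefficient * sqrt(mz) / 1000
  if (any(out <= 0)) {
    stop("corrected drift time <= 0; check EDC coefficient and units",
         call. = FALSE)
  }
  out
}

#' Reduced-mass CCS normalization
#'
#' Maps a CCS to the normalized scale used for power-law calibration:
#' `ccs' = ccs * sqrt(mu) / z` with reduced mass
#' `mu = m_ion * m_gas / (m_ion + m_gas)` and `m_ion = mz * z`.
#'
#' @param ccs CCS value(s), A^2.
#' @param mz m/z of the ion(s).
#' @param charge Charge state(s), >= 1.
#' @param gas_mass Drift-gas mass, Da (28.0134 for nitrogen).
#' @return Normalized CCS value(s).
#' @export
normalize_ccs <- function(ccs, mz, charge = 1L, gas_mass = 28.0134) {
  stopifnot(all(ccs > 0), all(mz > 0), all(charge >= 1), gas_mass > 0)
  m_ion <- mz * charge
  mu <- m_ion * gas_mass / (m_ion + gas_mass)
  ccs * sqrt(mu) / charge
}

#' @rdname normalize_ccs
#' @param normalized_ccs Normalized CCS value(s) to map back.
#' @export
denormalize_ccs <- function(normalized_ccs, mz, charge = 1L, gas_mass = 28.0134) {
  m_ion <- mz * charge
  mu <- m_ion * gas_mass / (m_ion + gas_mass)
  normalized_ccs * charge / sqrt(mu)
}

#' Read a calibrant table
#'
#' Delimited text with columns `mz`, `charge`, `drift_time_ms`,
#' `reference_ccs_A2`.
#'
#' @param path File path.
#' @return A tibble with columns `mz`, `charge`, `drift_time`, `reference_ccs`.
#' @export
read_calibrants <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("mz", "charge", "drift_time_ms", "reference_ccs_A2")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("calibrant table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    mz = df$mz,
    charge = as.integer(df$charge),
    drift_time = df$drift_time_ms,
    reference_ccs = df$reference_ccs_A2
  )
}

#' Fit a traveling-wave CCS calibration
#'
#' Fits the standard TWIMS power-law calibration `ccs' = A * t'^B` by
#' ordinary least squares of `log(ccs')` on `log(t')`, where `t'` is the
#' EDC-corrected drift time and `ccs'` the reduced-mass-normalized reference
#' CCS of each calibrant.
#'
#' @param calibrants A data frame with columns `mz`, `charge`, `drift_time`
#'   (ms) and `reference_ccs` (A^2), e.g. from [read_calibrants()].
#' @param edc_coefficient EDC delay coefficient (instrument-specific).
#' @param gas_mass Drift-gas mass, Da; defaults to nitrogen.
#' @return An object of class `ccs_calibration` with elements `A`, `B`,
#'   `edc_coefficient`, `gas_mass`, `lock_factor`, `fit` (the underlying
#'   `lm`) and `calibrants`.
#' @export
#' @examples
#' cal <- tibble::tibble(
#'   mz = c(120, 250, 400, 600), charge = 1,
#'   drift_time = c(2.1, 3.4, 4.6, 6.0),
#'   reference_ccs = c(120, 160, 200, 240)
#' )
#' fit_ccs_calibration(cal, edc_coefficient = 1.41)
fit_ccs_calibration <- function(calibrants, edc_coefficient,
                                gas_mass = 28.0134) {
  need <- c("mz", "charge", "drift_time", "reference_ccs")
  missing <- setdiff(need, names(calibrants))
  if (length(missing) > 0) {
    stop("`calibrants` missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  td <- corrected_drift_time(calibrants$drift_time, calibrants$mz,
                             edc_coefficient)
  if (length(unique(td)) < 2) {
    stop("need >= 2 calibrants with distinct corrected drift times",
         call. = FALSE)
  }
  ccs_norm <- normalize_ccs(calibrants$reference_ccs, calibrants$mz,
                            calibrants$charge, gas_mass)
  fit <- stats::lm(log(ccs_norm) ~ log(td))
  structure(
    list(
      A = exp(unname(stats::coef(fit)[1])),
      B = unname(stats::coef(fit)[2]),
      edc_coefficient = edc_coefficient,
      gas_mass = gas_mass,
      lock_factor = 1,
      fit = fit,
      calibrants = tibble::as_tibble(calibrants)
    ),
    class = "ccs_calibration"
  )
}

#' Convert drift times to CCS with a fitted calibration
#'
#' `ccs = lock_factor * A * t'^B * z / sqrt(mu)`.
#'
#' @param model A `ccs_calibration` object.
#' @param drift_time Drift time(s), ms.
#' @param mz m/z value(s).
#' @param charge Charge state(s).
#' @return CCS value(s), A^2.
#' @export
drift_to_ccs <- function(model, drift_time, mz, charge = 1L) {
  stopifnot(inherits(model, "ccs_calibration"))
  td <- corrected_drift_time(drift_time, mz, model$edc_coefficient)
  ccs_norm <- model$A * td^model$B
  model$lock_factor * denormalize_ccs(ccs_norm, mz, charge, model$gas_mass)
}

#' Single-point lock-CCS correction
#'
#' Applies the multiplicative correction used with a continuously infused
#' reference compound (e.g. leucine enkephalin): the calibration output is
#' rescaled by `reference / measured`. Ratios outside (0.5, 2) signal gross
#' miscalibration and raise an error.
#'
#' @param model A `ccs_calibration` object.
#' @param lock_measured_ccs CCS of the lock compound measured with `model`.
#' @param lock_reference_ccs Its reference CCS.
#' @return The model with an updated `lock_factor`.
#' @export
lock_ccs_correction <- function(model, lock_measured_ccs, lock_reference_ccs) {
  stopifnot(inherits(model, "ccs_calibration"),
            lock_measured_ccs > 0, lock_reference_ccs > 0)
  factor <- lock_reference_ccs / lock_measured_ccs
  if (factor <= 0.5 || factor >= 2) {
    stop("lock factor ", signif(factor, 4),
         " outside (0.5, 2): gross miscalibration", call. = FALSE)
  }
  model$lock_factor <- model$lock_factor * factor
  model
}

#' CCS deviation between a measurement and a reference
#'
#' @param measured,reference CCS values, A^2 (vectorized).
#' @return A tibble with columns `measured_ccs`, `reference_ccs`,
#'   `delta_abs` (A^2) and `delta_pct` (%).
#' @export
#' @examples
#' delta_ccs(131.44, 133.13)
delta_ccs <- function(measured, reference) {
  if (any(reference <= 0)) stop("`reference` must be > 0", call. = FALSE)
  tibble::tibble(
    measured_ccs = measured,
    reference_ccs = reference,
    delta_abs = measured - reference,
    delta_pct = 100 * (measured - reference) / reference
  )
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat("TWIMS CCS calibration (power law)\n")
  cat(sprintf("  A = %.6g, B = %.6g, lock factor = %.6g\n",
              x$A, x$B, x$lock_factor))
  cat(sprintf("  EDC coefficient = %g, drift gas mass = %g Da, n = %d calibrants\n",
              x$edc_coefficient, x$gas_mass, nrow(x$calibrants)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ccs_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("A", "B", "lock_factor"),
    estimate = c(x$A, x$B, x$lock_factor)
  )
}

#' @exportS3Method generics::glance
glance.ccs_calibration <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    n_calibrants = nrow(x$calibrants),
    lock_factor = x$lock_factor
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ccs_calibration <- function(object, ...) {
  td <- corrected_drift_time(object$calibrants$drift_time,
                             object$calibrants$mz, object$edc_coefficient)
  ccs_norm <- normalize_ccs(object$calibrants$reference_ccs,
                            object$calibrants$mz, object$calibrants$charge,
                            object$gas_mass)
  df <- tibble::tibble(td = td, ccs_norm = ccs_norm)
  grid <- tibble::tibble(td = seq(min(td), max(td), length.out = 200))
  grid$ccs_norm <- object$A * grid$td^object$B
  ggplot2::ggplot(df, ggplot2::aes(.data$td, .data$ccs_norm)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "corrected drift time (ms)",
      y = "normalized CCS",
      title = sprintf("CCS' = %.4g t'^%.4g", object$A, object$B)
    )
}
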