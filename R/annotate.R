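# The 4D matching engine: tolerance filters per dimension, isotope and MS/MS
# subscores, composite scoring, deterministic ranking, MSI confidence levels
# and the cumulative identification funnel.

#' Matching tolerances
#'
#' Defaults reproduce the search criteria of the urine screening workflow:
#' precursor/product mass error +/- 20 ppm, isotope similarity >= 80%, RT
#' +/- 0.3 min and delta-CCS within +/- 2% OR +/- 4 A^2 (the dual criterion
#' avoids over-filtering small ions, for which 2% is under 3 A^2).
#' `msms_min` is the minimum fragment-match score (% of reference fragment
#' intensity recovered) for the MS/MS dimension to count as passed; it has
#' no analogue in the instrument software and is deliberately permissive.
#'
#' @param ppm Precursor mass tolerance, +/- ppm.
#' @param rt Retention-time tolerance, +/- minutes.
#' @param ccs_pct Relative CCS tolerance, +/- %.
#' @param ccs_abs Absolute CCS tolerance, +/- A^2.
#' @param isotope_min Minimum isotope similarity, %.
#' @param fragment_ppm Product-ion mass tolerance, +/- ppm.
#' @param msms_min Minimum MS/MS score to pass the fragment filter, %.
#' @return A `match_tolerances` list.
#' @export
match_tolerances <- function(ppm = 20, rt = 0.3, ccs_pct = 2, ccs_abs = 4,
                             isotope_min = 80, fragment_ppm = 20,
                             msms_min = 10) {
  vals <- c(ppm = ppm, rt = rt, ccs_pct = ccs_pct, ccs_abs = ccs_abs,
            isotope_min = isotope_min, fragment_ppm = fragment_ppm)
  if (any(vals <= 0)) stop("all tolerances must be strictly positive",
                           call. = FALSE)
  if (msms_min < 0) stop("`msms_min` must be >= 0", call. = FALSE)
  structure(list(ppm = ppm, rt = rt, ccs_pct = ccs_pct, ccs_abs = ccs_abs,
                 isotope_min = isotope_min, fragment_ppm = fragment_ppm,
                 msms_min = msms_min),
            class = "match_tolerances")
}

assert_pattern <- function(p, arg) {
  if (length(p) < 2 || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6) {
    stop("`", arg, "` must be a normalized isotope pattern (length >= 2, ",
         "entries in [0,1], summing to 1)", call. = FALSE)
  }
}

#' Isotope-pattern similarity
#'
#' `100 * (1 - 0.5 * sum(|p_i - q_i|))` over patterns padded with zeros to a
#' common length; 100 for identical patterns, 0 for disjoint ones.
#'
#' @param observed,theoretical Normalized relative-abundance vectors.
#' @return Similarity in percent.
#' @export
isotope_similarity <- function(observed, theoretical) {
  assert_pattern(observed, "observed")
  assert_pattern(theoretical, "theoretical")
  n <- max(length(observed), length(theoretical))
  p <- c(observed, numeric(n - length(observed)))
  q <- c(theoretical, numeric(n - length(theoretical)))
  100 * (1 - 0.5 * sum(abs(p - q)))
}

#' Fragment-spectrum match score
#'
#' Intensity-weighted fraction of the reference spectrum recovered by the
#' observed fragments: reference peaks are taken in decreasing intensity and
#' greedily paired to the nearest unused observed peak within
#' `+/- fragment_ppm`; the score is 100 times the matched share of total
#' reference intensity.
#'
#' @param observed,reference Peak tables with columns `mz`, `intensity`.
#' @param fragment_ppm Product-ion mass tolerance, ppm.
#' @return Score in percent.
#' @export
msms_score <- function(observed, reference, fragment_ppm = 20) {
  if (is.null(reference) || nrow(reference) == 0) {
    stop("`reference` spectrum must contain at least one peak", call. = FALSE)
  }
  if (is.null(observed) || nrow(observed) == 0) return(0)
  ord <- order(-reference$intensity, reference$mz)
  used <- rep(FALSE, nrow(observed))
  matched <- 0
  for (i in ord) {
    dppm <- abs(1e6 * (observed$mz - reference$mz[i]) / reference$mz[i])
    ok <- which(!used & dppm <= fragment_ppm)
    if (length(ok) > 0) {
      pick <- ok[which.min(dppm[ok])]
      used[pick] <- TRUE
      matched <- matched + reference$intensity[i]
    }
  }
  100 * matched / sum(reference$intensity)
}

#' Dual CCS tolerance check
#'
#' A CCS deviation passes when either `|delta_pct| <= ccs_pct` or
#' `|delta_abs| <= ccs_abs` (both bounds inclusive).
#'
#' @param dccs A deviation tibble from [delta_ccs()] (vectorized over rows).
#' @param tol A [match_tolerances()] object.
#' @return Logical vector.
#' @export
ccs_within_tolerance <- function(dccs, tol = match_tolerances()) {
  abs(dccs$delta_pct) <= tol$ccs_pct | abs(dccs$delta_abs) <= tol$ccs_abs
}

feature_field <- function(feature, name) {
  x <- feature[[name]]
  if (is.null(x)) return(NULL)
  if (is.list(x)) x <- x[[1]]
  if (length(x) == 0 || (is.atomic(x) && length(x) == 1 && is.na(x))) {
    return(NULL)
  }
  x
}

all_match_dimensions <- c("mz", "isotope", "rt", "msms", "ccs")

#' Generate library candidates for one feature
#'
#' Compares a detected ion against every same-mode record of a 4D library
#' and keeps the records that pass every requested dimension filter. Deltas
#' and subscores are populated for every dimension available on both sides;
#' a requested dimension that is missing from the feature (no isotope
#' envelope, no fragments, no CCS) or from a record (no reference spectrum,
#' no CCS) is skipped for the affected comparisons rather than failed, and
#' the skipped dimensions are recorded in the `dimensions_used` column.
#'
#' @param feature A one-row feature tibble (see [simulate_features()]) or a
#'   named list with at least `mode` and `mz`, optionally `rt`, `ccs`,
#'   `isotopes` (normalized envelope) and `fragments` (peak tibble).
#' @param library A library tibble.
#' @param tol A [match_tolerances()] object.
#' @param dimensions Dimensions to filter on, a subset of
#'   `c("mz", "isotope", "rt", "msms", "ccs")`.
#' @return A ranked candidate tibble (one row per passing record) with
#'   per-dimension deltas, subscores, `composite`, `msi_level`, `rank` and
#'   `dimensions_used`.
#' @export
generate_candidates <- function(feature, library, tol = match_tolerances(),
                                dimensions = all_match_dimensions) {
  if (length(dimensions) == 0) {
    stop("`dimensions` must contain at least one of ",
         paste(all_match_dimensions, collapse = ", "), call. = FALSE)
  }
  dimensions <- match.arg(dimensions, all_match_dimensions, several.ok = TRUE)
  f_mode <- feature_field(feature, "mode")
  f_mz <- feature_field(feature, "mz")
  f_rt <- feature_field(feature, "rt")
  f_ccs <- feature_field(feature, "ccs")
  f_iso <- feature_field(feature, "isotopes")
  f_frag <- feature_field(feature, "fragments")
  stopifnot(!is.null(f_mode), !is.null(f_mz))

  recs <- library[library$mode == f_mode, , drop = FALSE]
  out <- empty_candidates()
  if (nrow(recs) == 0) return(out)

  skipped <- character()
  if ("isotope" %in% dimensions && is.null(f_iso)) skipped <- c(skipped, "isotope")
  if ("rt" %in% dimensions && is.null(f_rt)) skipped <- c(skipped, "rt")
  if ("msms" %in% dimensions && is.null(f_frag)) skipped <- c(skipped, "msms")
  if ("ccs" %in% dimensions && is.null(f_ccs)) skipped <- c(skipped, "ccs")
  if (length(skipped) > 0) {
    attr(out, "dimensions_skipped") <- skipped
  }

  rows <- lapply(seq_len(nrow(recs)), function(i) {
    rec <- recs[i, ]
    dppm <- ppm_error(f_mz, rec$mz)
    pass_mz <- abs(dppm) <= tol$ppm
    used <- "mz"

    iso_sim <- NA_real_
    pass_iso <- NA
    if (!is.null(f_iso)) {
      theo <- isotope_pattern(rec$formula, n_peaks = max(2L, length(f_iso)))
      iso_sim <- isotope_similarity(f_iso, theo)
      pass_iso <- iso_sim >= tol$isotope_min
      used <- c(used, "isotope")
    }

    drt <- NA_real_
    pass_rt <- NA
    if (!is.null(f_rt) && !is.na(rec$rt)) {
      drt <- f_rt - rec$rt
      pass_rt <- abs(drt) <= tol$rt
      used <- c(used, "rt")
    }

    ms_score <- NA_real_
    pass_msms <- NA
    ref_spec <- rec$spectrum[[1]]
    if (!is.null(f_frag) && !is.null(ref_spec) && nrow(ref_spec) > 0) {
      ms_score <- msms_score(f_frag, ref_spec, tol$fragment_ppm)
      pass_msms <- ms_score >= tol$msms_min & ms_score > 0
      used <- c(used, "msms")
    }

    d_abs <- NA_real_
    d_pct <- NA_real_
    pass_ccs <- NA
    if (!is.null(f_ccs) && !is.na(rec$ccs)) {
      dev <- delta_ccs(f_ccs, rec$ccs)
      d_abs <- dev$delta_abs
      d_pct <- dev$delta_pct
      pass_ccs <- ccs_within_tolerance(dev, tol)
      used <- c(used, "ccs")
    }

    keep <- pass_mz &&
      (!"isotope" %in% dimensions || !isFALSE(pass_iso)) &&
      (!"rt" %in% dimensions || !isFALSE(pass_rt)) &&
      (!"msms" %in% dimensions || !isFALSE(pass_msms)) &&
      (!"ccs" %in% dimensions || !isFALSE(pass_ccs))
    if (!keep) return(NULL)

    subs <- candidate_subscores(dppm, drt, d_pct, iso_sim, ms_score, tol)
    tibble::tibble(
      name = rec$name, hmdb_id = rec$hmdb_id, adduct = rec$adduct,
      mode = rec$mode, record_mz = rec$mz, record_rt = rec$rt,
      record_ccs = rec$ccs,
      authentic_standard = rec$authentic_standard,
      dppm = dppm, drt = drt, delta_ccs_abs = d_abs, delta_ccs_pct = d_pct,
      isotope_similarity = iso_sim, msms_score = ms_score,
      sub_mz = subs["mz"], sub_rt = subs["rt"], sub_ccs = subs["ccs"],
      sub_isotope = subs["isotope"], sub_msms = subs["msms"],
      composite = mean(subs, na.rm = TRUE),
      passed_mz = pass_mz, passed_isotope = pass_iso, passed_rt = pass_rt,
      passed_msms = pass_msms, passed_ccs = pass_ccs,
      dimensions_used = paste(used, collapse = "+")
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(out)
  cands <- dplyr::bind_rows(rows)
  cands$msi_level <- assign_msi_level(cands)
  ranked <- rank_candidates(cands)
  attr(ranked, "dimensions_skipped") <- skipped
  ranked
}

empty_candidates <- function() {
  tibble::tibble(
    name = character(), hmdb_id = character(), adduct = character(),
    mode = character(), record_mz = numeric(), record_rt = numeric(),
    record_ccs = numeric(), authentic_standard = logical(),
    dppm = numeric(), drt = numeric(), delta_ccs_abs = numeric(),
    delta_ccs_pct = numeric(), isotope_similarity = numeric(),
    msms_score = numeric(), sub_mz = numeric(), sub_rt = numeric(),
    sub_ccs = numeric(), sub_isotope = numeric(), sub_msms = numeric(),
    composite = numeric(), passed_mz = logical(), passed_isotope = logical(),
    passed_rt = logical(), passed_msms = logical(), passed_ccs = logical(),
    dimensions_used = character(), msi_level = integer(), rank = integer()
  )
}

candidate_subscores <- function(dppm, drt, delta_pct, iso_sim, ms_score, tol) {
  clamp <- function(x) pmin(pmax(x, 0), 100)
  c(
    mz = clamp(100 * (1 - abs(dppm) / tol$ppm)),
    rt = if (is.na(drt)) NA_real_ else clamp(100 * (1 - abs(drt) / tol$rt)),
    ccs = if (is.na(delta_pct)) NA_real_ else {
      clamp(100 * (1 - min(abs(delta_pct) / tol$ccs_pct, 1)))
    },
    isotope = if (is.na(iso_sim)) NA_real_ else clamp(iso_sim),
    msms = if (is.na(ms_score)) NA_real_ else clamp(ms_score)
  )
}

#' Composite identification score
#'
#' Equal-weight arithmetic mean of the available dimension subscores: the
#' mass subscore is `100 * (1 - |dppm| / ppm_tol)`, RT
#' `100 * (1 - |drt| / rt_tol)`, CCS `100 * (1 - min(|dCCS%| / ccs_pct, 1))`,
#' and the isotope-similarity and MS/MS scores enter unchanged; every
#' subscore is clamped to [0, 100]. Transparent by design: vendor
#' identification scores are proprietary and are carried only as annotations.
#'
#' @param candidates A candidate tibble from [generate_candidates()].
#' @param tol A [match_tolerances()] object.
#' @return Numeric vector of composite scores in [0, 100].
#' @export
composite_score <- function(candidates, tol = match_tolerances()) {
  vapply(seq_len(nrow(candidates)), function(i) {
    subs <- candidate_subscores(
      candidates$dppm[i], candidates$drt[i], candidates$delta_ccs_pct[i],
      candidates$isotope_similarity[i], candidates$msms_score[i], tol
    )
    if (all(is.na(subs))) stop("candidate has no available subscores",
                               call. = FALSE)
    mean(subs, na.rm = TRUE)
  }, numeric(1))
}

#' Rank candidates deterministically
#'
#' Descending composite score; ties broken by ascending |dppm|, then by
#' compound name, so the order never depends on input order.
#'
#' @param candidates A candidate tibble.
#' @return The tibble sorted, with a `rank` column.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0) {
    candidates$rank <- integer()
    return(candidates)
  }
  out <- dplyr::arrange(candidates, dplyr::desc(.data$composite),
                        abs(.data$dppm), .data$name)
  out$rank <- seq_len(nrow(out))
  out
}

#' Assign MSI identification confidence levels
#'
#' Level 1 requires a match to an authentic standard on at least two
#' orthogonal properties beyond accurate mass measured in the same
#' laboratory: m/z and RT passed plus at least one of MS/MS or CCS. Level 2
#' is a fragment-spectrum match that does not meet the level-1 requirement
#' (e.g. an in-silico or external reference). Level 3 is an accurate-mass
#' (+ isotope) match only, and level 4 anything weaker.
#'
#' @param candidates A candidate tibble with `passed_*` columns and
#'   `authentic_standard`.
#' @return Integer vector of levels (1-4).
#' @export
assign_msi_level <- function(candidates) {
  n <- nrow(candidates)
  vapply(seq_len(n), function(i) {
    p <- function(col) isTRUE(candidates[[col]][i])
    level1 <- isTRUE(candidates$authentic_standard[i]) && p("passed_mz") &&
      p("passed_rt") && (p("passed_msms") || p("passed_ccs"))
    if (level1) return(1L)
    if (p("passed_mz") && p("passed_msms")) return(2L)
    if (p("passed_mz") && p("passed_isotope")) return(3L)
    4L
  }, integer(1))
}

#' Cumulative identification funnel for one feature
#'
#' Applies the matching criteria cumulatively -- (m/z + isotope), then + RT,
#' then + MS/MS, then + CCS -- and reports the candidate count after each
#' stage together with the top-ranked surviving candidate. Dimensions absent
#' from the feature are skipped, so their stage repeats the previous count.
#'
#' @param feature A feature (as in [generate_candidates()]).
#' @param library A library tibble.
#' @param tol A [match_tolerances()] object.
#' @return A `funnel_report` with elements `stages` (tibble `stage`,
#'   `criteria`, `n_candidates`), `candidates` (ranked survivors of the last
#'   stage), `all_candidates` (ranked stage-1 set with per-dimension pass
#'   flags) and `top_candidate` (one-row tibble or `NULL`).
#' @export
annotation_funnel <- function(feature, library, tol = match_tolerances()) {
  stage_dims <- list(
    c("mz", "isotope"),
    c("mz", "isotope", "rt"),
    c("mz", "isotope", "rt", "msms"),
    c("mz", "isotope", "rt", "msms", "ccs")
  )
  criteria <- c("m/z + isotope", "+ RT", "+ MS/MS", "+ CCS")
  sets <- lapply(stage_dims, function(d) {
    generate_candidates(feature, library, tol, dimensions = d)
  })
  stages <- tibble::tibble(
    stage = seq_along(sets),
    criteria = criteria,
    n_candidates = vapply(sets, nrow, integer(1))
  )
  final <- sets[[length(sets)]]
  structure(
    list(
      stages = stages,
      candidates = final,
      all_candidates = sets[[1]],
      top_candidate = if (nrow(final) > 0) final[1, ] else NULL
    ),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Identification funnel\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  stage %d (%-13s): %d candidate(s)\n", x$stages$stage[i],
                x$stages$criteria[i], x$stages$n_candidates[i]))
  }
  if (!is.null(x$top_candidate)) {
    cat(sprintf("  top candidate: %s (%s, composite %.1f, MSI level %d)\n",
                x$top_candidate$name, x$top_candidate$adduct,
                x$top_candidate$composite, x$top_candidate$msi_level))
  } else {
    cat("  no candidate survived all criteria\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.funnel_report <- function(x, ...) {
  x$stages
}

#' @exportS3Method ggplot2::autoplot
autoplot.funnel_report <- function(object, ...) {
  df <- object$stages
  df$criteria <- factor(df$criteria, levels = df$criteria)
  ggplot2::ggplot(df, ggplot2::aes(.data$criteria, .data$n_candidates)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_candidates),
                       vjust = -0.4) +
    ggplot2::labs(x = "cumulative matching criteria", y = "candidates")
}
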