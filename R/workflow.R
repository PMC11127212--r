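# Feature-table IO, run configuration and the end-to-end annotation
# workflow: features in, ranked matches + per-feature funnels + run summary
# out, with deterministic formatting so reruns are byte-identical.

#' Read / write feature tables
#'
#' Delimited text with columns `feature_id`, `mode`, `mz`, `rt_min`,
#' `intensity`, plus either `ccs_A2` or `drift_time_ms`; optional `isotopes`
#' (semicolon-joined `shift:fraction` pairs) and `msp_key` resolving
#' fragment spectra from a sidecar MSP file.
#'
#' @param path Feature table path.
#' @param msp_path Optional sidecar MSP path; defaults to `path` with
#'   extension `.msp` when present.
#' @return A feature tibble (see [simulate_features()]).
#' @export
read_features <- function(path, msp_path = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("feature_id", "mode", "mz", "rt_min", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("feature table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!any(c("ccs_A2", "drift_time_ms") %in% names(df))) {
    stop("feature table needs `ccs_A2` or `drift_time_ms`", call. = FALSE)
  }
  n <- nrow(df)
  if (is.null(msp_path)) {
    candidate <- sub("\\.[A-Za-z]+$", ".msp", path)
    if (file.exists(candidate)) msp_path <- candidate
  }
  spectra <- if (!is.null(msp_path)) read_msp(msp_path) else list()
  isotopes <- if ("isotopes" %in% names(df)) {
    lapply(df$isotopes, parse_isotope_string)
  } else {
    rep(list(NULL), n)
  }
  fragments <- if ("msp_key" %in% names(df)) {
    lapply(df$msp_key, function(k) {
      if (is.na(k) || k == "") return(NULL)
      sp <- spectra[[k]]
      if (is.null(sp)) stop("msp_key '", k, "' not found in MSP file",
                            call. = FALSE)
      sp$peaks
    })
  } else {
    rep(list(NULL), n)
  }
  tibble::tibble(
    feature_id = as.character(df$feature_id), mode = df$mode, mz = df$mz,
    rt = df$rt_min,
    ccs = if ("ccs_A2" %in% names(df)) df$ccs_A2 else NA_real_,
    drift_time = if ("drift_time_ms" %in% names(df)) df$drift_time_ms
                 else NA_real_,
    intensity = df$intensity, isotopes = isotopes, fragments = fragments
  )
}

parse_isotope_string <- function(x) {
  if (is.na(x) || x == "") return(NULL)
  parts <- strsplit(strsplit(x, ";")[[1]], ":")
  shifts <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  fracs <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  out <- numeric(max(shifts) + 1L)
  out[shifts + 1L] <- fracs
  if (sum(out) <= 0) stop("isotope envelope has no abundance", call. = FALSE)
  out / sum(out)  # undo serialization rounding
}

format_isotope_string <- function(p) {
  if (is.null(p)) return("")
  paste(sprintf("%d:%.8f", seq_along(p) - 1L, p), collapse = ";")
}

#' @rdname read_features
#' @param features A feature tibble.
#' @export
write_features <- function(features, path, msp_path = NULL) {
  has_frag <- !vapply(features$fragments, is.null, logical(1))
  keys <- ifelse(has_frag, paste0(features$feature_id, "|fragments"), "")
  out <- tibble::tibble(
    feature_id = features$feature_id, mode = features$mode,
    mz = round(features$mz, 4), rt_min = round(features$rt, 2),
    ccs_A2 = round(features$ccs, 2),
    intensity = round(features$intensity, 1),
    isotopes = vapply(features$isotopes, format_isotope_string, character(1)),
    msp_key = keys
  )
  truth <- intersect(c("true_name", "true_hmdb_id", "true_adduct"),
                     names(features))
  for (col in truth) out[[col]] <- features[[col]]
  readr::write_csv(out, path, na = "")
  if (any(has_frag)) {
    if (is.null(msp_path)) msp_path <- sub("\\.[A-Za-z]+$", ".msp", path)
    spectra <- lapply(which(has_frag), function(i) {
      list(peaks = features$fragments[[i]], precursor_mz = features$mz[i],
           source = "measured")
    })
    names(spectra) <- keys[has_frag]
    write_msp(spectra, msp_path)
  }
  invisible(path)
}

#' Read a plain-text key-value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized keys:
#' `library`, `features`, `out_matches`, `out_funnel`, `calibrants`,
#' `edc_coefficient`, `gas_mass`, `seed`, and every [match_tolerances()]
#' field (`ppm`, `rt`, `ccs_pct`, `ccs_abs`, `isotope_min`, `fragment_ppm`,
#' `msms_min`). Unspecified tolerances keep their defaults, so a minimal
#' configuration reproduces the standard search criteria.
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (line in lines) {
    if (!grepl("=", line, fixed = TRUE)) {
      stop("malformed configuration line: '", line, "'", call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", line))
    value <- trimws(sub("^[^=]*=", "", line))
    num <- suppressWarnings(as.numeric(value))
    out[[key]] <- if (!is.na(num)) num else value
  }
  out
}

#' Run the end-to-end annotation workflow
#'
#' For every feature: convert drift time to CCS when a calibration is
#' supplied, generate and rank 4D candidates, run the cumulative
#' identification funnel, and assemble a run-level summary (identifications
#' per MSI level and per mode). Optionally writes the match table (CSV, with
#' m/z to 4 decimals, RT/CCS and scores to 2) and the per-feature funnel
#' counts (JSON); identical inputs and configuration give byte-identical
#' outputs.
#'
#' @param features A feature tibble or path to a feature table.
#' @param library A library tibble or path to a library CSV.
#' @param tol A [match_tolerances()] object.
#' @param calibration Optional `ccs_calibration`, used when features carry
#'   drift times but no CCS.
#' @param out_matches,out_funnel Optional output paths.
#' @return A list with `matches` (ranked candidate tibble over all
#'   features), `funnels` (named list of `funnel_report`s) and `summary`
#'   (tibble of identification counts).
#' @export
run_annotate_workflow <- function(features, library,
                                  tol = match_tolerances(),
                                  calibration = NULL,
                                  out_matches = NULL, out_funnel = NULL) {
  if (is.character(library)) library <- read_library(library)
  if (is.character(features)) features <- read_features(features)
  validate_library(library)

  if (nrow(features) > 0 && "drift_time" %in% names(features)) {
    needs_ccs <- is.na(features$ccs) & !is.na(features$drift_time)
    if (any(needs_ccs)) {
      if (is.null(calibration)) {
        stop("features carry drift times but no CCS; a `calibration` is ",
             "required", call. = FALSE)
      }
      features$ccs[needs_ccs] <- drift_to_ccs(
        calibration, features$drift_time[needs_ccs], features$mz[needs_ccs]
      )
    }
  }

  ord <- order(features$feature_id)
  features <- features[ord, ]
  funnels <- list()
  match_rows <- list()
  for (i in seq_len(nrow(features))) {
    feat <- features[i, ]
    rep <- annotation_funnel(feat, library, tol)
    funnels[[feat$feature_id]] <- rep
    if (nrow(rep$candidates) > 0) {
      match_rows[[feat$feature_id]] <-
        dplyr::bind_cols(tibble::tibble(feature_id = feat$feature_id),
                         rep$candidates)
    }
  }
  matches <- if (length(match_rows) > 0) dplyr::bind_rows(match_rows) else {
    dplyr::bind_cols(tibble::tibble(feature_id = character()),
                     empty_candidates())
  }

  summary <- if (nrow(matches) > 0) {
    top <- matches[matches$rank == 1, ]
    top |>
      dplyr::count(.data$mode, .data$msi_level, name = "n_features") |>
      dplyr::arrange(.data$mode, .data$msi_level)
  } else {
    tibble::tibble(mode = character(), msi_level = integer(),
                   n_features = integer())
  }

  if (!is.null(out_matches)) write_match_table(matches, out_matches)
  if (!is.null(out_funnel)) write_funnel_json(funnels, out_funnel)
  list(matches = matches, funnels = funnels, summary = summary)
}

write_match_table <- function(matches, path) {
  out <- matches
  for (col in c("record_mz", "dppm")) out[[col]] <- round(out[[col]], 4)
  for (col in c("record_rt", "record_ccs", "drt", "delta_ccs_abs",
                "delta_ccs_pct", "isotope_similarity", "msms_score",
                "sub_mz", "sub_rt", "sub_ccs", "sub_isotope", "sub_msms",
                "composite")) {
    out[[col]] <- round(out[[col]], 2)
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

write_funnel_json <- function(funnels, path) {
  payload <- lapply(funnels, function(rep) {
    list(
      stages = stats::setNames(as.list(rep$stages$n_candidates),
                               rep$stages$criteria),
      top_candidate = if (is.null(rep$top_candidate)) NULL else {
        list(name = rep$top_candidate$name,
             adduct = rep$top_candidate$adduct,
             composite = round(rep$top_candidate$composite, 2),
             msi_level = rep$top_candidate$msi_level)
      }
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
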