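# The 4D reference-library data model: one row per (compound, adduct record)
# with m/z, RT, CCS and an optional fragment spectrum in a list-column.
# Fragment spectra are serialized to a sidecar NIST MSP file keyed by
# "hmdb_id|adduct|mode".

library_csv_columns <- c(
  "name", "hmdb_id", "formula", "monoisotopic_mass", "superclass",
  "adduct", "mode", "mz", "rt_min", "ccs_A2", "msp_key", "authentic_standard"
)

annotation_columns <- c(
  "dppm_printed", "drt_printed", "dccs_printed", "score_printed",
  "msms_score_printed", "isotope_similarity_printed"
)

msp_key <- function(hmdb_id, adduct, mode) {
  paste(hmdb_id, adduct, mode, sep = "|")
}

#' Validate a 4D reference library
#'
#' Checks the invariants of a library tibble: every stored monoisotopic mass
#' agrees with the mass recomputed from the formula to within `mass_tol`
#' (rows flagged as decoys are exempt, since mass-shift decoys break formula
#' consistency by design), `(hmdb_id, adduct, mode)` keys are unique, and
#' CCS values, when present, lie in (50, 500) A^2.
#'
#' @param library A library tibble (see [read_library()]).
#' @param mass_tol Maximum |stored - recomputed| mass difference, Da.
#' @return The library, invisibly; errors describe each offending row.
#' @export
validate_library <- function(library, mass_tol = 5e-4) {
  stopifnot(is.data.frame(library), nrow(library) >= 0)
  if (nrow(library) == 0) return(invisible(library))
  decoy <- if ("decoy" %in% names(library)) library$decoy else rep(FALSE, nrow(library))
  decoy[is.na(decoy)] <- FALSE

  recomputed <- monoisotopic_mass(library$formula)
  off <- which(!decoy & abs(recomputed - library$monoisotopic_mass) > mass_tol)
  if (length(off) > 0) {
    stop("stored monoisotopic mass contradicts formula (> ", mass_tol,
         " Da) for: ",
         paste(sprintf("%s [%s] (stored %.4f, computed %.4f)",
                       library$name[off], library$formula[off],
                       library$monoisotopic_mass[off], recomputed[off]),
               collapse = "; "),
         call. = FALSE)
  }
  key <- msp_key(library$hmdb_id, library$adduct, library$mode)
  if (anyDuplicated(key)) {
    stop("duplicate (hmdb_id, adduct, mode) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  has_ccs <- !is.na(library$ccs)
  if (any(has_ccs & (library$ccs <= 50 | library$ccs >= 500))) {
    stop("CCS values must lie in (50, 500) A^2", call. = FALSE)
  }
  if (!all(library$mode %in% c("positive", "negative"))) {
    stop("`mode` must be 'positive' or 'negative'", call. = FALSE)
  }
  invisible(library)
}

empty_library <- function() {
  tibble::tibble(
    name = character(), hmdb_id = character(), formula = character(),
    monoisotopic_mass = numeric(), superclass = character(),
    adduct = character(), mode = character(), mz = numeric(),
    rt = numeric(), ccs = numeric(), spectrum = list(),
    spectrum_source = character(), authentic_standard = logical()
  )
}

#' Read a 4D reference library
#'
#' CSV libraries are flat (one row per adduct record) with fragment spectra
#' resolved from a companion MSP file via the `msp_key` column; JSON
#' libraries carry spectra inline. Entries are validated on read.
#'
#' @param path Path to the library file.
#' @param format `"csv"` or `"json"`.
#' @param msp_path Optional path to the sidecar MSP file (CSV only). Defaults
#'   to `path` with extension `.msp` when that file exists.
#' @return A library tibble with columns `name`, `hmdb_id`, `formula`,
#'   `monoisotopic_mass`, `superclass`, `adduct`, `mode`, `mz`, `rt`, `ccs`,
#'   `spectrum` (list of peak tibbles or `NULL`), `spectrum_source`,
#'   `authentic_standard`, plus any pass-through annotation columns.
#' @export
read_library <- function(path, format = c("csv", "json"), msp_path = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    return(library_from_json(path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  missing <- setdiff(library_csv_columns, names(df))
  if (length(missing) > 0) {
    stop("library missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) return(empty_library())
  if (is.null(msp_path)) {
    candidate <- sub("\\.[A-Za-z]+$", ".msp", path)
    if (file.exists(candidate)) msp_path <- candidate
  }
  spectra <- if (!is.null(msp_path)) read_msp(msp_path) else list()

  key <- ifelse(is.na(df$msp_key) | df$msp_key == "", NA_character_, df$msp_key)
  spectrum <- lapply(key, function(k) {
    if (is.na(k)) return(NULL)
    sp <- spectra[[k]]
    if (is.null(sp)) {
      stop("msp_key '", k, "' not found in MSP file", call. = FALSE)
    }
    sp$peaks
  })
  spectrum_source <- vapply(key, function(k) {
    if (is.na(k)) return(NA_character_)
    src <- spectra[[k]]$source
    if (is.null(src)) "measured" else src
  }, character(1), USE.NAMES = FALSE)

  lib <- tibble::tibble(
    name = df$name, hmdb_id = df$hmdb_id, formula = df$formula,
    monoisotopic_mass = df$monoisotopic_mass, superclass = df$superclass,
    adduct = df$adduct, mode = df$mode, mz = df$mz, rt = df$rt_min,
    ccs = df$ccs_A2, spectrum = spectrum, spectrum_source = spectrum_source,
    authentic_standard = as.logical(df$authentic_standard)
  )
  extra <- intersect(c(annotation_columns, "decoy"), names(df))
  for (col in extra) lib[[col]] <- df[[col]]
  validate_library(lib)
  lib
}

#' Write a 4D reference library
#'
#' The inverse of [read_library()]: CSV plus MSP sidecar (written only when
#' at least one record carries a spectrum), or JSON with inline spectra.
#' Reading back reproduces the library field-for-field.
#'
#' @param library A validated library tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param msp_path Sidecar MSP path (CSV only); defaults to `path` with
#'   extension `.msp`.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, format = c("csv", "json"),
                          msp_path = NULL) {
  format <- match.arg(format)
  validate_library(library)
  if (format == "json") {
    library_to_json(library, path)
    return(invisible(path))
  }
  has_spec <- !vapply(library$spectrum, is.null, logical(1))
  keys <- ifelse(has_spec,
                 msp_key(library$hmdb_id, library$adduct, library$mode), "")
  out <- tibble::tibble(
    name = library$name, hmdb_id = library$hmdb_id,
    formula = library$formula,
    monoisotopic_mass = library$monoisotopic_mass,
    superclass = library$superclass, adduct = library$adduct,
    mode = library$mode, mz = library$mz, rt_min = library$rt,
    ccs_A2 = library$ccs, msp_key = keys,
    authentic_standard = library$authentic_standard
  )
  extra <- intersect(c(annotation_columns, "decoy"), names(library))
  for (col in extra) out[[col]] <- library[[col]]
  readr::write_csv(out, path, na = "")
  if (any(has_spec)) {
    if (is.null(msp_path)) msp_path <- sub("\\.[A-Za-z]+$", ".msp", path)
    spectra <- lapply(which(has_spec), function(i) {
      list(peaks = library$spectrum[[i]],
           precursor_mz = library$mz[i],
           source = library$spectrum_source[i])
    })
    names(spectra) <- keys[has_spec]
    write_msp(spectra, msp_path)
  }
  invisible(path)
}

library_to_json <- function(library, path) {
  rows <- lapply(seq_len(nrow(library)), function(i) {
    row <- as.list(library[i, setdiff(names(library), "spectrum")])
    sp <- library$spectrum[[i]]
    if (!is.null(sp)) {
      row$spectrum <- list(mz = sp$mz, intensity = sp$intensity)
    }
    row
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

library_from_json <- function(path) {
  rows <- jsonlite::read_json(path)
  if (length(rows) == 0) return(empty_library())
  one <- function(row) {
    sp <- row$spectrum
    row$spectrum <- NULL
    row <- lapply(row, function(x) if (is.null(x)) NA else x)
    out <- tibble::as_tibble(row)
    out$spectrum <- if (is.null(sp)) list(NULL) else {
      list(tibble::tibble(mz = unlist(sp$mz), intensity = unlist(sp$intensity)))
    }
    out
  }
  lib <- dplyr::bind_rows(lapply(rows, one))
  lib$ccs <- as.numeric(lib$ccs)
  lib$spectrum_source <- as.character(lib$spectrum_source)
  lib <- dplyr::relocate(lib, "spectrum", .after = "ccs")
  validate_library(lib)
  lib
}

#' Read / write NIST MSP fragment-spectrum files
#'
#' Minimal MSP support for the standard `Name:` / `PrecursorMZ:` /
#' `Num Peaks:` block layout used to exchange fragment spectra. A
#' non-standard `Source:` field records whether a spectrum was measured from
#' a standard or generated in silico.
#'
#' @param path MSP file path.
#' @return `read_msp()`: a named list (by `Name`) of lists with elements
#'   `peaks` (tibble `mz`, `intensity`), `precursor_mz`, `source`.
#' @export
read_msp <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^Name:", lines[i])) { i <- i + 1L; next }
    name <- trimws(sub("^Name:", "", lines[i]))
    precursor <- NA_real_
    source <- "measured"
    npeaks <- 0L
    i <- i + 1L
    while (i <= n && !grepl("^Num Peaks:", lines[i])) {
      if (grepl("^PrecursorMZ:", lines[i])) {
        precursor <- as.numeric(trimws(sub("^PrecursorMZ:", "", lines[i])))
      } else if (grepl("^Source:", lines[i])) {
        source <- trimws(sub("^Source:", "", lines[i]))
      }
      i <- i + 1L
    }
    if (i > n) stop("MSP block '", name, "' has no 'Num Peaks:' line",
                    call. = FALSE)
    npeaks <- as.integer(trimws(sub("^Num Peaks:", "", lines[i])))
    peak_lines <- lines[(i + 1L):(i + npeaks)]
    parts <- strsplit(trimws(peak_lines), "[[:space:]]+")
    peaks <- tibble::tibble(
      mz = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
      intensity = vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    )
    peaks <- peaks[order(peaks$mz), ]
    spectra[[name]] <- list(peaks = peaks, precursor_mz = precursor,
                            source = source)
    i <- i + npeaks + 1L
  }
  spectra
}

#' @rdname read_msp
#' @param spectra A named list as returned by `read_msp()`.
#' @export
write_msp <- function(spectra, path) {
  blocks <- vapply(names(spectra), function(key) {
    sp <- spectra[[key]]
    peaks <- sp$peaks[order(sp$peaks$mz), ]
    paste0(
      "Name: ", key, "\n",
      if (!is.null(sp$precursor_mz) && !is.na(sp$precursor_mz)) {
        sprintf("PrecursorMZ: %.4f\n", sp$precursor_mz)
      } else "",
      if (!is.null(sp$source) && !is.na(sp$source)) {
        paste0("Source: ", sp$source, "\n")
      } else "",
      "Num Peaks: ", nrow(peaks), "\n",
      paste(sprintf("%.4f %.1f", peaks$mz, peaks$intensity), collapse = "\n"),
      "\n"
    )
  }, character(1))
  readr::write_lines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}

#' Packaged reference library of 55 level-1 urinary metabolites
#'
#' The identification results for 55 metabolites confirmed at Metabolomics
#' Standards Initiative confidence level 1 in pooled human urine on a
#' UPLC/TWIMS-QTOF platform (HILIC separation, positive and negative
#' electrospray), transcribed with per-record m/z, retention time, CCS and
#' the originally reported mass error, RT error, CCS error, identification
#' scores and isotope similarities as pass-through annotation columns
#' (`*_printed`). Molecular formulas are taken from the HMDB accessions and
#' verified against the stored monoisotopic masses on load. A few records
#' carry synthetic in-silico fragment spectra used by the worked examples.
#'
#' @return A library tibble (67 adduct records across 55 compounds).
#' @export
#' @examples
#' lib <- urine_reference_library()
#' summarize_library(lib)
urine_reference_library <- function() {
  read_library(ims4d_extdata("urine_library_55.csv"), format = "csv",
               msp_path = ims4d_extdata("urine_library_55.msp"))
}

#' Summarize a 4D reference library
#'
#' Counts entries (distinct compounds), CCS values, records per adduct,
#' entries with at least one record per ionization mode, and entries at or
#' below the very-low-molecular-weight (VLM) threshold.
#'
#' @param library A library tibble.
#' @param vlm_threshold VLM mass cutoff, Da.
#' @return A `library_summary` list with elements `n_entries`,
#'   `n_ccs_values`, `n_positive`, `n_negative`, `n_vlm`, `vlm_threshold`,
#'   `adduct_counts` (tibble) and `mode_counts` (tibble).
#' @export
summarize_library <- function(library, vlm_threshold = 250) {
  if (nrow(library) == 0) {
    return(structure(
      list(n_entries = 0L, n_ccs_values = 0L, n_positive = 0L,
           n_negative = 0L, n_vlm = 0L, vlm_threshold = vlm_threshold,
           adduct_counts = tibble::tibble(adduct = character(), n = integer()),
           mode_counts = tibble::tibble(mode = character(), n = integer())),
      class = "library_summary"
    ))
  }
  entries <- dplyr::distinct(library, .data$hmdb_id,
                             .keep_all = TRUE)
  mode_counts <- library |>
    dplyr::distinct(.data$hmdb_id, .data$mode) |>
    dplyr::count(.data$mode, name = "n")
  n_mode <- function(m) {
    n <- mode_counts$n[mode_counts$mode == m]
    if (length(n) == 0) 0L else as.integer(n)
  }
  structure(
    list(
      n_entries = nrow(entries),
      n_ccs_values = sum(!is.na(library$ccs)),
      n_positive = n_mode("positive"),
      n_negative = n_mode("negative"),
      n_vlm = sum(entries$monoisotopic_mass <= vlm_threshold),
      vlm_threshold = vlm_threshold,
      adduct_counts = dplyr::count(library, .data$adduct, name = "n"),
      mode_counts = mode_counts
    ),
    class = "library_summary"
  )
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf("4D library: %d compounds, %d CCS values\n",
              x$n_entries, x$n_ccs_values))
  cat(sprintf("  positive-mode entries: %d, negative-mode entries: %d\n",
              x$n_positive, x$n_negative))
  cat(sprintf("  VLMs (<= %g Da): %d\n", x$vlm_threshold, x$n_vlm))
  if (nrow(x$adduct_counts) > 0) {
    cat("  records per adduct:\n")
    for (i in seq_len(nrow(x$adduct_counts))) {
      cat(sprintf("    %-12s %d\n", x$adduct_counts$adduct[i],
                  x$adduct_counts$n[i]))
    }
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.library_summary <- function(x, ...) {
  tibble::tibble(
    n_entries = x$n_entries, n_ccs_values = x$n_ccs_values,
    n_positive = x$n_positive, n_negative = x$n_negative,
    n_vlm = x$n_vlm, vlm_threshold = x$vlm_threshold
  )
}
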