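# Seeded generators: noisy features from a library, decoy entries, and the
# packaged tryptophan identification example, so the whole pipeline is
# testable without instrument data.

#' Feature noise model
#'
#' Gaussian noise expressed in the same domains as the matching tolerances
#' (ppm for mass, minutes for RT, percent for CCS), so noise scales relate
#' directly to filter widths. The defaults are half-tolerance noise levels
#' for a well-behaved TWIMS-QTOF acquisition: mass error SD 5 ppm, RT SD
#' 0.075 min, CCS SD 0.5%.
#'
#' @param ppm_sd Mass-error SD, ppm.
#' @param rt_sd RT-error SD, minutes.
#' @param ccs_sd_pct Multiplicative CCS-error SD, %.
#' @param intensity_log_sd SD of log-intensity.
#' @param fragment_dropout Probability that an individual fragment peak is
#'   missing from a feature's spectrum.
#' @param seed Optional integer seed; generation is deterministic given it.
#' @return A `noise_model` list.
#' @export
noise_model <- function(ppm_sd = 5, rt_sd = 0.075, ccs_sd_pct = 0.5,
                        intensity_log_sd = 0.5, fragment_dropout = 0,
                        seed = NULL) {
  stopifnot(ppm_sd >= 0, rt_sd >= 0, ccs_sd_pct >= 0, intensity_log_sd >= 0,
            fragment_dropout >= 0, fragment_dropout <= 1)
  structure(list(ppm_sd = ppm_sd, rt_sd = rt_sd, ccs_sd_pct = ccs_sd_pct,
                 intensity_log_sd = intensity_log_sd,
                 fragment_dropout = fragment_dropout, seed = seed),
            class = "noise_model")
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate features from a 4D library
#'
#' Draws `n_per_record` features from every library record: m/z is
#' perturbed by `Normal(0, ppm_sd)` in ppm, RT by `Normal(0, rt_sd)`
#' minutes, CCS multiplicatively by `Normal(0, ccs_sd_pct / 100)`; the
#' isotope envelope is the theoretical pattern of the record's formula and
#' fragments are copied from the record's spectrum with per-peak dropout.
#' Ground-truth columns (`true_name`, `true_hmdb_id`, `true_adduct`) make
#' recovery experiments self-scoring.
#'
#' @param library A library tibble.
#' @param n_per_record Features drawn per library record.
#' @param noise A [noise_model()].
#' @return A feature tibble: `feature_id`, `mode`, `mz`, `rt`, `ccs`,
#'   `intensity`, `isotopes` (list), `fragments` (list), truth columns.
#' @export
simulate_features <- function(library, n_per_record = 1,
                              noise = noise_model()) {
  if (n_per_record < 0) stop("`n_per_record` must be >= 0", call. = FALSE)
  if (nrow(library) == 0 || n_per_record == 0) {
    return(tibble::tibble(
      feature_id = character(), mode = character(), mz = numeric(),
      rt = numeric(), ccs = numeric(), intensity = numeric(),
      isotopes = list(), fragments = list(), true_name = character(),
      true_hmdb_id = character(), true_adduct = character()
    ))
  }
  with_local_seed(noise$seed, {
    idx <- rep(seq_len(nrow(library)), each = n_per_record)
    n <- length(idx)
    rec <- library[idx, ]
    mz <- rec$mz * (1 + stats::rnorm(n, 0, noise$ppm_sd) / 1e6)
    rt <- pmax(rec$rt + stats::rnorm(n, 0, noise$rt_sd), 0)
    ccs <- rec$ccs * (1 + stats::rnorm(n, 0, noise$ccs_sd_pct / 100))
    intensity <- 1e5 * exp(stats::rnorm(n, 0, noise$intensity_log_sd))
    isotopes <- lapply(rec$formula, isotope_pattern, n_peaks = 4)
    fragments <- lapply(seq_len(n), function(i) {
      sp <- rec$spectrum[[i]]
      if (is.null(sp)) return(NULL)
      if (noise$fragment_dropout > 0) {
        keep <- stats::runif(nrow(sp)) >= noise$fragment_dropout
        sp <- sp[keep, , drop = FALSE]
        if (nrow(sp) == 0) return(NULL)
      }
      sp
    })
    tibble::tibble(
      feature_id = sprintf("F%05d", seq_len(n)),
      mode = rec$mode, mz = mz, rt = rt, ccs = ccs, intensity = intensity,
      isotopes = isotopes, fragments = fragments,
      true_name = rec$name, true_hmdb_id = rec$hmdb_id,
      true_adduct = rec$adduct
    )
  })
}

#' Generate decoy library entries
#'
#' Decoys stress-test the matching engine: `"mz_shift"` adds `magnitude` Da
#' to every record m/z while keeping the formula (breaking mass/formula
#' consistency on purpose, so decoys carry a `decoy` marker that exempts
#' them from mass validation); `"isomer"` keeps formula and m/z but moves RT
#' by `+3 * rt_sd` and CCS upward far enough to fail both CCS tolerance
#' branches (at least 3% and more than the absolute tolerance window), and
#' drops the reference spectrum (an isomer need not share fragmentation).
#'
#' @param library A library tibble.
#' @param strategy `"mz_shift"` or `"isomer"`.
#' @param magnitude Mass shift for `"mz_shift"`, Da.
#' @param noise A [noise_model()] supplying `rt_sd` for `"isomer"`.
#' @return A library tibble of decoys with `decoy = TRUE`.
#' @export
make_decoys <- function(library, strategy = c("mz_shift", "isomer"),
                        magnitude = 0.01, noise = noise_model()) {
  strategy <- match.arg(strategy)
  if (nrow(library) == 0) {
    out <- library
    out$decoy <- logical(0)
    return(out)
  }
  out <- library
  out$name <- paste0(library$name, " (decoy)")
  out$hmdb_id <- paste0(library$hmdb_id, "-DECOY")
  out$authentic_standard <- FALSE
  out$decoy <- TRUE
  if (strategy == "mz_shift") {
    out$mz <- library$mz + magnitude
  } else {
    out$rt <- library$rt + 3 * noise$rt_sd
    out$ccs <- library$ccs + pmax(0.03 * library$ccs, 4.5)
    out$spectrum <- rep(list(NULL), nrow(out))
    out$spectrum_source <- NA_character_
  }
  out
}

trp_fragments <- function() {
  tibble::tibble(
    mz = c(115.0542, 118.0651, 144.0808, 146.0600, 188.0706),
    intensity = c(20, 45, 35, 100, 60)
  )
}

#' Packaged tryptophan identification example
#'
#' A self-contained worked example of the cumulative 4D identification
#' funnel: one positive-mode urinary feature (m/z 205.0968, RT 5.71 min,
#' CCS 147.31 A^2, tryptophan fragment spectrum and isotope envelope) and a
#' ten-candidate library in which all ten records pass the accurate-mass,
#' isotope and RT criteria, five survive fragment matching
#' (glycyl-phenylalanine and phenylalanyl-glycine as water-loss ions, plus
#' the three tryptophan stereo-forms), and only l-tryptophan falls inside
#' the CCS tolerance. The five fragment-failing isobars are synthetic
#' constructs (flagged by `SYN` accessions and named "synthetic isobar");
#' all fragment spectra are in-silico stand-ins.
#'
#' @return A list with elements `feature` (one-row feature tibble) and
#'   `library` (10-record library tibble).
#' @export
#' @examples
#' ex <- tryptophan_funnel_example()
#' annotation_funnel(ex$feature, ex$library)
tryptophan_funnel_example <- function() {
  trp_mass <- monoisotopic_mass("C11H12N2O2")
  dipep_mass <- monoisotopic_mass("C11H14N2O3")
  trp <- trp_fragments()
  # fragment sets sharing peaks with the observed spectrum (pass MS/MS)
  glyphe <- tibble::tibble(mz = c(118.0651, 146.0600), intensity = c(40, 80))
  phegly <- tibble::tibble(mz = c(146.0600, 188.0706), intensity = c(50, 50))
  # disjoint fragment sets for the synthetic isobars (fail MS/MS)
  syn_spec <- function(mzs) tibble::tibble(mz = mzs,
                                          intensity = c(100, 40))
  lib <- tibble::tibble(
    name = c("l-Tryptophan", "d-Tryptophan", "(+/-)-Tryptophan",
             "Glycyl-phenylalanine", "Phenylalanyl-glycine",
             paste0("Synthetic isobar ", LETTERS[1:5])),
    hmdb_id = c("HMDB00929", "HMDB13609", "DLTRP-MIX", "HMDB28848",
                "HMDB28995", paste0("SYN000", 1:5)),
    formula = c(rep("C11H12N2O2", 3), rep("C11H14N2O3", 2),
                rep("C11H12N2O2", 5)),
    monoisotopic_mass = c(rep(trp_mass, 3), rep(dipep_mass, 2),
                          rep(trp_mass, 5)),
    superclass = c(rep("organoheterocyclic compounds", 3),
                   rep("organic acids and derivatives", 2),
                   rep("other", 5)),
    adduct = c(rep("[M+H]+", 3), rep("[M+H-H2O]+", 2), rep("[M+H]+", 5)),
    mode = "positive",
    mz = c(205.0968,
           adduct_mz(trp_mass, "[M+H]+"),
           adduct_mz(trp_mass, "[M+H]+"),
           adduct_mz(dipep_mass, "[M+H-H2O]+"),
           adduct_mz(dipep_mass, "[M+H-H2O]+"),
           rep(adduct_mz(trp_mass, "[M+H]+"), 5)),
    rt = c(5.71, 5.80, 5.63, 5.90, 5.55, 5.50, 5.62, 5.75, 5.85, 5.95),
    ccs = c(147.31, 152.80, 153.20, 154.00, 153.60,
            152.50, 153.90, 155.40, 156.80, 158.00),
    spectrum = list(trp, trp, trp, glyphe, phegly,
                    syn_spec(c(91.0542, 65.0386)),
                    syn_spec(c(77.0386, 51.0229)),
                    syn_spec(c(93.0573, 66.0464)),
                    syn_spec(c(80.0495, 53.0386)),
                    syn_spec(c(95.0491, 67.0542))),
    spectrum_source = "in_silico",
    authentic_standard = c(TRUE, TRUE, TRUE, FALSE, FALSE, rep(FALSE, 5))
  )
  validate_library(lib)
  feature <- tibble::tibble(
    feature_id = "URINE-TRP", mode = "positive", mz = 205.0968, rt = 5.71,
    ccs = 147.31, intensity = 1e5,
    isotopes = list(isotope_pattern("C11H12N2O2", 4)),
    fragments = list(trp_fragments())
  )
  list(feature = feature, library = lib)
}
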