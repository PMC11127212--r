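# Independent oracles and small random-instance generators used by the
# property tests. These deliberately re-derive results with different
# algorithms (full enumeration, plain loops) than the package code paths.

# All compositions of n atoms over k isotope slots (k small).
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, nrow = 1))
  out <- list()
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1)
    out[[length(out) + 1]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

# Brute-force isotope pattern by explicit enumeration of every per-element
# isotopologue composition (multinomial probabilities), no truncation during
# accumulation.
oracle_isotope_pattern <- function(formula, n_peaks) {
  counts <- parse_formula(formula)
  iso <- isotope_abundances()
  # start: probability 1 at shift 0
  dist <- c(1)
  for (el in names(counts)) {
    rows <- iso[iso$element == el, ]
    comps <- compositions(counts[[el]], nrow(rows))
    shifts <- as.vector(comps %*% rows$mass_shift)
    probs <- apply(comps, 1, function(cc) {
      stats::dmultinom(cc, prob = rows$abundance)
    })
    el_dist <- numeric(max(shifts) + 1)
    for (i in seq_along(shifts)) {
      el_dist[shifts[i] + 1] <- el_dist[shifts[i] + 1] + probs[i]
    }
    new_dist <- numeric(length(dist) + length(el_dist) - 1)
    for (i in seq_along(dist)) {
      for (j in seq_along(el_dist)) {
        new_dist[i + j - 1] <- new_dist[i + j - 1] + dist[i] * el_dist[j]
      }
    }
    dist <- new_dist
  }
  head_n <- dist[seq_len(min(n_peaks, length(dist)))]
  head_n / sum(head_n)
}

# Independent exhaustive candidate filter: plain loops and explicit
# arithmetic, mirroring the documented filter rules.
oracle_candidate_keys <- function(feature, library, tol, dimensions) {
  keys <- character()
  f_iso <- feature$isotopes[[1]]
  f_frag <- feature$fragments[[1]]
  for (i in seq_len(nrow(library))) {
    rec <- library[i, ]
    if (rec$mode != feature$mode) next
    dppm <- 1e6 * (feature$mz - rec$mz) / rec$mz
    ok <- abs(dppm) <= tol$ppm
    if (ok && "isotope" %in% dimensions && !is.null(f_iso)) {
      theo <- isotope_pattern(rec$formula, n_peaks = length(f_iso))
      sim <- 100 * (1 - 0.5 * sum(abs(f_iso - theo)))
      ok <- sim >= tol$isotope_min
    }
    if (ok && "rt" %in% dimensions && !is.na(feature$rt) && !is.na(rec$rt)) {
      ok <- abs(feature$rt - rec$rt) <= tol$rt
    }
    if (ok && "msms" %in% dimensions && !is.null(f_frag) &&
        !is.null(rec$spectrum[[1]])) {
      score <- oracle_msms_score(f_frag, rec$spectrum[[1]], tol$fragment_ppm)
      ok <- score >= tol$msms_min && score > 0
    }
    if (ok && "ccs" %in% dimensions && !is.na(feature$ccs) &&
        !is.na(rec$ccs)) {
      d_abs <- feature$ccs - rec$ccs
      d_pct <- 100 * d_abs / rec$ccs
      ok <- abs(d_pct) <= tol$ccs_pct || abs(d_abs) <= tol$ccs_abs
    }
    if (ok) keys <- c(keys, paste(rec$hmdb_id, rec$adduct, sep = "|"))
  }
  sort(keys)
}

# Greedy fragment matching re-coded with a while loop over a worklist.
oracle_msms_score <- function(observed, reference, fragment_ppm) {
  order_ref <- order(-reference$intensity, reference$mz)
  available <- rep(TRUE, nrow(observed))
  matched <- 0
  for (i in order_ref) {
    best <- NA
    best_ppm <- Inf
    j <- 1
    while (j <= nrow(observed)) {
      if (available[j]) {
        p <- abs(1e6 * (observed$mz[j] - reference$mz[i]) / reference$mz[i])
        if (p <= fragment_ppm && p < best_ppm) {
          best <- j
          best_ppm <- p
        }
      }
      j <- j + 1
    }
    if (!is.na(best)) {
      available[best] <- FALSE
      matched <- matched + reference$intensity[i]
    }
  }
  100 * matched / sum(reference$intensity)
}

random_formula_pool <- c(
  "C6H12O6", "C5H10O2", "C9H11NO2", "C10H12N2O3", "C4H6O4", "C7H8O",
  "C2H7NO3S", "C5H4N4O", "C11H12N2O2", "C6H13NO2"
)

# A small random library + feature instance for filter-oracle equivalence.
random_match_instance <- function() {
  n <- sample(3:8, 1)
  formulas <- sample(random_formula_pool, n, replace = TRUE)
  masses <- monoisotopic_mass(formulas)
  adducts <- sample(c("[M+H]+", "[M-H]-"), n, replace = TRUE)
  modes <- ifelse(adducts == "[M+H]+", "positive", "negative")
  spectra <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.4) return(NULL)
    k <- sample(2:4, 1)
    tibble::tibble(mz = sort(stats::runif(k, 50, 200)),
                   intensity = stats::runif(k, 10, 100))
  })
  lib <- tibble::tibble(
    name = sprintf("cmpd%02d", seq_len(n)),
    hmdb_id = sprintf("TEST%04d", seq_len(n)),
    formula = formulas,
    monoisotopic_mass = masses,
    superclass = "other",
    adduct = adducts, mode = modes,
    mz = adduct_mz(masses, adducts) * (1 + stats::runif(n, -15, 15) / 1e6),
    rt = stats::runif(n, 0, 12),
    ccs = stats::runif(n, 100, 200),
    spectrum = spectra,
    spectrum_source = "in_silico",
    authentic_standard = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
  base <- lib[sample(n, 1), ]
  frag <- if (is.null(base$spectrum[[1]]) || stats::runif(1) < 0.3) {
    k <- sample(2:4, 1)
    tibble::tibble(mz = sort(stats::runif(k, 50, 200)),
                   intensity = stats::runif(k, 10, 100))
  } else {
    sp <- base$spectrum[[1]]
    keep <- stats::runif(nrow(sp)) < 0.8
    if (!any(keep)) sp else sp[keep, , drop = FALSE]
  }
  feature <- tibble::tibble(
    feature_id = "RAND", mode = base$mode,
    mz = base$mz * (1 + stats::runif(1, -30, 30) / 1e6),
    rt = max(base$rt + stats::runif(1, -0.6, 0.6), 0),
    ccs = base$ccs * (1 + stats::runif(1, -0.06, 0.06)),
    intensity = 1e5,
    isotopes = list(isotope_pattern(sample(random_formula_pool, 1), 4)),
    fragments = list(frag)
  )
  dims <- c("mz", sample(c("isotope", "rt", "msms", "ccs"),
                         sample(0:4, 1)))
  list(feature = feature, library = lib, dimensions = unique(dims))
}

# Synthetic calibrants generated exactly from a known power law, used to
# check that fitting recovers the generating parameters.
make_synthetic_calibrants <- function(A = 400, B = 0.55, edc = 1.41,
                                      gas_mass = 28.0134, n = 8) {
  mz <- seq(120, 800, length.out = n)
  drift <- seq(1.5, 9, length.out = n)
  td <- drift - edc * sqrt(mz) / 1000
  ccs_norm <- A * td^B
  tibble::tibble(
    mz = mz, charge = 1L, drift_time = drift,
    reference_ccs = denormalize_ccs(ccs_norm, mz, 1L, gas_mass)
  )
}

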