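# Chemical-formula arithmetic: parsing, monoisotopic mass, isotope patterns,
# adduct m/z and ppm mass error.

# Physical constants (Da). The proton mass is the H-atom mass minus the
# electron mass; charged adduct deltas are built from these so that computed
# m/z values are exact for singly charged ions.
ELECTRON_MASS <- 0.00054857990907
PROTON_MASS <- 1.00782503207 - ELECTRON_MASS

.ims4d <- new.env(parent = emptyenv())

ims4d_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ims4d")
  if (!nzchar(path)) {
    # during development (pkgload) fall back to source tree
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' Packaged element monoisotopic masses
#'
#' Monoisotopic masses (mass of the most abundant isotope, Da) for the
#' elements supported by [parse_formula()]. Shipped as a plain-text table
#' inside the package and extendable by editing it.
#'
#' @return A tibble with columns `element` and `monoisotopic_mass`.
#' @export
#' @examples
#' element_masses()
element_masses <- function() {
  if (is.null(.ims4d$elements)) {
    .ims4d$elements <- readr::read_tsv(
      ims4d_extdata("elements.tsv"),
      col_types = readr::cols(
        element = readr::col_character(),
        monoisotopic_mass = readr::col_double()
      ),
      progress = FALSE
    )
  }
  .ims4d$elements
}

#' Packaged isotope-abundance table
#'
#' Natural isotopic abundances aggregated by nominal mass shift relative to
#' the principal isotope (fine structure is not resolved).
#'
#' @return A tibble with columns `element`, `mass_shift` and `abundance`.
#' @export
isotope_abundances <- function() {
  if (is.null(.ims4d$isotopes)) {
    .ims4d$isotopes <- readr::read_tsv(
      ims4d_extdata("isotopes.tsv"),
      col_types = readr::cols(
        element = readr::col_character(),
        mass_shift = readr::col_integer(),
        abundance = readr::col_double()
      ),
      progress = FALSE
    )
  }
  .ims4d$isotopes
}

#' Parse a molecular formula in Hill notation
#'
#' Accepts plain element-count tokens (e.g. `"C11H12N2O2"`). Parentheses,
#' charges and isotope labels are not supported: adduct charges are carried by
#' the adduct registry (see [adduct_registry()]), never by the formula.
#'
#' @param text A single non-empty formula string.
#' @return A named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C2H7NO3S")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("`text` must be a single non-empty formula string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(nchar(tokens)) != nchar(text)) {
    stop("malformed formula: ", text, call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  known <- element_masses()$element
  bad <- setdiff(elements, known)
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  storage.mode(out) <- "integer"
  counts_out <- as.integer(out)
  names(counts_out) <- names(out)
  counts_out
}

as_formula_counts <- function(f) {
  if (is.character(f)) {
    return(parse_formula(f))
  }
  if (is.numeric(f) && !is.null(names(f)) && all(nzchar(names(f)))) {
    if (any(f < 1)) stop("element counts must be >= 1", call. = FALSE)
    return(f)
  }
  stop("`formula` must be a formula string or a named count vector", call. = FALSE)
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula A formula string or named element-count vector from
#'   [parse_formula()]. Character input may be a vector of formulas.
#' @return Monoisotopic mass(es) in Da.
#' @export
#' @examples
#' monoisotopic_mass("C11H12N2O2") # l-tryptophan, 204.0899
monoisotopic_mass <- function(formula) {
  if (is.character(formula) && length(formula) > 1) {
    return(vapply(formula, monoisotopic_mass, numeric(1), USE.NAMES = FALSE))
  }
  counts <- as_formula_counts(formula)
  masses <- element_masses()
  idx <- match(names(counts), masses$element)
  sum(counts * masses$monoisotopic_mass[idx])
}

#' Coarse isotope pattern of a molecular formula
#'
#' Computes the isotopologue distribution aggregated by nominal mass shift
#' (M, M+1, M+2, ...) by convolving the per-element isotope distributions
#' (binomial/multinomial expansion), then truncating to `n_peaks` and
#' renormalizing to sum 1. Fine isotopic structure is deliberately not
#' resolved: the pattern feeds the coarse isotope-similarity score used in
#' library matching.
#'
#' @param formula Formula string or named count vector.
#' @param n_peaks Number of isotopologue peaks to keep (2 to 4).
#' @return Numeric vector of relative abundances summing to 1.
#' @export
#' @examples
#' isotope_pattern("C6H12O6", n_peaks = 3)
isotope_pattern <- function(formula, n_peaks = 4) {
  if (!is.numeric(n_peaks) || length(n_peaks) != 1 || n_peaks < 2) {
    stop("`n_peaks` must be a single integer >= 2", call. = FALSE)
  }
  if (n_peaks > 4) stop("`n_peaks` must be <= 4", call. = FALSE)
  n_peaks <- as.integer(n_peaks)
  counts <- as_formula_counts(formula)
  # memoise by formula string: library matching recomputes patterns per record
  cache_key <- if (is.character(formula)) paste0(formula, "#", n_peaks) else NULL
  if (!is.null(cache_key)) {
    if (is.null(.ims4d$pattern_cache)) {
      .ims4d$pattern_cache <- new.env(parent = emptyenv())
    }
    hit <- .ims4d$pattern_cache[[cache_key]]
    if (!is.null(hit)) return(hit)
  }
  iso <- isotope_abundances()

  # distribution of one atom of `el` over nominal shifts 0..n_peaks-1
  atom_dist <- function(el) {
    rows <- iso[iso$element == el, ]
    if (nrow(rows) == 0) stop("no isotope data for element ", el, call. = FALSE)
    d <- numeric(n_peaks)
    for (i in seq_len(nrow(rows))) {
      s <- rows$mass_shift[i] + 1L
      if (s <= n_peaks) d[s] <- d[s] + rows$abundance[i]
      # shifts beyond the window are dropped; renormalization at the end
    }
    d
  }

  conv_trunc <- function(a, b) {
    out <- numeric(n_peaks)
    for (i in seq_len(n_peaks)) {
      j <- seq_len(n_peaks - i + 1L)
      out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    }
    out
  }

  # exponentiation by squaring over truncated convolution
  dist_pow <- function(d, k) {
    result <- c(1, numeric(n_peaks - 1L))
    base <- d
    while (k > 0) {
      if (k %% 2 == 1) result <- conv_trunc(result, base)
      base <- conv_trunc(base, base)
      k <- k %/% 2
    }
    result
  }

  total <- c(1, numeric(n_peaks - 1L))
  for (el in names(counts)) {
    total <- conv_trunc(total, dist_pow(atom_dist(el), counts[[el]]))
  }
  out <- total / sum(total)
  if (!is.null(cache_key)) .ims4d$pattern_cache[[cache_key]] <- out
  out
}

#' Registry of supported ionization adducts
#'
#' Mass deltas follow the charged-species convention: `[M+H]+` adds the
#' proton mass (H atom minus electron), `[M-H]-` subtracts it, `[M+Na]+` adds
#' Na minus an electron, `[M]+` only removes an electron, and composite
#' adducts combine the corresponding atom and electron masses. All species
#' are singly charged.
#'
#' @return A tibble with columns `adduct`, `polarity`, `charge`, `mass_delta`.
#' @export
adduct_registry <- function() {
  h2o <- 2 * 1.00782503207 + 15.9949146196
  tibble::tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+H-H2O]+", "[M]+", "[M-H]-", "[M+Na-2H]-"),
    polarity = c("positive", "positive", "positive", "positive",
                 "negative", "negative"),
    charge = 1L,
    mass_delta = c(
      PROTON_MASS,
      22.9897692809 - ELECTRON_MASS,
      PROTON_MASS - h2o,
      -ELECTRON_MASS,
      -PROTON_MASS,
      22.9897692809 - 2 * 1.00782503207 + ELECTRON_MASS
    )
  )
}

#' m/z of a neutral mass under a given adduct
#'
#' @param neutral_mass Neutral monoisotopic mass(es), Da.
#' @param adduct Adduct name(s) from [adduct_registry()].
#' @return m/z value(s).
#' @export
#' @examples
#' adduct_mz(monoisotopic_mass("C11H12N2O2"), "[M+H]+")
adduct_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0)) stop("`neutral_mass` must be > 0", call. = FALSE)
  reg <- adduct_registry()
  idx <- match(adduct, reg$adduct)
  if (anyNA(idx)) {
    stop("unknown adduct name(s): ",
         paste(unique(adduct[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  (neutral_mass + reg$mass_delta[idx]) / reg$charge[idx]
}

#' Signed relative mass error in parts per million
#'
#' @param measured_mz,theoretical_mz Positive m/z values (vectorized).
#' @return `1e6 * (measured - theoretical) / theoretical`.
#' @export
#' @examples
#' ppm_error(206.0458, adduct_mz(monoisotopic_mass("C10H7NO4"), "[M+H]+"))
ppm_error <- function(measured_mz, theoretical_mz) {
  if (any(measured_mz <= 0) || any(theoretical_mz <= 0)) {
    stop("m/z values must be > 0", call. = FALSE)
  }
  1e6 * (measured_mz - theoretical_mz) / theoretical_mz
}
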