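# Elemental-formula mass engine, linear mass-defect screen and isotope-pattern
# simulation used to flag halogenated molecular features. Polyhalogenation
# pushes the mass defect of a molecule far below that of ordinary CHNO
# metabolites, so a linear window in (mass, defect) space is an effective
# first-pass screen; the simulated isotope envelope (Br/Cl give strong M+2
# signatures) confirms candidates.

# Monoisotopic masses of the most abundant isotope (u), standard reference
# values; and per-element isotopologue distributions on the unit-spaced
# (nominal) offset grid relative to the monoisotopic peak.
.ELEMENTS <- list(
  C  = list(mass = 12.0,          iso = c(`0` = 0.9893,   `1` = 0.0107)),
  H  = list(mass = 1.0078250319,  iso = c(`0` = 0.999885, `1` = 0.000115)),
  N  = list(mass = 14.0030740052, iso = c(`0` = 0.99636,  `1` = 0.00364)),
  O  = list(mass = 15.9949146221, iso = c(`0` = 0.99757,  `1` = 0.00038, `2` = 0.00205)),
  S  = list(mass = 31.97207069,   iso = c(`0` = 0.9499,   `1` = 0.0075,  `2` = 0.0425, `4` = 0.0001)),
  P  = list(mass = 30.97376151,   iso = c(`0` = 1)),
  F  = list(mass = 18.9984032,    iso = c(`0` = 1)),
  Cl = list(mass = 34.96885271,   iso = c(`0` = 0.7576,   `2` = 0.2424)),
  Br = list(mass = 78.9183376,    iso = c(`0` = 0.5069,   `2` = 0.4931)),
  I  = list(mass = 126.904468,    iso = c(`0` = 1))
)

#' Common electrospray adduct mass shifts
#'
#' Named vector of mass shifts (Da) from the neutral monoisotopic mass to the
#' observed ion, for dereplication arithmetic (e.g. `[M+NH4]+`).
#' @export
adducts <- c(
  "[M+H]+"   =  1.00727646,
  "[M+NH4]+" = 18.03382555,
  "[M+Na]+"  = 22.98922070,
  "[M+K]+"   = 38.96315791,
  "[M-H]-"   = -1.00727646,
  "[M+Cl]-"  = 34.96940126
)

#' Parse an elemental formula string
#'
#' Supports C, H, N, O, S, P, Br, Cl, I and F with optional counts, e.g.
#' `"C30H44N2O9S2"`.
#'
#' @param formula character scalar, or an already-parsed named count vector.
#' @return named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C6H6O2")
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
    if (is.null(names(counts))) stop("numeric formula must be a named count vector")
  } else {
    stopifnot(is.character(formula), length(formula) == 1L)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    toks <- toks[nzchar(toks)]
    if (paste(toks, collapse = "") != formula) {
      stop("could not parse formula: ", formula)
    }
    els <- sub("[0-9]*$", "", toks)
    ns <- sub("^[A-Z][a-z]?", "", toks)
    counts <- ifelse(nzchar(ns), as.integer(ns), 1L)
    names(counts) <- els
    counts <- tapply(counts, names(counts), sum)
  }
  bad <- setdiff(names(counts), names(.ELEMENTS))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("element counts must be >= 0")
  if (sum(counts) < 1) stop("formula must contain at least one atom")
  storage.mode(counts) <- "integer"
  counts
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of most-abundant-isotope masses over all atoms.
#'
#' @param formula formula string or named count vector (see [parse_formula()]).
#' @return mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C6H6O2")   # 110.0368
#' monoisotopic_mass("C11H20O4") # 216.1362
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(vapply(names(counts), function(e) .ELEMENTS[[e]]$mass, 0) * counts)
}

#' Mass defect of a measured mass
#'
#' @param mass numeric vector of masses (Da), all > 0.
#' @param definition `"nearest_integer"` (mass − round(mass), in (−0.5, 0.5])
#'   or `"fractional_part"` (mass − floor(mass), in \[0, 1)).
#' @return numeric vector of defects (Da).
#' @export
mass_defect <- function(mass, definition = c("nearest_integer", "fractional_part")) {
  definition <- match.arg(definition)
  stopifnot(all(mass > 0))
  switch(definition,
    nearest_integer = mass - round(mass),
    fractional_part = mass - floor(mass)
  )
}

#' Parameters of the linear mass-defect screening window
#'
#' The expected defect is modelled as a straight line in mass,
#' `expected(m) = intercept + slope * m / 100`, and a feature passes when its
#' defect lies within `tolerance` of the line. Defaults follow the published
#' screen for halogenated Pseudoalteromonas metabolites: intercept 0.0937 Da,
#' slope −0.02 Da per 100 Da, tolerance ±0.0100 Da.
#'
#' @param intercept Da.
#' @param slope Da per 100 Da.
#' @param tolerance Da, > 0.
#' @param defect_definition convention passed to [mass_defect()].
#' @return object of class `mass_defect_params`.
#' @export
mass_defect_params <- function(intercept = 0.0937, slope = -0.02,
                               tolerance = 0.0100,
                               defect_definition = c("nearest_integer", "fractional_part")) {
  stopifnot(tolerance > 0)
  structure(
    list(intercept = intercept, slope = slope, tolerance = tolerance,
         defect_definition = match.arg(defect_definition)),
    class = "mass_defect_params"
  )
}

#' Does a mass fall inside the halogen mass-defect window?
#'
#' @param mass numeric vector of neutral masses (Da).
#' @param params a [mass_defect_params()] object.
#' @return logical vector.
#' @export
#' @examples
#' defect_window_pass(300.0337) # TRUE
#' defect_window_pass(500.0437) # FALSE
defect_window_pass <- function(mass, params = mass_defect_params()) {
  stopifnot(inherits(params, "mass_defect_params"), all(mass > 0))
  expected <- params$intercept + params$slope * mass / 100
  defect <- mass_defect(mass, params$defect_definition)
  abs(defect - expected) <= params$tolerance
}

#' Screen a feature table for halogenated candidates
#'
#' Applies [defect_window_pass()] to every feature mass and reports the
#' defect, the expected defect and the verdict.
#'
#' @param features data frame with columns `feature_id` and `neutral_mass`,
#'   or a numeric vector of masses.
#' @param params a [mass_defect_params()] object.
#' @return data frame: feature_id, neutral_mass, defect, expected, pass.
#' @export
screen_halogenated <- function(features, params = mass_defect_params()) {
  if (is.numeric(features)) {
    features <- data.frame(
      feature_id = if (is.null(names(features)))
        sprintf("M%04d", seq_along(features)) else names(features),
      neutral_mass = as.numeric(features)
    )
  }
  stopifnot(all(c("feature_id", "neutral_mass") %in% names(features)))
  m <- features$neutral_mass
  data.frame(
    feature_id = features$feature_id,
    neutral_mass = m,
    defect = mass_defect(m, params$defect_definition),
    expected = params$intercept + params$slope * m / 100,
    pass = defect_window_pass(m, params),
    stringsAsFactors = FALSE
  )
}

#' Theoretical isotope pattern of a formula
#'
#' Convolves per-element isotopologue distributions on the unit-spaced
#' (nominal) offset grid: peak `k` aggregates all isotopologues whose nominal
#' mass is `k` units above the monoisotopic peak (the familiar M, M+1,
#' M+2, ... envelope). Abundances are normalised so the tallest peak is 1.
#'
#' @param formula formula string or named count vector.
#' @param n_peaks maximum number of peaks to return (M .. M+(n_peaks-1)).
#' @param truncate drop trailing peaks below this fraction of the base peak;
#'   set to 0 to keep the full (untruncated) distribution.
#' @return data frame: offset (integer, Da-spaced), abundance (max = 1),
#'   with the pre-normalisation probability in attribute `"probability"`.
#' @export
#' @examples
#' isotope_pattern("Br2")  # M : M+2 : M+4 close to 1 : 1.95 : 0.95
isotope_pattern <- function(formula, n_peaks = 12L, truncate = 1e-6) {
  counts <- parse_formula(formula)
  dist <- 1 # probability vector over offsets 0, 1, 2, ...
  for (e in names(counts)) {
    iso <- .ELEMENTS[[e]]$iso
    v <- numeric(max(as.integer(names(iso))) + 1L)
    v[as.integer(names(iso)) + 1L] <- iso
    for (i in seq_len(counts[[e]])) {
      dist <- convolve_abund(dist, v)
    }
  }
  prob <- dist
  keep <- seq_len(min(length(dist), n_peaks))
  dist <- dist[keep]
  rel <- dist / max(dist)
  if (truncate > 0) {
    last <- max(which(rel >= truncate))
    dist <- dist[seq_len(last)]
    rel <- rel[seq_len(last)]
  }
  out <- data.frame(offset = seq_along(rel) - 1L, abundance = rel)
  attr(out, "probability") <- dist
  attr(out, "total_probability") <- sum(prob)
  out
}

# Discrete convolution of two abundance vectors indexed from offset 0.
convolve_abund <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Cosine match between an observed and a theoretical isotope pattern
#'
#' Observed peaks are binned onto the theoretical unit-spaced offset grid
#' (relative to the lowest observed mass); the score is the cosine of the two
#' abundance vectors over the union of slots. Peaks that do not land within
#' `tol` of an integer slot are kept in their own slot and so count against
#' the match.
#'
#' @param observed two-column matrix or data frame (mass, abundance); masses
#'   may be absolute or already offsets.
#' @param theoretical data frame as returned by [isotope_pattern()].
#' @param tol Da tolerance for assigning an observed peak to a slot.
#' @return cosine similarity in \[0, 1\].
#' @export
pattern_match_score <- function(observed, theoretical, tol = 0.05) {
  observed <- as.matrix(observed)
  stopifnot(nrow(observed) >= 1, nrow(theoretical) >= 1)
  off <- observed[, 1] - min(observed[, 1])
  slot <- round(off)
  slot[abs(off - slot) > tol] <- NA
  n_slots <- max(c(slot, theoretical$offset), na.rm = TRUE) + 1L
  v_obs <- numeric(n_slots)
  ok <- !is.na(slot)
  if (!any(ok)) return(0)
  for (i in which(ok)) {
    v_obs[slot[i] + 1L] <- v_obs[slot[i] + 1L] + observed[i, 2]
  }
  v_th <- numeric(n_slots)
  v_th[theoretical$offset + 1L] <- theoretical$abundance
  denom <- sqrt(sum(v_obs^2)) * sqrt(sum(v_th^2))
  if (denom == 0) return(0)
  overlap <- v_obs > 0 & v_th > 0
  if (!any(overlap)) return(0)
  sum(v_obs * v_th) / denom
}
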