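# Elemental isotope data: IUPAC 2021 representative atomic masses (Da) and
# isotopic abundances (mole fraction). Restricted to the elements that occur
# in the small-molecule substrates/products this package targets.
.ISOTOPES <- list(
  C  = list(mass = c(12.0000000000, 13.0033548351), abundance = c(0.9893, 0.0107)),
  H  = list(mass = c(1.0078250319, 2.0141017781),   abundance = c(0.999885, 0.000115)),
  N  = list(mass = c(14.0030740045, 15.0001088989), abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317566, 17.9991596128),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.9737619984,  abundance = 1.0),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.9678670040, 35.9670807100),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  F  = list(mass = 18.9984031627,  abundance = 1.0),
  Cl = list(mass = c(34.9688526820, 36.9659026020), abundance = c(0.7576, 0.2424)),
  Br = list(mass = c(78.9183376000, 80.9162897000), abundance = c(0.5069, 0.4931))
)

# m(H) - m(e-); charge carrier for [M+H]+ / [M-H]-
.PROTON_MASS <- 1.007276466621

#' Parse a molecular formula string
#'
#' Parses standard element-count notation (e.g. `"C12H15NO2"`) into an
#' `ElementComposition`: a named integer vector of element counts. Hill order
#' is not required on input; [format_formula()] renders the canonical
#' Hill-order string (C first, then H, then remaining elements alphabetically).
#'
#' @param text Formula string. Supported elements: C, H, N, O, P, S, F, Cl, Br.
#' @return An `ElementComposition` (named integer vector, class
#'   `"ElementComposition"`).
#' @examples
#' parse_formula("C12H15NO2")
#' format_formula(parse_formula("H2O"))
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  pattern <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("formula '", text, "' does not match element-count grammar")
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.ISOTOPES))
      stop("unknown or unsupported element symbol '", sym, "'")
    if (n < 0L) stop("negative count for ", sym)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) stop("formula '", text, "' contains no atoms")
  element_composition(counts)
}

#' Construct an ElementComposition from named counts
#'
#' @param counts Named integer vector or list, element symbol -> count.
#' @return `ElementComposition`.
#' @export
element_composition <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by element symbol")
  bad <- setdiff(names(counts), names(.ISOTOPES))
  if (length(bad))
    stop("unknown or unsupported element symbol '", bad[[1]], "'")
  if (any(counts < 0)) stop("element counts must be non-negative")
  nm <- names(counts)
  counts <- as.integer(round(counts))
  names(counts) <- nm
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) stop("composition must contain at least one atom")
  structure(counts, class = "ElementComposition")
}

#' @export
format.ElementComposition <- function(x, ...) format_formula(x)

#' Canonical Hill-order formula string
#'
#' @param comp `ElementComposition`.
#' @return Character scalar, e.g. `"C12H15NO2"`.
#' @export
format_formula <- function(comp) {
  comp <- as_composition(comp)
  syms <- names(comp)
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    ord <- sort(syms)
  }
  paste0(vapply(ord, function(s) {
    n <- comp[[s]]
    if (n == 1L) s else paste0(s, n)
  }, character(1)), collapse = "")
}

#' @export
print.ElementComposition <- function(x, ...) {
  cat("<ElementComposition> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

as_composition <- function(x) {
  if (inherits(x, "ElementComposition")) return(x)
  if (is.character(x)) return(parse_formula(x))
  element_composition(x)
}

#' Adduct specification
#'
#' Describes how a neutral molecule is ionized. Only singly charged
#' protonation states are supported: `"M+H"` (positive mode), `"M-H"`
#' (negative mode), and the neutral `"M"`.
#'
#' @param kind One of `"M+H"`, `"M-H"`, `"M"` (bracketed forms
#'   `"[M+H]+"` / `"[M-H]-"` also accepted).
#' @return An `AdductSpec` with fields `kind` and `polarity` (+1, -1, 0).
#' @export
adduct_spec <- function(kind = c("M+H", "M-H", "M")) {
  if (inherits(kind, "AdductSpec")) return(kind)
  kind <- gsub("^\\[|\\][+-]?$", "", kind[[1]])
  kind <- match.arg(kind, c("M+H", "M-H", "M"))
  polarity <- switch(kind, "M+H" = 1L, "M-H" = -1L, "M" = 0L)
  structure(list(kind = kind, polarity = polarity), class = "AdductSpec")
}

# composition of the ion (atoms only; charge handled via electron mass)
ion_composition <- function(comp, adduct) {
  comp <- as_composition(comp)
  adduct <- adduct_spec(adduct)
  counts <- as.integer(comp)
  names(counts) <- names(comp)
  if (adduct$kind == "M+H") {
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + 1L
  } else if (adduct$kind == "M-H") {
    if (!"H" %in% names(counts) || counts[["H"]] < 1L)
      stop("cannot deprotonate a composition without hydrogen")
    counts[["H"]] <- counts[["H"]] - 1L
    counts <- counts[counts > 0L]
  }
  element_composition(counts)
}

#' Monoisotopic m/z of a formula under an adduct
#'
#' Sum of lightest-isotope atomic masses, plus or minus a proton mass for
#' `[M+H]+` / `[M-H]-`. Only singly charged ions are supported, so the m/z
#' equals the ion mass.
#'
#' Note: for the deoxyfluorinated sugar phosphate C6H12FO8P this computes an
#' `[M-H]-` of 261.018 Da; some screening literature quotes a nominal 261.1
#' for this ion class. The computed value is reported as-is.
#'
#' @param comp `ElementComposition` or formula string.
#' @param adduct `AdductSpec` or kind string; must be ionic (`"M+H"`/`"M-H"`).
#' @return m/z in Da.
#' @examples
#' monoisotopic_mz("C12H15NO2", "M+H") # 206.118 (dehydrosalsolidine)
#' monoisotopic_mz("C12H17NO2", "M+H") # 208.133 (salsolidine)
#' @export
monoisotopic_mz <- function(comp, adduct) {
  comp <- as_composition(comp)
  adduct <- adduct_spec(adduct)
  if (adduct$polarity == 0L)
    stop("a neutral molecule has no m/z; use an ionic adduct (M+H or M-H)")
  mono <- sum(vapply(names(comp), function(s) {
    iso <- .ISOTOPES[[s]]
    iso$mass[[which.min(iso$mass)]] * comp[[s]]
  }, numeric(1)))
  mono + adduct$polarity * .PROTON_MASS
}

#' Neutral monoisotopic mass
#' @param comp `ElementComposition` or formula string.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_composition(comp)
  sum(vapply(names(comp), function(s) {
    iso <- .ISOTOPES[[s]]
    min(iso$mass) * comp[[s]]
  }, numeric(1)))
}

# Convolve two centroided peak lists (mass, abundance), aggregating peaks by
# nominal isotopologue unit and pruning dust.
convolve_peaks <- function(a, b, prune = 1e-15) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$abundance, b$abundance)
  merge_peaks(list(mass = as.numeric(mass), abundance = as.numeric(ab)),
              prune)
}

# Aggregate peaks sharing a nominal M+k unit (integer offset from the
# lightest peak) at their abundance-weighted mean mass. Unit grouping is
# associative under convolution, so element-wise convolution aggregates
# exactly like one-shot isotopologue enumeration -- a fixed sub-unit distance
# tolerance would group order-dependently right at its boundary (e.g. 37Cl or
# 81Br versus 13C2 fine structure, ~0.01 Da apart).
merge_peaks <- function(p, prune = 0) {
  grp <- round(p$mass - min(p$mass))
  m <- vapply(split(seq_along(p$mass), grp), function(i) {
    stats::weighted.mean(p$mass[i], p$abundance[i])
  }, numeric(1))
  a <- vapply(split(p$abundance, grp), sum, numeric(1))
  o <- order(m)
  keep <- a[o] > prune
  list(mass = unname(m[o][keep]), abundance = unname(a[o][keep]))
}

# n-fold self-convolution by binary exponentiation
power_peaks <- function(p, n) {
  result <- NULL
  base <- p
  while (n > 0L) {
    if (n %% 2L == 1L)
      result <- if (is.null(result)) base else convolve_peaks(result, base)
    n <- n %/% 2L
    if (n > 0L) base <- convolve_peaks(base, base)
  }
  result
}

#' Natural-abundance isotopologue envelope
#'
#' Computes the centroided isotope pattern of a molecular formula (optionally
#' ionized) as the convolution across elements of each element's multinomial
#' isotopologue distribution. Peaks are aggregated per nominal M+k unit at
#' their abundance-weighted mean mass (fine isotope structure, e.g. 13C vs
#' 15N splitting ~0.01 Da, is deliberately not resolved -- far below the
#' 0.2 Da extraction windows used downstream); the envelope is truncated at
#' `truncation` total abundance and renormalized to sum to 1.
#'
#' @param comp `ElementComposition` or formula string.
#' @param adduct Adduct (default neutral `"M"`). For ionic adducts peak masses
#'   are shifted by the electron mass so that the base peak matches
#'   [monoisotopic_mz()].
#' @param truncation Abundance fraction below which peaks are dropped
#'   (in (0, 0.01]; default 1e-6).
#' @return An `IsotopeEnvelope`: list with `mass` (Da, increasing),
#'   `abundance` (sums to 1), and `nominal_offset` (integer M+k labels).
#' @examples
#' isotope_envelope("C12H15NO2", "M+H")
#' @export
isotope_envelope <- function(comp, adduct = "M", truncation = 1e-6) {
  if (!is.numeric(truncation) || truncation <= 0 || truncation > 0.01)
    stop("truncation must lie in (0, 0.01]")
  adduct <- adduct_spec(adduct)
  ion <- ion_composition(comp, adduct)
  env <- NULL
  for (s in names(ion)) {
    iso <- .ISOTOPES[[s]]
    single <- list(mass = iso$mass, abundance = iso$abundance)
    elem <- power_peaks(single, ion[[s]])
    env <- if (is.null(env)) elem else convolve_peaks(env, elem)
  }
  # electron correction so masses are true ion m/z
  env$mass <- env$mass - adduct$polarity * (1.0078250319 - .PROTON_MASS)
  keep <- env$abundance >= truncation
  mass <- env$mass[keep]
  ab <- env$abundance[keep] / sum(env$abundance[keep])
  structure(list(mass = mass, abundance = ab,
                 nominal_offset = as.integer(round(mass - mass[[1]]))),
            class = "IsotopeEnvelope")
}

#' @export
print.IsotopeEnvelope <- function(x, ...) {
  cat("<IsotopeEnvelope> ", length(x$mass), " peaks\n", sep = "")
  print(data.frame(label = paste0("M+", x$nominal_offset),
                   mass = round(x$mass, 4),
                   abundance = signif(x$abundance, 4)))
  invisible(x)
}

#' Fraction of an envelope falling inside an m/z window
#'
#' Sums the envelope abundance within `[target - window/2, target + window/2]`
#' and expresses it relative to the envelope's base (most abundant) peak.
#' This is the predicted isotope interference of one species onto another
#' detection channel, e.g. the M+2 of an imine substrate leaking into the
#' amine product channel two mass units higher.
#'
#' @param envelope `IsotopeEnvelope`.
#' @param target_mz Window center (Da).
#' @param window Full window width (Da), default 0.2.
#' @return Non-negative fraction (>= 1 when the base peak itself is in the
#'   window).
#' @export
interference_fraction <- function(envelope, target_mz, window = 0.2) {
  if (!inherits(envelope, "IsotopeEnvelope") || length(envelope$mass) == 0L)
    stop("envelope is empty or not an IsotopeEnvelope")
  if (!is.numeric(window) || window <= 0) stop("window must be > 0")
  inwin <- envelope$mass >= target_mz - window / 2 &
           envelope$mass <= target_mz + window / 2
  sum(envelope$abundance[inwin]) / max(envelope$abundance)
}
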