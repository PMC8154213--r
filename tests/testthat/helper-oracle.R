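# Independent brute-force isotopologue oracle: enumerates every way of
# distributing each element's atoms over its isotopes, computes multinomial
# probabilities and exact masses, and aggregates peaks by a merge tolerance.
# Kept deliberately independent of the package's convolution path.

.ORACLE_ISOTOPES <- list(
  C  = list(mass = c(12.0000000000, 13.0033548351), p = c(0.9893, 0.0107)),
  H  = list(mass = c(1.0078250319, 2.0141017781),   p = c(0.999885, 0.000115)),
  N  = list(mass = c(14.0030740045, 15.0001088989), p = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317566, 17.9991596128),
            p = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.9737619984,  p = 1.0),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.9678670040,
                     35.9670807100),
            p = c(0.9499, 0.0075, 0.0425, 0.0001)),
  F  = list(mass = 18.9984031627,  p = 1.0),
  Cl = list(mass = c(34.9688526820, 36.9659026020), p = c(0.7576, 0.2424)),
  Br = list(mass = c(78.9183376000, 80.9162897000), p = c(0.5069, 0.4931))
)

# all ways to split n atoms over k isotope slots
iso_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (i in 0:n) {
    sub <- iso_compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, sub))
  }
  out
}

# counts: named integer vector of the *ion* composition; polarity shifts the
# masses by the electron mass so they line up with package envelopes.
# Aggregation convention matches the published one: peaks grouped per nominal
# M+k unit at their abundance-weighted mean mass.
oracle_envelope <- function(counts, polarity = 0L, truncation = 1e-6) {
  per_elem <- lapply(names(counts), function(s) {
    iso <- .ORACLE_ISOTOPES[[s]]
    combos <- iso_compositions(counts[[s]], length(iso$mass))
    data.frame(
      mass = as.numeric(combos %*% iso$mass),
      p = apply(combos, 1L, function(k) stats::dmultinom(k, prob = iso$p))
    )
  })
  full <- Reduce(function(a, b) {
    data.frame(mass = as.numeric(outer(a$mass, b$mass, `+`)),
               p = as.numeric(outer(a$p, b$p)))
  }, per_elem)
  full$mass <- full$mass - polarity * (1.0078250319 - 1.007276466621)
  mass <- full$mass; p <- full$p
  grp <- round(mass - min(mass))
  agg_m <- vapply(split(seq_along(mass), grp),
                  function(i) sum(mass[i] * p[i]) / sum(p[i]), numeric(1))
  agg_p <- vapply(split(p, grp), sum, numeric(1))
  o <- order(agg_m)
  agg_m <- agg_m[o]; agg_p <- agg_p[o]
  keep <- agg_p >= truncation
  list(mass = unname(agg_m[keep]),
       abundance = unname(agg_p[keep] / sum(agg_p[keep])))
}

# ion composition for M+H / M-H without touching package internals
oracle_ion_counts <- function(formula, adduct) {
  comp <- parse_formula(formula)
  counts <- stats::setNames(as.integer(comp), names(comp))
  if (adduct == "M+H") {
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + 1L
  } else if (adduct == "M-H") {
    counts[["H"]] <- counts[["H"]] - 1L
    counts <- counts[counts > 0L]
  }
  counts
}
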