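# Degenerate-codon mathematics for directed-evolution library design:
# IUPAC codon expansion, amino-acid-level library size, and the number of
# clones to screen for a target coverage of an equiprobable variant library.

#' Expand a degenerate IUPAC codon
#'
#' Expands a three-letter IUPAC nucleotide code (e.g. `"RBT"`) into its DNA
#' triplet set and the amino acids they encode under the standard genetic
#' code. `"RBT"` encodes the six residues T, S, I, G, A, V used in
#' reduced-alphabet active-site libraries.
#'
#' @param code Three IUPAC nucleotide symbols.
#' @return A `DegenerateCodon`: list with `code`, `codons` (sorted DNA
#'   triplets), `residues` (sorted one-letter amino acids, stop excluded),
#'   `has_stop`.
#' @examples
#' expand_codon("RBT")  # 6 codons -> T, S, I, G, A, V
#' expand_codon("NNN")  # 64 codons -> all 20 residues + stop
#' @export
expand_codon <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
    stop("code must be a 3-letter IUPAC string")
  code <- toupper(code)
  map <- Biostrings::IUPAC_CODE_MAP
  syms <- strsplit(code, "")[[1]]
  bad <- setdiff(syms, names(map))
  if (length(bad)) stop("invalid IUPAC symbol '", bad[[1]], "'")
  per_pos <- lapply(syms, function(s) strsplit(map[[s]], "")[[1]])
  grid <- expand.grid(per_pos, stringsAsFactors = FALSE)
  codons <- sort(apply(grid, 1L, paste0, collapse = ""))
  aas <- Biostrings::GENETIC_CODE[codons]
  residues <- sort(unique(aas[aas != "*"]))
  structure(list(code = code, codons = unname(codons),
                 residues = unname(residues),
                 has_stop = any(aas == "*")),
            class = "DegenerateCodon")
}

#' @export
print.DegenerateCodon <- function(x, ...) {
  cat(sprintf("<DegenerateCodon> %s: %d codon(s) -> {%s}%s\n", x$code,
              length(x$codons), paste(x$residues, collapse = ","),
              if (x$has_stop) " + stop" else ""))
  invisible(x)
}

as_codon <- function(x) if (inherits(x, "DegenerateCodon")) x else expand_codon(x)

#' Amino-acid-level library size
#'
#' Product over the mutated positions of the number of distinct encoded amino
#' acids (stops and codon-level redundancy collapsed). Two RBT positions give
#' 6 x 6 = 36 possible amino acid combinations. The codon-level combination
#' count (always >= the residue-level count) is attached as attribute
#' `codon_combinations`.
#'
#' @param positions List of `DegenerateCodon`s or IUPAC code strings.
#' @return Integer residue-level variant count, with attribute
#'   `codon_combinations`.
#' @examples
#' library_size(list("RBT", "RBT"))  # 36
#' @export
library_size <- function(positions) {
  if (!length(positions)) stop("need at least one position")
  if (!is.list(positions)) positions <- as.list(positions)
  positions <- lapply(positions, as_codon)
  sizes <- vapply(positions, function(p) length(p$residues), integer(1))
  if (any(sizes == 0L))
    stop("a position encodes only stop codons")
  structure(prod(sizes),
            codon_combinations = prod(vapply(positions, function(p)
              length(p$codons), integer(1))))
}

#' Clones required for a target library coverage
#'
#' Number of clones to screen so that any given variant of an equiprobable
#' `V`-variant library is sampled with probability `F`:
#' `n = ln(1 - F) / ln(1 - 1/V)`, rounded to the nearest integer
#' (`mode = "ceiling"` rounds up instead). For F = 0.95 and V = 36 this gives
#' 106 clones.
#'
#' @param F Target coverage fraction in (0, 1).
#' @param V Variant count (>= 1); `V = 1` needs a single clone.
#' @param mode `"nearest"` (default, matches the conventional printed values)
#'   or `"ceiling"`.
#' @return Integer clone count.
#' @examples
#' clones_for_coverage(0.95, 36)  # 106
#' @export
clones_for_coverage <- function(F, V, mode = c("nearest", "ceiling")) {
  mode <- match.arg(mode)
  if (!is.numeric(F) || F <= 0 || F >= 1)
    stop("coverage F must lie strictly within (0, 1)")
  if (!is.numeric(V) || V < 1) stop("V must be >= 1")
  if (V == 1) return(1L)
  n <- log(1 - F) / log(1 - 1 / V)
  as.integer(if (mode == "ceiling") ceiling(n) else round(n))
}

#' Library design summary table
#'
#' For each candidate degenerate codon set (one entry per design; each design
#' is a list of per-position codes), tabulates the expanded codons, encoded
#' residues, residue- and codon-level library sizes, and the clones required
#' at the requested coverages.
#'
#' @param designs Named list; each element a character vector of IUPAC codes
#'   (one per mutated position).
#' @param coverage Coverage fractions (default 0.90, 0.95, 0.99).
#' @return data.frame, one row per design.
#' @examples
#' design_table(list(doubleRBT = c("RBT", "RBT")))
#' @export
design_table <- function(designs, coverage = c(0.90, 0.95, 0.99)) {
  if (is.character(designs)) designs <- list(designs)
  if (is.null(names(designs)))
    names(designs) <- vapply(designs, paste, character(1), collapse = "/")
  rows <- lapply(names(designs), function(nm) {
    codes <- designs[[nm]]
    V <- library_size(as.list(codes))
    row <- data.frame(design = nm,
                      codes = paste(codes, collapse = "/"),
                      residues = paste(vapply(codes, function(cd)
                        paste(expand_codon(cd)$residues, collapse = ""),
                        character(1)), collapse = "/"),
                      variants = as.integer(V),
                      codon_combinations =
                        as.integer(attr(V, "codon_combinations")),
                      stringsAsFactors = FALSE)
    for (f in coverage)
      row[[sprintf("clones_%g", 100 * f)]] <- clones_for_coverage(f, V)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
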