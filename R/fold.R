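#' Fold an RNA sequence into its minimum-free-energy hairpin structure
#'
#' Computes the minimum-free-energy nested secondary structure of a single
#' strand under the package's self-contained nearest-neighbour model:
#' Watson–Crick and G:U wobble pairs with stacking energies, size-dependent
#' hairpin / bulge / internal-loop penalties, an affine multibranch term,
#' hairpin loops of at least 3 unpaired bases, no pseudoknots and no dangling
#' ends. Interior loops are capped at 30 unpaired nucleotides. The energy
#' parameters are returned by [fold_params()].
#'
#' The dynamic programme is deterministic: for a given sequence the same
#' structure is always returned. The empty structure has energy 0, so the
#' reported MFE is never positive.
#'
#' @param sequence a single nucleotide string (A/C/G/T/U, case-insensitive).
#' @return an object of class `hairpin_structure`: a list with elements
#'   `sequence` (normalized DNA), `mfe` (kcal/mol, <= 0), `dot_bracket`,
#'   `partner` (integer vector, 1-based index of the pairing partner or `NA`)
#'   and `pairs` (two-column matrix of (i, j) pairs with i < j).
#' @examples
#' fold_rna("GGGGAAAACCCC")$dot_bracket
#' fold_rna("AAAAAAAAAAAA")$mfe   # no complementarity: 0
#' @export
fold_rna <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence))
    invalid_arg("'sequence' must be a single string")
  seq <- normalize_dna(sequence)
  if (nchar(seq) < 1L) invalid_arg("empty sequence")
  if (grepl("[^ACGT]", seq))
    invalid_arg("sequence contains a non-ACGTU character")
  res <- .fold_mfe_cpp(seq)
  partner <- res$partner
  i <- which(!is.na(partner) & partner > seq_along(partner))
  pairs <- cbind(i = i, j = partner[i])
  structure(
    list(sequence = seq, mfe = res$mfe, dot_bracket = res$dot_bracket,
         partner = partner, pairs = pairs),
    class = "hairpin_structure"
  )
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat("hairpin_structure:", nchar(x$sequence), "nt, MFE",
      sprintf("%.2f", x$mfe), "kcal/mol,", nrow(x$pairs), "pairs\n")
  cat(as_rna(x$sequence), "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Energy parameters of the folding model
#'
#' Returns the nearest-neighbour parameter set used by [fold_rna()], in
#' kcal/mol. Pair types are named `AU`, `UA`, `CG`, `GC`, `GU`, `UG`; the
#' stack entry `stack[p, q]` is the energy of pair `p` at (i, j) stacked on
#' pair `q` at (i+1, j-1). The ten unique Watson–Crick stacks are Turner
#' values completed by the symmetry `stack(p, q) = stack(rev(q), rev(p))`;
#' G:U-containing stacks use a coarse three-level scheme (-1.5 against C-G/G-C
#' neighbours, -0.8 against A-U/U-A, -0.5 for tandem wobbles, +0.47 for the
#' destabilising 5'GG/3'UU and its symmetric mate). Loop penalties beyond the
#' tabulated sizes are extrapolated as `last + 1.08 * log(n / last_size)`.
#'
#' These values are the single source of truth for tests that re-derive
#' structure energies independently of the dynamic programme.
#'
#' @return a list with elements `stack` (6 x 6 named matrix), `hairpin`
#'   (penalties for loop sizes 3–9), `bulge` (sizes 1–6), `internal`
#'   (sizes 2–6), `asym` (coefficient and cap for internal-loop asymmetry),
#'   `multi` (affine multibranch a/b/c), `maxloop`, `min_hairpin_loop`.
#' @export
fold_params <- function() {
  pn <- c("AU", "UA", "CG", "GC", "GU", "UG")
  S <- matrix(0, 6, 6, dimnames = list(pn, pn))
  S["AU", "AU"] <- -0.93; S["AU", "UA"] <- -1.10; S["UA", "AU"] <- -1.33
  S["CG", "UA"] <- -2.08; S["CG", "AU"] <- -2.11; S["GC", "UA"] <- -2.24
  S["GC", "AU"] <- -2.35; S["CG", "GC"] <- -2.36; S["GC", "GC"] <- -3.26
  S["GC", "CG"] <- -3.42
  S["UA", "UA"] <- -0.93; S["AU", "GC"] <- -2.08; S["AU", "CG"] <- -2.24
  S["UA", "GC"] <- -2.11; S["UA", "CG"] <- -2.35; S["CG", "CG"] <- -3.26
  for (p in pn) {
    for (q in pn) {
      pu <- p %in% c("GU", "UG"); qu <- q %in% c("GU", "UG")
      if (!pu && !qu) next
      if (pu && qu) S[p, q] <- -0.50
      else {
        wc <- if (pu) q else p
        S[p, q] <- if (wc %in% c("CG", "GC")) -1.50 else -0.80
      }
    }
  }
  S["GU", "GU"] <- 0.47; S["UG", "UG"] <- 0.47
  list(
    stack = S,
    hairpin = c(`3` = 5.4, `4` = 5.6, `5` = 5.7, `6` = 5.4, `7` = 6.0,
                `8` = 5.5, `9` = 6.4),
    bulge = c(`1` = 3.8, `2` = 2.8, `3` = 3.2, `4` = 3.6, `5` = 4.0,
              `6` = 4.4),
    internal = c(`2` = 1.5, `3` = 2.2, `4` = 2.7, `5` = 3.0, `6` = 3.2),
    asym = c(coef = 0.6, max = 3.0),
    multi = c(a = 3.4, b = 0.4, c = 0.0),
    loop_extrapolation = 1.08,
    maxloop = 30L,
    min_hairpin_loop = 3L
  )
}
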