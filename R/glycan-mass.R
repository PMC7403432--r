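## Monoisotopic mass engine for permethylated N-glycans.
##
## All masses are derived at run time from atomic monoisotopic masses; the
## only chemistry encoded here is the elemental formula of each permethylated
## residue as it sits in a glycan chain, plus the end-group correction
## (methylated reducing terminus and the extra methyl freed at the
## non-reducing termini, net H2O + 2 CH2) and the sodium cation.

#' Atomic monoisotopic masses (Da)
#'
#' Monoisotopic masses of the elements needed for permethylated glycan
#' mass calculation (CODATA/AME values, Da).
#'
#' @return Named numeric vector with elements C, H, N, O, Na.
#' @examples
#' atomicMasses()[["O"]]
#' @export
atomicMasses <- function() {
  c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
    O = 15.9949146196, Na = 22.9897692809)
}

## Elemental composition (C, H, N, O) of each fully permethylated residue as
## incorporated in a chain.  Hex = Man/Gal pooled by mass; dHex = fucose;
## NeuAc = N-acetylneuraminic acid with its carboxyl methyl-esterified.
.residueFormulas <- list(
  hexnac = c(C = 11, H = 19, N = 1, O = 5),
  hex    = c(C = 9,  H = 16, N = 0, O = 5),
  dhex   = c(C = 8,  H = 14, N = 0, O = 4),
  neuac  = c(C = 16, H = 27, N = 1, O = 8)
)

## Net end-group correction for a free, fully permethylated glycan: one H2O
## plus two CH2 (methylated anomeric hydroxyl + non-reducing terminus).
.endGroupFormula <- c(C = 2, H = 6, N = 0, O = 1)

.formulaMass <- function(formula) {
  am <- atomicMasses()
  sum(formula * am[c("C", "H", "N", "O")])
}

.monosaccharides <- c("hexnac", "hex", "dhex", "neuac")

#' Construct a monosaccharide composition
#'
#' A composition counts the four mass-distinguishable monosaccharide classes
#' of human plasma N-glycans: HexNAc (GlcNAc), Hex (Man/Gal, pooled because
#' they are isobaric), dHex (fucose) and NeuAc (sialic acid).
#'
#' @param hexnac,hex,dhex,neuac Non-negative integer counts.
#' @return Named integer vector of class \code{glycanComposition}.
#' @examples
#' glycanComposition(hexnac = 4, hex = 4, neuac = 1)  # A2G1S1
#' @export
glycanComposition <- function(hexnac = 0L, hex = 0L, dhex = 0L, neuac = 0L) {
  x <- c(hexnac = hexnac, hex = hex, dhex = dhex, neuac = neuac)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("composition counts must be non-negative integers")
  x <- as.integer(round(x))
  names(x) <- .monosaccharides
  class(x) <- "glycanComposition"
  x
}

.asComposition <- function(x) {
  if (inherits(x, "glycanComposition")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    miss <- setdiff(names(x), .monosaccharides)
    if (length(miss))
      stop("unknown monosaccharide(s): ", paste(miss, collapse = ", "))
    full <- stats::setNames(rep(0L, 4L), .monosaccharides)
    full[names(x)] <- as.integer(x)
    return(do.call(glycanComposition, as.list(full)))
  }
  stop("cannot interpret object as a monosaccharide composition")
}

#' Permethylated sodiated monoisotopic m/z
#'
#' Computes the monoisotopic m/z of the singly charged [M+Na]+ ion of a
#' fully permethylated glycan, the ion species observed for permethylated
#' N-glycans in positive-mode MALDI-TOF.  The mass is the sum of
#' permethylated residue masses plus the end-group correction (net
#' H2O + 2 CH2) and the Na+ mass, all derived from atomic monoisotopic
#' masses.
#'
#' @param composition A \code{\link{glycanComposition}} or named count
#'   vector (names among hexnac, hex, dhex, neuac).
#' @param adduct Adduct ion; only \code{"Na"} (sodiated, singly charged)
#'   is supported.
#' @return Monoisotopic m/z in Da.
#' @examples
#' permethylatedMz(glycanComposition(hexnac = 4, hex = 4, neuac = 1))
#' # ~2227.1, the bi-antennary monosialo species A2G1S1
#' @export
permethylatedMz <- function(composition, adduct = c("Na")) {
  adduct <- match.arg(adduct)
  comp <- .asComposition(composition)
  if (sum(comp) < 1L)
    stop("empty composition: at least one residue is required")
  residues <- vapply(.monosaccharides,
                     function(m) .formulaMass(.residueFormulas[[m]]),
                     numeric(1))
  unname(sum(comp * residues) + .formulaMass(.endGroupFormula) +
           atomicMasses()[["Na"]])
}

#' Validate an N-glycan composition
#'
#' An N-glycan carries the trimannosyl-chitobiose core, i.e. at least
#' 2 HexNAc and 3 Hex.
#'
#' @param composition A composition (see \code{\link{glycanComposition}}).
#' @return \code{TRUE} invisibly, or an error.
#' @export
checkNGlycanCore <- function(composition) {
  comp <- .asComposition(composition)
  if (comp[["hexnac"]] < 2L || comp[["hex"]] < 3L)
    stop("not a valid N-glycan composition: requires hexnac >= 2 and ",
         "hex >= 3 (trimannosyl-chitobiose core)")
  invisible(TRUE)
}
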