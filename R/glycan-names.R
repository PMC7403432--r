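## AxFyGzSw short-name grammar for complex N-glycans, extended with an
## optional bisecting token (B) and an M-grammar for high-mannose and hybrid
## species:
##
##   complex:      A<d> [B] [F<d?>] G<d> S<d>     e.g. A2G1S1, A3FG3S3, A2BG2S2
##   high-mannose: M<d>                            e.g. M5 .. M9
##   hybrid:       M<d> A1 [G<d> S<d>]             e.g. M5A1, M4A1G1S1
##
## A = antennae, B = bisecting GlcNAc, F = fucoses (bare F means 1),
## G = galactoses, S = sialic acids, M = mannoses (hybrid M counts the
## mannoses outside added antenna galactose).

#' Parse a glycan short name
#'
#' Reconstructs the monosaccharide composition (and the structural hints the
#' name encodes) from an AxFyGzSw-style label.  For complex names,
#' hexnac = antennae + 2 (+1 if bisected), hex = Gal + 3, neuac = S,
#' dhex = F.  High-mannose names M5..M9 give hexnac 2 and hex = M; hybrid
#' names M*A1[G*S*] give hexnac 3 and hex = M + G.
#'
#' @param label Character scalar short name.
#' @return List with \code{composition} (\code{glycanComposition}),
#'   \code{antennae}, \code{bisecting}, \code{gal}, and \code{glycan_class}
#'   hint (\code{NA} when the name does not determine it).
#' @examples
#' parseShortName("A2G1S1")$composition
#' parseShortName("A3FG3S3")$composition
#' @export
parseShortName <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop("label must be a single character string")
  ## high-mannose / hybrid grammar
  m <- regmatches(label, regexec("^M([0-9])(A1(G([0-9])S([0-9]))?)?$", label))[[1]]
  if (length(m)) {
    man <- as.integer(m[2])
    if (m[3] == "") {
      if (man < 5L)
        stop("malformed label '", label, "': high-mannose names are M5..M9")
      return(list(composition = glycanComposition(hexnac = 2L, hex = man),
                  antennae = 0L, bisecting = FALSE, gal = 0L,
                  glycan_class = "high-mannose"))
    }
    gal <- if (m[4] == "") 0L else as.integer(m[5])
    sia <- if (m[4] == "") 0L else as.integer(m[6])
    return(list(composition = glycanComposition(hexnac = 3L, hex = man + gal,
                                                neuac = sia),
                antennae = 1L, bisecting = FALSE, gal = gal,
                glycan_class = "hybrid"))
  }
  ## complex grammar
  m <- regmatches(label,
                  regexec("^A([0-9])(B)?(F([0-9])?)?G([0-9])S([0-9])$",
                          label))[[1]]
  if (!length(m)) {
    tok <- sub("^(A[0-9]?(B)?)?.*$", "\\1", label)
    stop("malformed label '", label, "': cannot parse at token '",
         if (nzchar(tok)) substr(label, nchar(tok) + 1L, nchar(label)) else label,
         "'")
  }
  ant <- as.integer(m[2])
  bisect <- m[3] == "B"
  fuc <- if (m[4] == "") 0L else if (m[5] == "") 1L else as.integer(m[5])
  gal <- as.integer(m[6])
  sia <- as.integer(m[7])
  list(composition = glycanComposition(hexnac = ant + 2L + bisect,
                                       hex = gal + 3L, dhex = fuc,
                                       neuac = sia),
       antennae = ant, bisecting = bisect, gal = gal,
       glycan_class = if (ant >= 1L) "complex" else NA_character_)
}

#' Compose a glycan short name
#'
#' Inverse of \code{\link{parseShortName}} given a composition and its
#' structural annotation.
#'
#' @param composition A composition.
#' @param annotation A \code{\link{structuralAnnotation}} list (needs
#'   \code{glycan_class}, \code{antennae}, \code{bisecting} and
#'   \code{terminal_gal}).
#' @return Character short name.
#' @export
composeShortName <- function(composition, annotation) {
  comp <- .asComposition(composition)
  cls <- annotation$glycan_class
  gal <- annotation$terminal_gal + annotation$sialic_caps  # total Gal
  if (cls == "high-mannose")
    return(paste0("M", comp[["hex"]]))
  if (cls == "hybrid") {
    man <- comp[["hex"]] - gal
    base <- paste0("M", man, "A1")
    if (gal == 0L && comp[["neuac"]] == 0L) return(base)
    return(paste0(base, "G", gal, "S", comp[["neuac"]]))
  }
  fuc <- comp[["dhex"]]
  paste0("A", annotation$antennae,
         if (isTRUE(annotation$bisecting)) "B" else "",
         if (fuc == 1L) "F" else if (fuc > 1L) paste0("F", fuc) else "",
         "G", gal, "S", comp[["neuac"]])
}
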