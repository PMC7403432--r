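## Structural classification of compositions.  Composition alone cannot
## distinguish a bisected n-antennary glycan from an (n+1)-antennary one
## (both add one HexNAc), nor core from antenna fucose, so curated overrides
## take precedence over these heuristics wherever the panel provides them.

#' Construct a structural annotation
#'
#' @param glycan_class One of \code{"complex"}, \code{"hybrid"},
#'   \code{"high-mannose"}.
#' @param antennae Number of GlcNAc attachments to core Man residues (0-4).
#' @param bisecting Logical, bisecting GlcNAc present.
#' @param core_fucose,antenna_fucose Fucose placement counts; their sum must
#'   equal the composition's dHex count.
#' @param terminal_gal,terminal_glcnac,sialic_caps Terminal-residue profile.
#' @return A list of class \code{structuralAnnotation}.
#' @export
structuralAnnotation <- function(glycan_class, antennae, bisecting = FALSE,
                                 core_fucose = 0L, antenna_fucose = 0L,
                                 terminal_gal = 0L, terminal_glcnac = 0L,
                                 sialic_caps = 0L) {
  glycan_class <- match.arg(glycan_class,
                            c("complex", "hybrid", "high-mannose"))
  ann <- list(glycan_class = glycan_class, antennae = as.integer(antennae),
              bisecting = isTRUE(bisecting),
              core_fucose = as.integer(core_fucose),
              antenna_fucose = as.integer(antenna_fucose),
              terminal_gal = as.integer(terminal_gal),
              terminal_glcnac = as.integer(terminal_glcnac),
              sialic_caps = as.integer(sialic_caps))
  if (ann$antennae < 0L || ann$antennae > 4L)
    stop("antennae must be between 0 and 4")
  if (glycan_class == "high-mannose" &&
      (ann$antennae != 0L || ann$bisecting))
    stop("high-mannose glycans have no antennae and no bisecting GlcNAc")
  class(ann) <- "structuralAnnotation"
  ann
}

#' Classify a composition into a structural annotation
#'
#' Heuristic defaults mirroring deductive composition-based assignment:
#' high-mannose iff hexnac = 2, hex >= 5 and no fucose or sialic acid;
#' hybrid iff hexnac = 3 and hex >= 5; otherwise complex with
#' antennae = hexnac - 2 - bisecting.  Curated \code{overrides} (e.g.
#' \code{bisecting = TRUE}, fucose placement, terminal galactose) take
#' precedence, reflecting that isobaric structures are resolved by prior
#' MS/MS knowledge rather than by mass.
#'
#' @param composition A composition.
#' @param overrides Named list of annotation fragments overriding the
#'   heuristics (\code{bisecting}, \code{core_fucose},
#'   \code{antenna_fucose}, \code{gal} = total galactose count,
#'   \code{glycan_class}).
#' @return A \code{\link{structuralAnnotation}}.
#' @examples
#' classifySpecies(glycanComposition(hexnac = 2, hex = 9))  # high-mannose
#' classifySpecies(glycanComposition(hexnac = 5, hex = 6, neuac = 3))
#' @export
classifySpecies <- function(composition, overrides = list()) {
  comp <- .asComposition(composition)
  checkNGlycanCore(comp)
  ov <- overrides
  cls <- ov$glycan_class
  if (is.null(cls)) {
    cls <- if (comp[["hexnac"]] == 2L && comp[["hex"]] >= 5L &&
               comp[["neuac"]] == 0L && comp[["dhex"]] == 0L)
      "high-mannose"
    else if (comp[["hexnac"]] == 3L && comp[["hex"]] >= 5L)
      "hybrid"
    else "complex"
  }
  bisect <- isTRUE(ov$bisecting)
  antennae <- switch(cls,
    "high-mannose" = 0L,
    "hybrid" = 1L,
    "complex" = comp[["hexnac"]] - 2L - as.integer(bisect))
  ## default fucose placement: core for mono/bi-antennary, antenna-first
  ## for tri/tetra (the dominant placements on human plasma N-glycans)
  fuc <- comp[["dhex"]]
  if (!is.null(ov$core_fucose) || !is.null(ov$antenna_fucose)) {
    core_f <- if (is.null(ov$core_fucose)) fuc - ov$antenna_fucose
              else ov$core_fucose
    ant_f <- fuc - core_f
  } else if (antennae >= 3L) {
    ant_f <- fuc; core_f <- 0L
  } else {
    core_f <- min(fuc, 1L); ant_f <- fuc - core_f
  }
  if (core_f < 0L || ant_f < 0L)
    stop("fucose placement overrides exceed the dHex count")
  ## total galactose; each sialic acid is assumed to cap one galactose, so
  ## terminal (exposed) Gal = total Gal - NeuAc
  gal <- if (!is.null(ov$gal)) as.integer(ov$gal)
         else if (cls == "complex") max(comp[["hex"]] - 3L, 0L)
         else 0L
  term_gal <- max(gal - comp[["neuac"]], 0L)
  structuralAnnotation(glycan_class = cls, antennae = antennae,
                       bisecting = bisect, core_fucose = core_f,
                       antenna_fucose = ant_f, terminal_gal = term_gal,
                       terminal_glcnac = max(antennae - gal, 0L),
                       sialic_caps = comp[["neuac"]])
}
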