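## The curated reference panel of quantified plasma N-glycan species.

#' @import methods
NULL

#' GlycanPanel: a curated reference panel of N-glycan species
#'
#' Holds, per species: short name, monosaccharide composition, theoretical
#' permethylated sodiated monoisotopic m/z, curated structural labels
#' (class, antennarity, bisecting, fucose placement, terminal galactose) and
#' a baseline relative abundance (percent) describing a reference plasma
#' N-glycome.
#'
#' @slot name Panel identifier.
#' @slot version Panel version string.
#' @slot species \code{data.frame}, one row per species.
#' @export
setClass("GlycanPanel",
         representation(name = "character", version = "character",
                        species = "data.frame"))

.panelRequiredCols <- c("short_name", "hexnac", "hex", "dhex", "neuac",
                        "mz", "glycan_class", "antennae", "bisecting",
                        "core_fucose", "antenna_fucose", "terminal_gal",
                        "baseline_pct")

setValidity("GlycanPanel", function(object) {
  sp <- object@species
  miss <- setdiff(.panelRequiredCols, colnames(sp))
  if (length(miss))
    return(paste("missing species columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(sp$short_name))
    return("species short names must be unique")
  theo <- apply(sp[, c("hexnac", "hex", "dhex", "neuac")], 1L,
                function(r) permethylatedMz(glycanComposition(
                  r[["hexnac"]], r[["hex"]], r[["dhex"]], r[["neuac"]])))
  if (any(abs(theo - sp$mz) > 0.01))
    return("stored m/z disagrees with the mass engine by more than 0.01 Da")
  if (any(sp$mz < 1500 | sp$mz > 5000))
    return("m/z outside the 1500-5000 acquisition window")
  if (nrow(sp) > 1L) {
    gaps <- diff(sort(sp$mz))
    if (min(gaps) <= 2 * defaultAnnotationTolerance())
      return("species m/z values closer than twice the annotation tolerance")
  }
  if (any(sp$core_fucose + sp$antenna_fucose != sp$dhex))
    return("core_fucose + antenna_fucose must equal dhex")
  TRUE
})

#' Default annotation tolerance (Da)
#'
#' Half-width used when matching picked peaks to panel species.  0.5 Da is
#' conservative for singly charged permethylated species, whose panel
#' spacings are far larger.
#' @return Numeric scalar, Da.
#' @export
defaultAnnotationTolerance <- function() 0.5

#' @describeIn GlycanPanel number of species
#' @param x,object A \code{GlycanPanel}.
#' @export
setMethod("length", "GlycanPanel", function(x) nrow(x@species))

#' Species table of a panel
#' @param panel A \code{GlycanPanel}.
#' @return The species \code{data.frame}.
#' @export
panelSpecies <- function(panel) panel@species

#' Short names of the panel species
#' @param panel A \code{GlycanPanel}.
#' @export
panelNames <- function(panel) panel@species$short_name

#' Theoretical m/z values of the panel species
#' @param panel A \code{GlycanPanel}.
#' @export
panelMz <- function(panel) stats::setNames(panel@species$mz,
                                           panel@species$short_name)

#' Baseline (reference) profile of the panel
#' @param panel A \code{GlycanPanel}.
#' @return Named percent vector summing to 100.
#' @export
panelBaseline <- function(panel) stats::setNames(panel@species$baseline_pct,
                                                 panel@species$short_name)

setMethod("show", "GlycanPanel", function(object) {
  sp <- object@species
  cat("GlycanPanel '", object@name, "' (version ", object@version, ")\n",
      sep = "")
  cat(" ", nrow(sp), " species, m/z ", round(min(sp$mz), 1), "-",
      round(max(sp$mz), 1), "\n", sep = "")
  cat("  classes:", paste(sprintf("%s=%d", names(table(sp$glycan_class)),
                                  table(sp$glycan_class)), collapse = " "),
      "\n")
})

## ---------------------------------------------------------------------------
## Curated default panel: 57 plasma N-glycan species.  Baselines describe a
## reference (major-allele) plasma N-glycome: dominated by the disialylated
## bi-antennary species, with category totals (percent) of mono 1.09,
## bi 88.0, tri 6.77, tetra 0.574, high-mannose 3.4, hybrid 0.166, and
## bisecting 7.83.  Fucose placement overrides mark curated exceptions to
## the composition heuristics (e.g. core-fucosylated tri-antennary species).

.defaultPanelTable <- function() {
  spec <- list(
    ## name, baseline %, list of curated overrides (or NULL)
    list("M5",       1.200, NULL), list("M6", 0.800, NULL),
    list("M7",       0.500, NULL), list("M8", 0.500, NULL),
    list("M9",       0.400, NULL),
    list("M5A1",     0.050, NULL), list("M6A1", 0.040, NULL),
    list("M4A1G1S1", 0.036, NULL), list("M5A1G1S1", 0.020, NULL),
    list("M6A1G1S1", 0.020, NULL),
    list("A1FG0S0",  0.100, NULL), list("A1G1S0", 0.250, NULL),
    list("A1FG1S0",  0.150, NULL), list("A1G1S1", 0.450, NULL),
    list("A1FG1S1",  0.140, NULL),
    list("A2G0S0",   1.600, NULL), list("A2FG0S0", 2.300, NULL),
    list("A2G1S0",   1.000, NULL), list("A2FG1S0", 1.200, NULL),
    list("A2G1S1",   0.439, NULL), list("A2FG1S1", 0.800, NULL),
    list("A2G2S0",   1.500, NULL), list("A2FG2S0", 2.200, NULL),
    list("A2G2S1",  16.000, NULL), list("A2FG2S1", 6.000, NULL),
    list("A2G2S2",  40.881, NULL), list("A2FG2S2", 6.500, NULL),
    list("A2BG0S0",  0.400, NULL), list("A2BG1S0", 0.500, NULL),
    list("A2BG1S1",  0.400, NULL), list("A2BFG1S1", 0.400, NULL),
    list("A2BG2S0",  0.630, NULL), list("A2BFG2S0", 0.500, NULL),
    list("A2BG2S1",  1.200, NULL), list("A2BFG2S1", 1.100, NULL),
    list("A2BG2S2",  1.450, NULL), list("A2BFG2S2", 1.000, NULL),
    list("A3G3S0",   0.050, NULL), list("A3G3S1", 0.150, NULL),
    list("A3G3S2",   0.450, NULL), list("A3G3S3", 3.680, NULL),
    list("A3FG3S0",  0.070, list(core_fucose = 1L)),
    list("A3FG3S1",  0.100, list(core_fucose = 1L)),
    list("A3FG3S2",  0.290, NULL),
    list("A3FG3S3",  1.580, NULL),
    list("A3F2G3S2", 0.050, list(core_fucose = 1L)),
    list("A3F2G3S3", 0.100, list(core_fucose = 1L)),
    list("A3BG3S1",  0.100, NULL), list("A3BG3S2", 0.050, NULL),
    list("A3BG3S3",  0.100, NULL),
    list("A4G4S1",   0.070, NULL), list("A4G4S2", 0.114, NULL),
    list("A4G4S3",   0.120, NULL), list("A4G4S4", 0.180, NULL),
    list("A4FG4S2",  0.020, list(core_fucose = 1L)),
    list("A4FG4S3",  0.020, NULL), list("A4FG4S4", 0.050, NULL)
  )
  rows <- lapply(spec, function(s) {
    parsed <- parseShortName(s[[1]])
    ov <- s[[3]]
    ov$bisecting <- parsed$bisecting
    ov$gal <- parsed$gal
    if (!is.na(parsed$glycan_class)) ov$glycan_class <- parsed$glycan_class
    ann <- classifySpecies(parsed$composition, overrides = ov)
    comp <- parsed$composition
    data.frame(short_name = s[[1]], hexnac = comp[["hexnac"]],
               hex = comp[["hex"]], dhex = comp[["dhex"]],
               neuac = comp[["neuac"]],
               mz = permethylatedMz(comp),
               glycan_class = ann$glycan_class, antennae = ann$antennae,
               bisecting = ann$bisecting, core_fucose = ann$core_fucose,
               antenna_fucose = ann$antenna_fucose,
               terminal_gal = ann$terminal_gal,
               baseline_pct = s[[2]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the packaged default glycan panel
#'
#' Returns the 57-species curated plasma N-glycan panel shipped with the
#' package (read from its versioned JSON document under
#' \code{inst/extdata}).  Every species passes the m/z consistency
#' invariant against the mass engine.
#'
#' @return A \code{\linkS4class{GlycanPanel}} of 57 species.
#' @examples
#' panel <- buildDefaultPanel()
#' length(panel)
#' @export
buildDefaultPanel <- function() {
  path <- system.file("extdata", "panel57.json", package = "glycomn")
  if (nzchar(path)) return(readPanel(path))
  ## fallback (e.g. during in-source development before installation)
  new("GlycanPanel", name = "plasma57", version = "1.0",
      species = .defaultPanelTable())
}

#' Read a glycan panel from its JSON document
#'
#' @param path Path to a panel JSON file (fields: name, version, species).
#' @return A \code{\linkS4class{GlycanPanel}}.
#' @export
readPanel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- as.data.frame(doc$species, stringsAsFactors = FALSE)
  for (col in c("hexnac", "hex", "dhex", "neuac", "antennae",
                "core_fucose", "antenna_fucose", "terminal_gal"))
    sp[[col]] <- as.integer(sp[[col]])
  sp$bisecting <- as.logical(sp$bisecting)
  new("GlycanPanel", name = doc$name, version = doc$version, species = sp)
}

#' Write a glycan panel to a JSON document
#'
#' @param panel A \code{GlycanPanel}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writePanel <- function(panel, path) {
  doc <- list(name = panel@name, version = panel@version,
              species = panel@species)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
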