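## Structural categories over the panel and compositional summaries.

#' Default structural category definitions
#'
#' Returns the named list of membership predicates used for grouped
#' analysis.  The antennarity categories (mono- through tetra-antennary)
#' are mutually exclusive and, together with high-mannose and hybrid,
#' partition the panel; the remaining categories (bisecting, fucosylation
#' and terminal-residue classes) overlap them.
#'
#' @return Named list of functions taking the panel species
#'   \code{data.frame} and returning a logical membership vector.
#' @export
defaultCategories <- function() {
  list(
    `mono-antennary`  = function(sp) sp$glycan_class == "complex" & sp$antennae == 1L,
    `bi-antennary`    = function(sp) sp$glycan_class == "complex" & sp$antennae == 2L,
    `tri-antennary`   = function(sp) sp$glycan_class == "complex" & sp$antennae == 3L,
    `tetra-antennary` = function(sp) sp$glycan_class == "complex" & sp$antennae == 4L,
    `high-mannose`    = function(sp) sp$glycan_class == "high-mannose",
    hybrid            = function(sp) sp$glycan_class == "hybrid",
    `more-than-two-antennae` = function(sp)
      sp$glycan_class == "complex" & sp$antennae > 2L,
    bisecting         = function(sp) sp$bisecting,
    `core-fucosylated`    = function(sp) sp$core_fucose > 0L,
    `antenna-fucosylated` = function(sp) sp$antenna_fucose > 0L,
    sialylated        = function(sp) sp$neuac > 0L,
    `terminal-gal`    = function(sp) sp$terminal_gal > 0L,
    `terminal-glcnac` = function(sp)
      sp$glycan_class == "complex" &
        sp$antennae > sp$terminal_gal + sp$neuac
  )
}

## names of the categories that partition the panel
.partitionCategories <- c("mono-antennary", "bi-antennary", "tri-antennary",
                          "tetra-antennary", "high-mannose", "hybrid")

#' Aggregate a glycome profile by structural category
#'
#' Category value = sum of the abundances of its member species.
#'
#' @param profiles A \code{\linkS4class{GlycomeExperiment}} or a named
#'   percent vector / species x samples matrix matching the panel.
#' @param panel A \code{\linkS4class{GlycanPanel}} (taken from the
#'   experiment when omitted).
#' @param categories Category definitions
#'   (default \code{\link{defaultCategories}}).
#' @return Category x samples matrix of percent (or a named vector for a
#'   single profile).
#' @examples
#' panel <- buildDefaultPanel()
#' aggregateByCategory(panelBaseline(panel), panel)
#' @export
aggregateByCategory <- function(profiles, panel = NULL,
                                categories = defaultCategories()) {
  if (is(profiles, "GlycomeExperiment")) {
    panel <- glycomePanel(profiles)
    m <- glycomePercent(profiles)
  } else if (is.matrix(profiles)) m <- profiles
  else m <- matrix(profiles, ncol = 1L,
                   dimnames = list(names(profiles), "profile"))
  sp <- panelSpecies(panel)
  if (!all(rownames(m) %in% sp$short_name))
    stop("profile refers to species unknown to the panel")
  sp <- sp[match(rownames(m), sp$short_name), ]
  out <- vapply(categories, function(pred) {
    member <- pred(sp)
    if (any(is.na(member))) stop("category predicate returned NA")
    colSums(m[member, , drop = FALSE])
  }, numeric(ncol(m)))
  out <- t(matrix(out, ncol = length(categories),
                  dimnames = list(colnames(m), names(categories))))
  if (ncol(out) == 1L && !is.matrix(profiles) &&
      !is(profiles, "GlycomeExperiment")) out[, 1L] else out
}

#' Monosaccharide contribution to the total N-glycan pool
#'
#' For each sample, the contribution of a monosaccharide is the sum over
#' glycans of (that monosaccharide's count fraction within the glycan) x
#' (the glycan's abundance).  Count-based by default; set
#' \code{weight = "mass"} to weight residues by their permethylated masses
#' instead.  Hex is reported split into Man and Gal where curated terminal
#' labels permit (Gal = terminal_gal, Man = remaining Hex), pooled
#' otherwise.
#'
#' @inheritParams aggregateByCategory
#' @param weight \code{"count"} (default) or \code{"mass"}.
#' @param splitHex Split Hex into Man/Gal using curated labels
#'   (default TRUE).
#' @return Monosaccharide x samples percent matrix (columns sum to 100),
#'   or a named vector for a single profile.
#' @export
monosaccharideContribution <- function(profiles, panel = NULL,
                                       weight = c("count", "mass"),
                                       splitHex = TRUE) {
  weight <- match.arg(weight)
  if (is(profiles, "GlycomeExperiment")) {
    panel <- glycomePanel(profiles)
    m <- glycomePercent(profiles)
  } else if (is.matrix(profiles)) m <- profiles
  else m <- matrix(profiles, ncol = 1L,
                   dimnames = list(names(profiles), "profile"))
  sp <- panelSpecies(panel)[match(rownames(m), panelSpecies(panel)$short_name), ]
  counts <- cbind(GlcNAc = sp$hexnac, Hex = sp$hex, Fuc = sp$dhex,
                  NeuAc = sp$neuac)
  if (splitHex) {
    gal <- sp$terminal_gal + sp$neuac  # galactoses = terminal + sialylated
    gal <- pmin(gal, sp$hex)
    counts <- cbind(GlcNAc = sp$hexnac, Man = sp$hex - gal, Gal = gal,
                    Fuc = sp$dhex, NeuAc = sp$neuac)
  }
  if (weight == "mass") {
    rm_ <- vapply(.monosaccharides, function(x)
      .formulaMass(.residueFormulas[[x]]), numeric(1))
    w <- c(GlcNAc = rm_[["hexnac"]], Man = rm_[["hex"]],
           Gal = rm_[["hex"]], Hex = rm_[["hex"]], Fuc = rm_[["dhex"]],
           NeuAc = rm_[["neuac"]])
    counts <- sweep(counts, 2L, w[colnames(counts)], `*`)
  }
  frac <- counts / rowSums(counts)
  out <- t(frac) %*% m
  if (ncol(out) == 1L && !is.matrix(profiles) &&
      !is(profiles, "GlycomeExperiment")) out[, 1L] else out
}
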