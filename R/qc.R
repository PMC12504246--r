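#' @include AllClasses.R atlas.R
NULL

qcLabels <- c("accurate", "inaccurate", "uncertain", "damage", "outside")

#' Generate a systematic sampling grid over a section
#'
#' Lays a regular grid of assessment points over the registration-resolution
#' image for manual systematic sampling of registration accuracy and tissue
#' damage. Points are enumerated row-major (y outer, x inner). Points whose
#' label-map value is 0 are prefilled \code{"outside"}; the rest are left
#' unlabeled for the rater.
#'
#' @param width,height Image dimensions in pixels.
#' @param spacing Grid spacing in pixels (>= 1).
#' @param offset Numeric (x, y) grid offset in pixels, default (0, 0).
#' @param lm Optional label map used for prefilling.
#' @return A \code{data.frame} with columns \code{index, x, y, label}
#'   (\code{label} is \code{NA} where unassessed), carrying \code{spacing}
#'   and \code{offset} as attributes.
#' @examples
#' g <- generateGrid(10, 10, spacing = 5)
#' g[, c("x", "y")]
#' @export
generateGrid <- function(width, height, spacing, offset = c(0, 0), lm = NULL) {
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing < 1)
    stop("spacing must be >= 1", call. = FALSE)
  xs <- seq(offset[1], width - 1, by = spacing)
  ys <- seq(offset[2], height - 1, by = spacing)
  xs <- xs[xs >= 0]; ys <- ys[ys >= 0]
  g <- expand.grid(x = xs, y = ys)[, c("x", "y")]  # row-major: y outer
  g <- g[order(g$y, g$x), ]
  g <- data.frame(index = seq_len(nrow(g)), x = g$x, y = g$y,
                  label = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(lm)) {
    v <- lm[cbind(roundHalfAway(g$y) + 1, roundHalfAway(g$x) + 1)]
    g$label[v == 0L] <- "outside"
  }
  attr(g, "spacing") <- spacing
  attr(g, "offset") <- offset
  g
}

#' Read and write assessment tables
#'
#' Assessments are exchanged as CSV with columns \code{index, label}; labels
#' come from the vocabulary \code{accurate, inaccurate, uncertain, damage,
#' outside}. \code{applyAssessment} merges a rater's CSV into a grid.
#'
#' @param grid A grid \code{data.frame} from [generateGrid()].
#' @param path CSV file path.
#' @return \code{readAssessment} returns a \code{data.frame};
#'   \code{applyAssessment} returns the grid with labels filled in;
#'   \code{writeAssessment} returns \code{path} invisibly.
#' @export
readAssessment <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(a$label), qcLabels)
  if (length(bad))
    stop("unknown assessment labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  a
}

#' @rdname readAssessment
#' @export
writeAssessment <- function(grid, path) {
  utils::write.csv(grid[, c("index", "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname readAssessment
#' @export
applyAssessment <- function(grid, path) {
  a <- if (is.character(path)) readAssessment(path) else path
  i <- match(a$index, grid$index)
  if (anyNA(i))
    stop("assessment refers to unknown grid indices", call. = FALSE)
  grid$label[i] <- a$label
  grid
}

#' Registration-accuracy and damage statistics over a sampling grid
#'
#' Attributes every in-tissue grid point (any label other than
#' \code{"outside"}) to its reporting region through the label map and region
#' mapping, then computes per-region accuracy
#' \eqn{\mathrm{accurate}/(\mathrm{accurate}+\mathrm{inaccurate})} — points
#' marked \code{uncertain} are excluded from the denominator — and per-region
#' and per-section damage fractions (damage points over in-tissue points).
#' Regions, and the section itself, whose damage fraction exceeds
#' \code{damageThreshold} are listed for exclusion.
#'
#' @param grid Grid \code{data.frame} from [generateGrid()].
#' @param lm Label map of the section.
#' @param mapping Named integer vector from [collapseHierarchy()], or
#'   \code{NULL} for raw label granularity.
#' @param damageThreshold Damage fraction above which a region or section is
#'   excluded (default 1, i.e. never).
#' @param hierarchy Optional hierarchy for region names.
#' @param sectionNr Section number recorded in the summary.
#' @return A list with elements \code{regions} (a \code{data.frame} with
#'   columns \code{region_id, region_name, accurate, inaccurate, uncertain,
#'   damage, points, accuracy, damage_fraction, excluded}), \code{section}
#'   (one-row \code{data.frame} with \code{section_nr, in_tissue_points,
#'   damage_points, damage_fraction, excluded}; fractions are \code{NA} when
#'   no point is in tissue) and \code{excludedRegions} (integer vector).
#' @export
qcStatistics <- function(grid, lm, mapping = NULL, damageThreshold = 1,
                         hierarchy = NULL, sectionNr = 0L) {
  if (anyNA(grid$label))
    stop(sum(is.na(grid$label)), " grid point(s) remain unlabeled; complete ",
         "the assessment first", call. = FALSE)
  bad <- setdiff(unique(grid$label), qcLabels)
  if (length(bad))
    stop("unknown assessment labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  inTissue <- grid$label != "outside"
  raw <- lm[cbind(roundHalfAway(grid$y) + 1, roundHalfAway(grid$x) + 1)]
  region <- if (is.null(mapping)) raw else applyMapping(raw, mapping)

  ids <- sort(unique(region[inTissue]))
  cnt <- function(lab, id) sum(inTissue & grid$label == lab & region == id)
  regions <- do.call(rbind, lapply(ids, function(id) {
    acc <- cnt("accurate", id); inacc <- cnt("inaccurate", id)
    unc <- cnt("uncertain", id); dmg <- cnt("damage", id)
    pts <- sum(inTissue & region == id)
    data.frame(region_id = id,
               accurate = acc, inaccurate = inacc, uncertain = unc,
               damage = dmg, points = pts,
               accuracy = if (acc + inacc > 0) acc / (acc + inacc) else NA_real_,
               damage_fraction = if (pts > 0) dmg / pts else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(regions)) {
    regions <- data.frame(region_id = integer(), accurate = integer(),
                          inaccurate = integer(), uncertain = integer(),
                          damage = integer(), points = integer(),
                          accuracy = numeric(), damage_fraction = numeric(),
                          excluded = logical(), region_name = character(),
                          stringsAsFactors = FALSE)
  } else {
    regions$excluded <- !is.na(regions$damage_fraction) &
      regions$damage_fraction > damageThreshold
  }
  if (is(hierarchy, "AtlasVolume")) hierarchy <- hierarchy@hierarchy
  regions$region_name <- if (is.null(hierarchy))
    ifelse(regions$region_id == 0L, "background",
           paste0("region_", regions$region_id))
  else regionName(hierarchy, regions$region_id)
  regions <- regions[, c("region_id", "region_name", "accurate", "inaccurate",
                         "uncertain", "damage", "points", "accuracy",
                         "damage_fraction", "excluded")]

  nTissue <- sum(inTissue)
  nDamage <- sum(inTissue & grid$label == "damage")
  secFrac <- if (nTissue > 0) nDamage / nTissue else NA_real_
  section <- data.frame(
    section_nr = as.integer(sectionNr),
    in_tissue_points = nTissue, damage_points = nDamage,
    damage_fraction = secFrac,
    excluded = !is.na(secFrac) && secFrac > damageThreshold,
    stringsAsFactors = FALSE)

  list(regions = regions, section = section,
       excludedRegions = regions$region_id[regions$excluded])
}

#' Write QC report tables
#'
#' Tab-separated outputs of [qcStatistics()]: a per-region table
#' (\code{region_id, region_name, accurate, inaccurate, uncertain, accuracy},
#' plus damage columns) and a per-section summary (\code{section_nr,
#' in_tissue_points, damage_points, damage_fraction, excluded}). Column
#' headers document that \code{uncertain} points are excluded from accuracy
#' denominators.
#'
#' @param qc Result of [qcStatistics()] (or a list of them, one per section).
#' @param regionPath,sectionPath Output TSV paths.
#' @return \code{regionPath}, invisibly.
#' @export
writeQCReport <- function(qc, regionPath, sectionPath) {
  if (!is.null(qc$regions)) qc <- list(qc)
  regions <- do.call(rbind, lapply(qc, function(q) {
    r <- q$regions
    if (nrow(r)) r$section_nr <- q$section$section_nr
    else r$section_nr <- integer(0)
    r
  }))
  sections <- do.call(rbind, lapply(qc, `[[`, "section"))
  con <- file(regionPath, "w")
  writeLines(paste0("# accuracy = accurate / (accurate + inaccurate); ",
                    "uncertain points excluded from the denominator"), con)
  utils::write.table(regions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  utils::write.table(sections, sectionPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(regionPath)
}
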