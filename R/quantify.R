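#' @include AllClasses.R atlas.R
NULL

#' Read a binary segmentation image
#'
#' Reads a PNG or TIFF segmentation (foreground = feature of interest).
#' Multi-channel images are reduced by the per-pixel maximum over the color
#' channels (alpha ignored); a pixel is foreground when its value exceeds
#' \code{threshold} (on the 0..1 intensity scale).
#'
#' @param path PNG or TIFF file.
#' @param threshold Foreground threshold for grayscale inputs (default 0:
#'   any nonzero pixel is foreground).
#' @return An integer 0/1 matrix.
#' @export
readSegmentation <- function(path, threshold = 0) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported segmentation format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L)
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE], c(1, 2), max)
  matrix(as.integer(img > threshold), nrow = nrow(img))
}

# Nearest-neighbor resample of a matrix to target dims (preserves binarity
# and label identity).
resampleNearest <- function(m, height, width) {
  ri <- pmin(nrow(m), pmax(1, roundHalfAway((0:(height - 1)) *
          (nrow(m) - 1) / max(1, height - 1)) + 1))
  ci <- pmin(ncol(m), pmax(1, roundHalfAway((0:(width - 1)) *
          (ncol(m) - 1) / max(1, width - 1)) + 1))
  m[ri, ci, drop = FALSE]
}

#' Quantify a segmentation against a section's atlas regions
#'
#' Tallies a binary segmentation within the regions of a section label map,
#' optionally collapsed to reporting ("parent") regions and restricted to one
#' hemisphere. Objects are 8-connected components of the foreground. In
#' \code{"split"} mode (default) components are computed after region
#' splitting: each maximal connected foreground run within one reporting
#' region is one object there, so pixel tallies conserve exactly. In
#' \code{"centroid"} mode whole components are assigned to the region under
#' the component centroid (rounded to the nearest pixel); pixel counts then
#' conserve globally but a region's object pixels may exceed its own pixel
#' count. A row with \code{region_id} 0 collects background so that region
#' pixels plus background equal the (masked) pixel total.
#'
#' @param seg Integer/logical segmentation matrix, or a file path accepted by
#'   [readSegmentation()]. Resampled (nearest-neighbor) to the label map
#'   dimensions when they differ, unless \code{resample = FALSE}.
#' @param lm Integer label map from [sliceAtlas()] or [warpedLabelMap()].
#' @param mapping Named integer vector from [collapseHierarchy()], or
#'   \code{NULL} to report at raw label granularity.
#' @param hemiMask Optional [HemiMask-class]; required when \code{side} is
#'   \code{"left"} or \code{"right"}.
#' @param side Hemisphere restriction: \code{"none"}, \code{"left"} or
#'   \code{"right"}.
#' @param mode Object counting rule, \code{"split"} or \code{"centroid"}.
#' @param hierarchy Hierarchy \code{data.frame} or [AtlasVolume-class] for
#'   region names (optional).
#' @param sectionNr Section number recorded in the report.
#' @param resample Allow resampling of \code{seg} to the label map dims.
#' @return A [QuantReport-class].
#' @export
quantifySection <- function(seg, lm, mapping = NULL, hemiMask = NULL,
                            side = c("none", "left", "right"),
                            mode = c("split", "centroid"),
                            hierarchy = NULL, sectionNr = 0L,
                            resample = TRUE) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  if (is.character(seg)) seg <- readSegmentation(seg)
  seg <- matrix(as.integer(seg != 0), nrow = nrow(seg))
  if (!all(dim(seg) == dim(lm))) {
    if (!resample)
      stop("segmentation dims (", paste(dim(seg), collapse = "x"),
           ") do not match label map dims (", paste(dim(lm), collapse = "x"),
           ") and resampling is disabled", call. = FALSE)
    seg <- resampleNearest(seg, nrow(lm), ncol(lm))
  }
  cl <- if (is.null(mapping)) lm else applyMapping(lm, mapping)
  if (side == "none") {
    sel <- matrix(TRUE, nrow(lm), ncol(lm))
  } else {
    if (is.null(hemiMask))
      stop("side = '", side, "' requires a hemisphere mask", call. = FALSE)
    if (!all(dim(hemiMask@left) == dim(lm)))
      stop("hemisphere mask dims do not match label map dims", call. = FALSE)
    sel <- if (side == "left") hemiMask@left else !hemiMask@left
  }
  fg <- seg == 1L & sel

  reportIds <- sort(unique(c(0L,
    if (!is.null(mapping)) setdiff(unique(as.integer(mapping)), 0L),
    unique(cl[sel]))))
  regionPixels <- vapply(reportIds, function(id) sum(cl[sel] == id), integer(1))
  objectPixels <- vapply(reportIds, function(id) sum(fg & cl == id), integer(1))
  objectCount <- integer(length(reportIds))

  if (any(fg)) {
    if (mode == "split") {
      clsMat <- ifelse(fg, cl, -1L)
      labm <- .labelComponents8(clsMat)
      k <- max(labm)
      if (k > 0) {
        first <- match(seq_len(k), labm)
        compClass <- cl[first]
        tab <- table(factor(compClass, levels = reportIds))
        objectCount <- as.integer(tab)
      }
    } else {
      clsMat <- ifelse(fg, 0L, -1L)
      labm <- .labelComponents8(clsMat)
      k <- max(labm)
      objectPixels <- integer(length(reportIds))
      if (k > 0) {
        pos <- which(labm > 0)
        comp <- labm[pos]
        py <- (pos - 1L) %% nrow(labm)        # 0-based pixel y
        px <- (pos - 1L) %/% nrow(labm)       # 0-based pixel x
        sizes <- tabulate(comp, k)
        cenX <- roundHalfAway(tapply(px, comp, mean))
        cenY <- roundHalfAway(tapply(py, comp, mean))
        compRegion <- cl[cbind(cenY + 1, cenX + 1)]
        for (c in seq_len(k)) {
          j <- match(compRegion[c], reportIds)
          if (is.na(j)) j <- match(0L, reportIds)
          objectCount[j] <- objectCount[j] + 1L
          objectPixels[j] <- objectPixels[j] + sizes[c]
        }
      }
    }
  }

  if (is(hierarchy, "AtlasVolume")) hierarchy <- hierarchy@hierarchy
  nms <- if (is.null(hierarchy)) ifelse(reportIds == 0L, "background",
                                        paste0("region_", reportIds))
         else regionName(hierarchy, reportIds)
  stats <- data.frame(
    region_id = reportIds, region_name = nms,
    region_pixels = regionPixels, object_pixels = objectPixels,
    object_count = objectCount,
    load = ifelse(regionPixels > 0, objectPixels / regionPixels, 0),
    stringsAsFactors = FALSE)
  new("QuantReport", sectionNr = as.integer(sectionNr), mask = side,
      mode = mode, mappingKey = mappingKey(mapping), stats = stats)
}

#' Aggregate per-section reports over a series
#'
#' Sums region, object and count tallies across sections and recomputes the
#' load from the summed pixels (never by averaging per-section loads, which
#' would weight small and large sections equally). All reports must share the
#' same region mapping, hemisphere restriction and counting mode.
#'
#' @param reports A list of [QuantReport-class] objects.
#' @return A \code{data.frame} with the same columns as a single report's
#'   statistics.
#' @export
aggregateReports <- function(reports) {
  if (!length(reports)) stop("no reports to aggregate", call. = FALSE)
  keys <- vapply(reports, function(r) r@mappingKey, character(1))
  if (length(unique(keys)) != 1L)
    stop("reports quantified under different region mappings cannot be ",
         "aggregated", call. = FALSE)
  if (length(unique(vapply(reports, function(r) r@mask, character(1)))) != 1L)
    stop("reports with different hemisphere masks cannot be aggregated",
         call. = FALSE)
  all <- do.call(rbind, lapply(reports, function(r) r@stats))
  agg <- aggregate(all[c("region_pixels", "object_pixels", "object_count")],
                   by = list(region_id = all$region_id), FUN = sum)
  agg$region_name <- all$region_name[match(agg$region_id, all$region_id)]
  agg$load <- ifelse(agg$region_pixels > 0,
                     agg$object_pixels / agg$region_pixels, 0)
  agg <- agg[order(agg$region_id),
             c("region_id", "region_name", "region_pixels",
               "object_pixels", "object_count", "load")]
  rownames(agg) <- NULL
  agg
}

#' Derive a per-section hemisphere mask from the atlas midline
#'
#' Assigns every pixel of a section to the left or right hemisphere by
#' mapping it to atlas space (through the nonlinear warp first, when markers
#' are given, so the mask respects deformations applied around the midline)
#' and comparing its coordinate along the atlas midline axis with the
#' declared midsagittal plane. Coordinates strictly below the plane are left;
#' on-plane coordinates count as right (a fixed tie convention).
#'
#' @param atlas An [AtlasVolume-class] with midline metadata.
#' @param a A [SectionAnchoring-class].
#' @param markers Optional warp marker matrix as in [buildWarp()].
#' @return A [HemiMask-class] (\code{height x width}).
#' @export
hemisphereMask <- function(atlas, a, markers = NULL) {
  if (is.na(atlas@midlineAxis))
    stop("atlas has no midline metadata; declare midline_axis/midline_coord ",
         "in the hierarchy JSON", call. = FALSE)
  validObject(a)
  gx <- rep(0:(a@width - 1), each = a@height)
  gy <- rep(0:(a@height - 1), times = a@width)
  if (!is.null(markers) && nrow(as.matrix(markers)) > 0L) {
    w <- buildWarp(markers, a@width, a@height)
    src <- warpLookup(w, gx, gy)
    gx <- src[, 1]; gy <- src[, 2]
  }
  coords <- pixelToAtlas(a, gx, gy)
  left <- coords[, atlas@midlineAxis] < atlas@midlineCoord
  new("HemiMask", left = matrix(left, nrow = a@height, ncol = a@width))
}

#' Write and read quantification tables
#'
#' Tab-separated report with columns \code{region_id, region_name,
#' region_pixels, object_pixels, object_count, load}.
#'
#' @param report A [QuantReport-class] or an aggregated \code{data.frame}
#'   from [aggregateReports()].
#' @param path Output TSV path.
#' @return \code{writeQuantReport} returns \code{path} invisibly;
#'   \code{readQuantReport} returns a \code{data.frame}.
#' @export
writeQuantReport <- function(report, path) {
  stats <- if (is(report, "QuantReport")) report@stats else report
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeQuantReport
#' @export
readQuantReport <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
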