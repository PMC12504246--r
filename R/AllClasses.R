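#' @import methods
NULL

#' Volumetric label atlas
#'
#' An \code{AtlasVolume} holds a 3D grid of integer region labels together
#' with voxel size, optional midsagittal-plane metadata, and the region
#' hierarchy used for reporting. Atlas coordinates throughout the package are
#' continuous 0-based voxel indices with voxel centers at integers; label 0 is
#' background everywhere and is never a hierarchy node.
#'
#' @slot name Character, atlas name.
#' @slot labels 3D integer array of region ids (0 = background).
#' @slot voxelSize Numeric length-3, voxel size in micrometers along each axis.
#' @slot midlineAxis Integer in 1..3, the axis orthogonal to the midsagittal
#'   plane, or \code{NA} when no midline is declared.
#' @slot midlineCoord Numeric, plane coordinate in 0-based voxel units along
#'   \code{midlineAxis}; coordinates strictly below it are "left".
#' @slot hierarchy A \code{data.frame} of region nodes with columns
#'   \code{id}, \code{name}, \code{parent_id} (\code{NA} for roots),
#'   \code{r}, \code{g}, \code{b}.
#'
#' @seealso [readAtlas()], [sliceAtlas()], [collapseHierarchy()]
#' @export
setClass("AtlasVolume",
  representation(
    name = "character",
    labels = "array",
    voxelSize = "numeric",
    midlineAxis = "integer",
    midlineCoord = "numeric",
    hierarchy = "data.frame"
  )
)

setValidity("AtlasVolume", function(object) {
  msg <- character()
  d <- dim(object@labels)
  if (length(d) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  else if (any(d < 2L))
    msg <- c(msg, "every atlas dimension must be >= 2")
  if (!is.integer(object@labels))
    msg <- c(msg, "labels must be integer")
  else if (any(object@labels < 0L))
    msg <- c(msg, "labels must be non-negative")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive finite numbers")
  if (length(object@midlineAxis) != 1L || length(object@midlineCoord) != 1L)
    msg <- c(msg, "midline metadata must be scalar")
  else if (!is.na(object@midlineAxis)) {
    if (!(object@midlineAxis %in% 1:3))
      msg <- c(msg, "midlineAxis must be in 1..3")
    else if (length(d) == 3L &&
             (is.na(object@midlineCoord) || object@midlineCoord < 0 ||
              object@midlineCoord > d[object@midlineAxis] - 1))
      msg <- c(msg, "midlineCoord must lie within [0, dim(axis) - 1]")
  }
  hmsg <- validateHierarchy(object@hierarchy)
  msg <- c(msg, hmsg)
  if (length(msg) == 0L && length(d) == 3L) {
    used <- sort(unique(as.vector(object@labels)))
    used <- used[used != 0L]
    missing <- setdiff(used, object@hierarchy$id)
    if (length(missing))
      msg <- c(msg, paste0("atlas labels not present in hierarchy: ",
                           paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Affine placement of a 2D section in atlas space
#'
#' A \code{SectionAnchoring} encodes one section's cut plane through the atlas
#' as an origin \code{o} (the atlas position of pixel (0,0)) and two in-plane
#' spanning vectors \code{u} and \code{v} covering the image's x and y extent.
#' Pixel \eqn{(x, y)} of a \eqn{W \times H} registration-resolution image maps
#' to \eqn{o + u\,x/(W-1) + v\,y/(H-1)}, so the four image corners map exactly
#' to \eqn{o}, \eqn{o+u}, \eqn{o+v} and \eqn{o+u+v}.
#'
#' @slot sectionNr Non-negative integer section number.
#' @slot width,height Integer pixel dimensions (>= 2) of the
#'   registration-resolution image.
#' @slot o,u,v Numeric length-3 vectors in atlas voxel units.
#'
#' @seealso [pixelToAtlas()], [sliceAtlas()], [propagateSeries()]
#' @export
setClass("SectionAnchoring",
  representation(
    sectionNr = "integer",
    width = "integer",
    height = "integer",
    o = "numeric",
    u = "numeric",
    v = "numeric"
  )
)

setValidity("SectionAnchoring", function(object) {
  msg <- character()
  if (length(object@sectionNr) != 1L || is.na(object@sectionNr) ||
      object@sectionNr < 0L)
    msg <- c(msg, "sectionNr must be a single non-negative integer")
  if (length(object@width) != 1L || length(object@height) != 1L ||
      is.na(object@width) || is.na(object@height) ||
      object@width < 2L || object@height < 2L)
    msg <- c(msg, "width and height must be >= 2")
  for (s in c("o", "u", "v")) {
    v <- slot(object, s)
    if (length(v) != 3L || any(!is.finite(v)))
      msg <- c(msg, paste0(s, " must be a finite 3-vector"))
  }
  if (length(msg) == 0L) {
    cr <- crossProduct(object@u, object@v)
    if (sqrt(sum(cr^2)) <= 0)
      msg <- c(msg, "u and v must be linearly independent (|u x v| > 0)")
  }
  if (length(msg)) msg else TRUE
})

crossProduct <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Serial section series descriptor
#'
#' A \code{SectionSeries} describes an ordered serial series of section
#' images: for each section a filename (carrying the section number as the
#' final \code{_sXXX} token), pixel dimensions, an optional
#' [SectionAnchoring-class] and optional nonlinear warp markers (an n x 4
#' matrix of \code{targetX, targetY, sourceX, sourceY} pixel quadruples).
#'
#' @slot atlasName Character, name of the atlas the series is registered to.
#' @slot sections List of per-section records, each a list with elements
#'   \code{filename}, \code{nr}, \code{width}, \code{height},
#'   \code{anchoring} (\code{SectionAnchoring} or \code{NULL}) and
#'   \code{markers} (numeric matrix or \code{NULL}).
#'
#' @seealso [readSeriesDescriptor()], [propagateSeries()]
#' @export
setClass("SectionSeries",
  representation(atlasName = "character", sections = "list")
)

setValidity("SectionSeries", function(object) {
  msg <- character()
  nrs <- vapply(object@sections, function(s) as.integer(s$nr), integer(1))
  if (anyDuplicated(nrs))
    msg <- c(msg, "section numbers must be unique")
  if (is.unsorted(nrs, strictly = TRUE) && length(nrs) > 1L)
    msg <- c(msg, "sections must be sorted by ascending section number")
  for (s in object@sections) {
    if (!is.null(s$filename) && nzchar(s$filename)) {
      nr <- tryCatch(parseSectionNumber(s$filename), error = function(e) NA_integer_)
      if (is.na(nr) || nr != s$nr)
        msg <- c(msg, paste0("filename '", s$filename,
                             "' does not carry section number ", s$nr))
    }
    if (!is.null(s$markers) &&
        (!is.matrix(s$markers) || ncol(s$markers) != 4L))
      msg <- c(msg, "markers must be an n x 4 matrix")
  }
  if (length(msg)) msg else TRUE
})

#' Piecewise-linear in-plane warp field
#'
#' A \code{WarpField} represents the nonlinear refinement of a linear section
#' registration: displacement markers (each a target position, i.e. where an
#' anchor point was dragged to, and a source position where it started), plus
#' a Delaunay triangulation of the target points. Four fixed corner markers
#' are auto-inserted so the triangulation always covers the full image.
#' A target pixel is looked up by computing its barycentric coordinates in
#' its containing target triangle and evaluating the same coordinates over
#' the corresponding source triangle.
#'
#' @slot markers Numeric n x 4 matrix with columns
#'   \code{targetX, targetY, sourceX, sourceY} (pixel units).
#' @slot triangles Integer t x 3 matrix of row indices into \code{markers}.
#' @slot width,height Integer image dimensions the field covers.
#'
#' @seealso [buildWarp()], [warpLookup()], [warpedLabelMap()]
#' @export
setClass("WarpField",
  representation(
    markers = "matrix",
    triangles = "matrix",
    width = "integer",
    height = "integer"
  )
)

setValidity("WarpField", function(object) {
  msg <- character()
  if (!is.numeric(object@markers) || ncol(object@markers) != 4L)
    msg <- c(msg, "markers must be an n x 4 numeric matrix")
  if (!is.integer(object@triangles) || ncol(object@triangles) != 3L)
    msg <- c(msg, "triangles must be a t x 3 integer matrix")
  if (length(msg) == 0L) {
    if (anyDuplicated(object@markers[, 1:2, drop = FALSE]))
      msg <- c(msg, "target points must be pairwise distinct")
    tx <- object@markers[, 1]; ty <- object@markers[, 2]
    for (i in seq_len(nrow(object@triangles))) {
      tr <- object@triangles[i, ]
      a2 <- (tx[tr[2]] - tx[tr[1]]) * (ty[tr[3]] - ty[tr[1]]) -
            (tx[tr[3]] - tx[tr[1]]) * (ty[tr[2]] - ty[tr[1]])
      if (abs(a2) <= 0) {
        msg <- c(msg, "triangulation contains a zero-area triangle")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-section hemisphere mask
#'
#' A \code{HemiMask} assigns every pixel of a section image to the left or
#' right hemisphere, derived from the atlas midsagittal plane: a pixel's 3D
#' atlas coordinate (after the nonlinear warp, when one is supplied) is
#' compared with the midline plane along the midline axis. Coordinates
#' exactly on the plane count as right.
#'
#' @slot left Logical height x width matrix; \code{TRUE} = left hemisphere.
#'
#' @seealso [hemisphereMask()], [leftMask()], [rightMask()]
#' @export
setClass("HemiMask", representation(left = "matrix"))

setValidity("HemiMask", function(object) {
  if (!is.logical(object@left) || anyNA(object@left))
    "left must be a logical matrix with no NA" else TRUE
})

#' 3D atlas-space point cloud
#'
#' A \code{PointCloud} is a named, colored set of 3D atlas-space points
#' extracted from section-plane markers, each carrying its source section and
#' pixel, the atlas region id at its coordinate (0 outside the volume, with
#' an \code{outside} flag) and the region name.
#'
#' @slot name Character, non-empty cloud name.
#' @slot color Integer length-3 RGB byte triple.
#' @slot points \code{data.frame} with columns \code{section_nr},
#'   \code{pixel_x}, \code{pixel_y}, \code{atlas_x}, \code{atlas_y},
#'   \code{atlas_z}, \code{region_id}, \code{region_name}, \code{outside}.
#'
#' @seealso [extractPoints()], [exportPointCloud()]
#' @export
setClass("PointCloud",
  representation(name = "character", color = "integer", points = "data.frame")
)

setValidity("PointCloud", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(object@color) != 3L || any(is.na(object@color)) ||
      any(object@color < 0L) || any(object@color > 255L))
    msg <- c(msg, "color must be an RGB byte triple")
  need <- c("section_nr", "pixel_x", "pixel_y", "atlas_x", "atlas_y",
            "atlas_z", "region_id", "region_name", "outside")
  if (!all(need %in% names(object@points)))
    msg <- c(msg, paste0("points must have columns: ",
                         paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Per-section regional quantification report
#'
#' A \code{QuantReport} holds per-region tallies of a binary segmentation
#' quantified against a section's atlas label map: region pixel count, object
#' (foreground) pixel count, object count, and the load fraction
#' \eqn{\mathrm{object\_pixels} / \mathrm{region\_pixels}} (0 when the region
#' has no pixels). Region 0 collects background pixels so totals conserve.
#'
#' @slot sectionNr Integer section number.
#' @slot mask Character, one of \code{"none"}, \code{"left"}, \code{"right"}.
#' @slot mode Character object-counting mode, \code{"split"} or
#'   \code{"centroid"}.
#' @slot mappingKey Character fingerprint of the region mapping used, so that
#'   reports quantified under different mappings cannot be aggregated.
#' @slot stats \code{data.frame} with columns \code{region_id},
#'   \code{region_name}, \code{region_pixels}, \code{object_pixels},
#'   \code{object_count}, \code{load}.
#'
#' @seealso [quantifySection()], [aggregateReports()]
#' @export
setClass("QuantReport",
  representation(
    sectionNr = "integer",
    mask = "character",
    mode = "character",
    mappingKey = "character",
    stats = "data.frame"
  )
)

setValidity("QuantReport", function(object) {
  msg <- character()
  if (!object@mask %in% c("none", "left", "right", "custom"))
    msg <- c(msg, "mask must be one of none/left/right/custom")
  s <- object@stats
  need <- c("region_id", "region_name", "region_pixels", "object_pixels",
            "object_count", "load")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste0("stats must have columns: ", paste(need, collapse = ", ")))
  else {
    if (any(s$region_pixels < 0) || any(s$object_pixels < 0) ||
        any(s$object_count < 0))
      msg <- c(msg, "counts must be non-negative")
    if (any(s$load < 0 | is.na(s$load)))
      msg <- c(msg, "load must be defined and >= 0")
    if (object@mode == "split" &&
        any(s$object_pixels > s$region_pixels))
      msg <- c(msg, "object_pixels cannot exceed region_pixels in split mode")
  }
  if (length(msg)) msg else TRUE
})
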