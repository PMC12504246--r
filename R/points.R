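#' @include AllClasses.R anchoring.R warp.R
NULL

#' Extract section-plane markers into 3D atlas space
#'
#' Converts user-placed markers on a registered section into atlas-space
#' points: each pixel is pushed through the nonlinear warp (when markers are
#' given), then through the section's affine anchoring, and annotated with
#' the atlas region at the nearest voxel. Points falling outside the volume
#' get region 0 and \code{outside = TRUE}. Marker pixels are interpreted in
#' the registration-resolution image; scale full-resolution pixel
#' coordinates down first.
#'
#' @param atlas An [AtlasVolume-class].
#' @param a A [SectionAnchoring-class].
#' @param x,y Numeric pixel coordinates of the markers (0-based).
#' @param markers Optional warp marker matrix as in [buildWarp()].
#' @return A \code{data.frame} with columns \code{section_nr, pixel_x,
#'   pixel_y, atlas_x, atlas_y, atlas_z, region_id, region_name, outside}.
#' @export
extractPoints <- function(atlas, a, x, y, markers = NULL) {
  validObject(a)
  stopifnot(length(x) == length(y))
  qx <- as.numeric(x); qy <- as.numeric(y)
  if (!is.null(markers) && nrow(as.matrix(markers)) > 0L) {
    w <- buildWarp(markers, a@width, a@height)
    src <- warpLookup(w, qx, qy)
    qx <- src[, 1]; qy <- src[, 2]
  }
  coords <- pixelToAtlas(a, qx, qy)
  ids <- lookupLabels(atlas, coords)
  d <- dim(atlas@labels)
  idx <- roundHalfAway(coords)
  outside <- !(idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
               idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
               idx[, 3] >= 0 & idx[, 3] <= d[3] - 1)
  data.frame(
    section_nr = rep(a@sectionNr, length(x)),
    pixel_x = as.numeric(x), pixel_y = as.numeric(y),
    atlas_x = coords[, 1], atlas_y = coords[, 2], atlas_z = coords[, 3],
    region_id = ids,
    region_name = regionName(atlas@hierarchy, ids),
    outside = outside,
    stringsAsFactors = FALSE)
}

#' Construct a point cloud
#'
#' @param points A points \code{data.frame} from [extractPoints()] (or rows
#'   bound over several sections).
#' @param name Non-empty cloud name.
#' @param color RGB byte triple.
#' @return A [PointCloud-class].
#' @export
pointCloud <- function(points, name = "cloud", color = c(255L, 0L, 0L)) {
  new("PointCloud", name = name, color = as.integer(color), points = points)
}

emptyPointsFrame <- function() {
  data.frame(section_nr = integer(), pixel_x = numeric(), pixel_y = numeric(),
             atlas_x = numeric(), atlas_y = numeric(), atlas_z = numeric(),
             region_id = integer(), region_name = character(),
             outside = logical(), stringsAsFactors = FALSE)
}

#' Export and import point clouds
#'
#' Two formats are supported. \code{"meshview_json"} is a compact viewer
#' format: \code{{"name", "color": [r,g,b], "points": [x,y,z, x,y,z, ...]}}
#' with a flat triplet list of atlas-voxel coordinates. \code{"csv"} is an
#' RFC-4180 table with header \code{section_nr,pixel_x,pixel_y,atlas_x,
#' atlas_y,atlas_z,region_id,region_name} and one row per point. Both
#' round-trip value-identically through the matching reader (the CSV reader
#' returns the tabulated columns; the JSON reader returns name, color and
#' coordinates).
#'
#' @param cloud A [PointCloud-class].
#' @param path Output file path.
#' @param format \code{"meshview_json"} or \code{"csv"}.
#' @return \code{exportPointCloud} returns \code{path} invisibly.
#'   \code{readPointCloudJSON} returns a [PointCloud-class] whose pixel and
#'   region columns are \code{NA} (the format stores coordinates only);
#'   \code{readPointCloudCSV} returns a \code{data.frame}.
#' @export
exportPointCloud <- function(cloud, path,
                             format = c("meshview_json", "csv")) {
  format <- match.arg(format)
  p <- cloud@points
  if (format == "meshview_json") {
    flat <- as.vector(t(as.matrix(p[, c("atlas_x", "atlas_y", "atlas_z")])))
    doc <- list(name = cloud@name, color = cloud@color, points = flat)
    jsonlite::write_json(doc, path, digits = NA,
                         auto_unbox = TRUE)
  } else {
    utils::write.csv(p[, c("section_nr", "pixel_x", "pixel_y", "atlas_x",
                           "atlas_y", "atlas_z", "region_id", "region_name")],
                     path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' @rdname exportPointCloud
#' @export
readPointCloudJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  flat <- as.numeric(doc$points)
  if (length(flat) %% 3L != 0L)
    stop("point list length is not a multiple of 3", call. = FALSE)
  n <- length(flat) / 3L
  m <- matrix(flat, ncol = 3, byrow = TRUE)
  pts <- data.frame(section_nr = rep(NA_integer_, n),
                    pixel_x = NA_real_, pixel_y = NA_real_,
                    atlas_x = m[, 1], atlas_y = m[, 2], atlas_z = m[, 3],
                    region_id = NA_integer_, region_name = NA_character_,
                    outside = NA, stringsAsFactors = FALSE)
  if (n == 0L) pts <- emptyPointsFrame()
  new("PointCloud", name = as.character(doc$name),
      color = as.integer(doc$color), points = pts)
}

#' @rdname exportPointCloud
#' @export
readPointCloudCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Keep points between two parallel planes
#'
#' Pure-geometry convenience filter: retains the points whose signed distance
#' along a plane normal lies within a closed interval, e.g. to inspect a slab
#' of a point cloud.
#'
#' @param cloud A [PointCloud-class].
#' @param normal Numeric 3-vector (need not be unit length).
#' @param dMin,dMax Bounds on the dot product of the atlas coordinate with
#'   \code{normal}.
#' @return The filtered [PointCloud-class].
#' @export
filterSlab <- function(cloud, normal, dMin, dMax) {
  p <- cloud@points
  d <- as.matrix(p[, c("atlas_x", "atlas_y", "atlas_z")]) %*% as.numeric(normal)
  initialize(cloud, points = p[d >= dMin & d <= dMax, , drop = FALSE])
}
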