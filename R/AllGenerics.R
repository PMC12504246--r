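#' @include AllClasses.R
NULL

#' Accessors for atlas and section objects
#'
#' Small accessor generics: use these instead of reaching into slots.
#'
#' @param x An object of the documented class.
#' @return \code{regionHierarchy} returns the hierarchy \code{data.frame};
#'   \code{atlasDims} the integer voxel dimensions; \code{voxelSize} the voxel
#'   size in micrometers; \code{midline} a list with elements \code{axis}
#'   (1-based, or \code{NA}) and \code{coord}; \code{nSections} and
#'   \code{sectionNumbers} the section count and numbers of a series;
#'   \code{leftMask}/\code{rightMask} logical matrices; \code{quantStats}
#'   the per-region statistics \code{data.frame} of a report.
#'
#' @name accessors
#' @aliases regionHierarchy atlasDims voxelSize midline nSections
#'   sectionNumbers leftMask rightMask quantStats
NULL

#' @rdname accessors
#' @export
setGeneric("regionHierarchy", function(x) standardGeneric("regionHierarchy"))
#' @rdname accessors
#' @export
setGeneric("atlasDims", function(x) standardGeneric("atlasDims"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("midline", function(x) standardGeneric("midline"))
#' @rdname accessors
#' @export
setGeneric("nSections", function(x) standardGeneric("nSections"))
#' @rdname accessors
#' @export
setGeneric("sectionNumbers", function(x) standardGeneric("sectionNumbers"))
#' @rdname accessors
#' @export
setGeneric("leftMask", function(x) standardGeneric("leftMask"))
#' @rdname accessors
#' @export
setGeneric("rightMask", function(x) standardGeneric("rightMask"))
#' @rdname accessors
#' @export
setGeneric("quantStats", function(x) standardGeneric("quantStats"))

#' @rdname accessors
setMethod("regionHierarchy", "AtlasVolume", function(x) x@hierarchy)
#' @rdname accessors
setMethod("atlasDims", "AtlasVolume", function(x) dim(x@labels))
#' @rdname accessors
setMethod("voxelSize", "AtlasVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("midline", "AtlasVolume",
  function(x) list(axis = x@midlineAxis, coord = x@midlineCoord))
#' @rdname accessors
setMethod("nSections", "SectionSeries", function(x) length(x@sections))
#' @rdname accessors
setMethod("sectionNumbers", "SectionSeries",
  function(x) vapply(x@sections, function(s) as.integer(s$nr), integer(1)))
#' @rdname accessors
setMethod("leftMask", "HemiMask", function(x) x@left)
#' @rdname accessors
setMethod("rightMask", "HemiMask", function(x) !x@left)
#' @rdname accessors
setMethod("quantStats", "QuantReport", function(x) x@stats)

setMethod("show", "AtlasVolume", function(object) {
  d <- dim(object@labels)
  ml <- if (is.na(object@midlineAxis)) "none" else
    sprintf("axis %d @ %.2f", object@midlineAxis, object@midlineCoord)
  cat("AtlasVolume '", object@name, "': ", paste(d, collapse = " x "),
      " voxels (", paste(format(object@voxelSize), collapse = " x "),
      " um)\n", sep = "")
  cat("  ", nrow(object@hierarchy), " hierarchy nodes, ",
      length(setdiff(unique(as.vector(object@labels)), 0L)),
      " labels in use, midline: ", ml, "\n", sep = "")
})

setMethod("show", "SectionAnchoring", function(object) {
  cat(sprintf("SectionAnchoring nr=%d (%d x %d px)\n",
              object@sectionNr, object@width, object@height))
  cat(sprintf("  o = (%s)\n  u = (%s)\n  v = (%s)\n",
              paste(format(object@o, digits = 6), collapse = ", "),
              paste(format(object@u, digits = 6), collapse = ", "),
              paste(format(object@v, digits = 6), collapse = ", ")))
})

setMethod("show", "SectionSeries", function(object) {
  n <- length(object@sections)
  anch <- sum(vapply(object@sections, function(s) !is.null(s$anchoring), logical(1)))
  mark <- sum(vapply(object@sections, function(s) !is.null(s$markers), logical(1)))
  cat("SectionSeries on atlas '", object@atlasName, "': ", n, " sections (",
      anch, " anchored, ", mark, " with markers)\n", sep = "")
})

setMethod("show", "WarpField", function(object) {
  cat(sprintf("WarpField: %d markers, %d triangles over %d x %d px\n",
              nrow(object@markers), nrow(object@triangles),
              object@width, object@height))
})

setMethod("show", "HemiMask", function(object) {
  cat(sprintf("HemiMask %d x %d px: %d left, %d right\n",
              nrow(object@left), ncol(object@left),
              sum(object@left), sum(!object@left)))
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud '%s' (rgb %s): %d points\n", object@name,
              paste(object@color, collapse = ","), nrow(object@points)))
})

setMethod("show", "QuantReport", function(object) {
  cat(sprintf("QuantReport section %d (mask=%s, mode=%s): %d regions\n",
              object@sectionNr, object@mask, object@mode,
              sum(object@stats$region_id != 0L)))
})
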