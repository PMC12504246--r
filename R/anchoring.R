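#' @include AllClasses.R
NULL

#' Construct a section anchoring
#'
#' @param o,u,v Numeric 3-vectors in atlas voxel units: \code{o} is the atlas
#'   position of pixel (0,0); \code{u} spans the image's x extent; \code{v}
#'   spans its y extent.
#' @param width,height Pixel dimensions (>= 2) of the registration-resolution
#'   image.
#' @param sectionNr Non-negative section number (default 0).
#' @return A [SectionAnchoring-class].
#' @examples
#' a <- anchoring(o = c(0, 0, 0), u = c(10, 0, 0), v = c(0, 10, 0),
#'                width = 11, height = 11)
#' pixelToAtlas(a, 5, 2)
#' @export
anchoring <- function(o, u, v, width, height, sectionNr = 0L) {
  new("SectionAnchoring", sectionNr = as.integer(sectionNr),
      width = as.integer(width), height = as.integer(height),
      o = as.numeric(o), u = as.numeric(u), v = as.numeric(v))
}

#' Parse the section number from a filename
#'
#' Serial series filenames carry the section number as a \code{_sXXX} token
#' (e.g. \code{rat42_s017.png} is section 17). When several such tokens
#' occur, the last one wins.
#'
#' @param filename A filename or path.
#' @return The integer section number.
#' @examples
#' parseSectionNumber("rat42_s017.png")
#' @export
parseSectionNumber <- function(filename) {
  m <- gregexpr("_s([0-9]+)", basename(filename))[[1]]
  if (m[1] == -1L)
    stop("filename '", filename, "' does not follow the _sXXX naming ",
         "convention (an '_s' followed by the section number, e.g. ",
         "'brain_s042.png')", call. = FALSE)
  last <- length(m)
  tok <- substr(basename(filename), m[last] + 2L,
                m[last] + attr(m, "match.length")[last] - 1L)
  as.integer(tok)
}

#' Map a section pixel to its 3D atlas coordinate
#'
#' Evaluates the cut-plane equation
#' \eqn{p = o + u\,x/(W-1) + v\,y/(H-1)} for pixel coordinates \eqn{(x, y)}
#' (0-based). Coordinates outside the image extrapolate linearly.
#'
#' @param a A [SectionAnchoring-class].
#' @param x,y Numeric pixel coordinates (vectors of equal length).
#' @return An n x 3 matrix of atlas coordinates (continuous 0-based voxel
#'   units); a single coordinate is still returned as a 1 x 3 matrix.
#' @export
pixelToAtlas <- function(a, x, y) {
  stopifnot(length(x) == length(y))
  fx <- x / (a@width - 1)
  fy <- y / (a@height - 1)
  cbind(a@o[1] + a@u[1] * fx + a@v[1] * fy,
        a@o[2] + a@u[2] * fx + a@v[2] * fy,
        a@o[3] + a@u[3] * fx + a@v[3] * fy)
}

# Nearest-voxel label lookup for an n x 3 matrix of continuous atlas
# coordinates; out-of-volume coordinates yield 0.
lookupLabels <- function(atlas, coords) {
  d <- dim(atlas@labels)
  idx <- roundHalfAway(coords) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- integer(nrow(coords))
  if (any(ok))
    out[ok] <- atlas@labels[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
  out
}

#' Slice the atlas at a section anchoring
#'
#' Extracts the 2D label map of a section: every pixel of the
#' registration-resolution image is mapped to atlas space with
#' [pixelToAtlas()] and assigned the label of the nearest voxel
#' (round half away from zero). Pixels falling outside the volume get 0.
#'
#' @param atlas An [AtlasVolume-class].
#' @param a A [SectionAnchoring-class].
#' @return An integer label map, \code{height x width}; pixel \code{(x, y)}
#'   (0-based) is element \code{[y + 1, x + 1]}.
#' @examples
#' atl <- synthAtlas(seed = 1, dims = c(24, 32, 24), nNuclei = 1)
#' a <- anchoring(c(0, 16, 0), c(23, 0, 0), c(0, 0, 23), 24, 24)
#' lm <- sliceAtlas(atl, a)
#' table(lm)
#' @export
sliceAtlas <- function(atlas, a) {
  validObject(a)
  W <- a@width; H <- a@height
  fx <- (0:(W - 1)) / (W - 1)
  fy <- (0:(H - 1)) / (H - 1)
  ones_w <- rep(1, W); ones_h <- rep(1, H)
  lab <- integer(H * W)
  d <- dim(atlas@labels)
  # per-axis coordinate matrices, H x W
  i1 <- roundHalfAway(a@o[1] + tcrossprod(ones_h, a@u[1] * fx) +
                        tcrossprod(a@v[1] * fy, ones_w)) + 1
  i2 <- roundHalfAway(a@o[2] + tcrossprod(ones_h, a@u[2] * fx) +
                        tcrossprod(a@v[2] * fy, ones_w)) + 1
  i3 <- roundHalfAway(a@o[3] + tcrossprod(ones_h, a@u[3] * fx) +
                        tcrossprod(a@v[3] * fy, ones_w)) + 1
  ok <- i1 >= 1 & i1 <= d[1] & i2 >= 1 & i2 <= d[2] & i3 >= 1 & i3 <= d[3]
  lab[ok] <- atlas@labels[cbind(i1[ok], i2[ok], i3[ok])]
  matrix(lab, nrow = H, ncol = W)
}

#' Propagate anchorings across a serial series
#'
#' Registration of a serial series typically anchors only sections with clear
#' landmarks; the remaining anchorings are inferred from the section numbers.
#' Sections between two anchored sections get componentwise linear
#' interpolation of \code{(o, u, v)} in the section number; sections outside
#' the anchored range are linearly extrapolated from the two nearest anchored
#' sections (or replicated when only one section is anchored). Anchored
#' sections are never modified.
#'
#' @param series A [SectionSeries-class] with at least one anchored section.
#' @param clamp If \code{TRUE}, sections outside the anchored range replicate
#'   the nearest anchored section instead of extrapolating.
#' @return The series with every section anchored.
#' @export
propagateSeries <- function(series, clamp = FALSE) {
  secs <- series@sections
  if (length(secs) == 0L) stop("empty series", call. = FALSE)
  anchored <- which(vapply(secs, function(s) !is.null(s$anchoring), logical(1)))
  if (length(anchored) == 0L)
    stop("no anchored section to propagate from", call. = FALSE)
  aNr <- vapply(secs[anchored], function(s) as.integer(s$nr), integer(1))
  aVec <- t(vapply(secs[anchored],
                   function(s) c(s$anchoring@o, s$anchoring@u, s$anchoring@v),
                   numeric(9)))
  ord <- order(aNr)
  aNr <- aNr[ord]; aVec <- aVec[ord, , drop = FALSE]

  interpAt <- function(n) {
    if (length(aNr) == 1L) return(aVec[1, ])
    below <- which(aNr < n); above <- which(aNr > n)
    if (length(below) && length(above)) {
      i1 <- max(below); i2 <- min(above)
    } else if (length(above)) {          # before the range: two smallest
      i1 <- 1L; i2 <- 2L
      if (clamp) return(aVec[1, ])
    } else {                             # after the range: two largest
      i1 <- length(aNr) - 1L; i2 <- length(aNr)
      if (clamp) return(aVec[length(aNr), ])
    }
    n1 <- aNr[i1]; n2 <- aNr[i2]
    aVec[i1, ] + (aVec[i2, ] - aVec[i1, ]) * (n - n1) / (n2 - n1)
  }

  for (i in seq_along(secs)) {
    if (!is.null(secs[[i]]$anchoring)) next
    vec <- interpAt(as.integer(secs[[i]]$nr))
    secs[[i]]$anchoring <- anchoring(vec[1:3], vec[4:6], vec[7:9],
                                     width = secs[[i]]$width,
                                     height = secs[[i]]$height,
                                     sectionNr = secs[[i]]$nr)
  }
  initialize(series, sections = secs)
}

#' Estimate an anchoring from pixel-to-atlas correspondences
#'
#' Solves the cut-plane model \eqn{p = o + u\,x/(W-1) + v\,y/(H-1)} in the
#' least-squares sense from point correspondences, enabling programmatic
#' registration and parameter-recovery checks. Three exact non-collinear
#' correspondences determine the anchoring with zero residual.
#'
#' @param pixels n x 2 matrix of pixel coordinates (0-based).
#' @param coords n x 3 matrix of the matching atlas coordinates.
#' @param width,height Registration image dimensions.
#' @param sectionNr Section number for the returned anchoring.
#' @return A [SectionAnchoring-class].
#' @export
estimateAnchoring <- function(pixels, coords, width, height, sectionNr = 0L) {
  pixels <- as.matrix(pixels); coords <- as.matrix(coords)
  if (nrow(pixels) < 3L)
    stop("need at least 3 correspondences, got ", nrow(pixels), call. = FALSE)
  if (nrow(pixels) != nrow(coords))
    stop("pixels and coords must have the same number of rows", call. = FALSE)
  X <- cbind(1, pixels[, 1] / (width - 1), pixels[, 2] / (height - 1))
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("rank-deficient correspondences: pixel points are collinear",
         call. = FALSE)
  beta <- qr.coef(qrX, coords)   # 3 x 3: rows (o, u, v), columns axes
  anchoring(o = beta[1, ], u = beta[2, ], v = beta[3, ],
            width = width, height = height, sectionNr = sectionNr)
}

# ---- series descriptor JSON ------------------------------------------------

#' Read and write series registration descriptors
#'
#' The descriptor is a JSON document
#' \code{{"atlas": str, "sections": [{"filename", "nr", "width", "height",
#' "anchoring": [ox,oy,oz,ux,uy,uz,vx,vy,vz], "markers":
#' [[tx,ty,sx,sy], ...]}, ...]}}; \code{anchoring} and \code{markers} are
#' optional per section. Writing then reading is value-identical.
#'
#' @param path File path.
#' @param series A [SectionSeries-class].
#' @return \code{readSeriesDescriptor} returns a [SectionSeries-class];
#'   \code{writeSeriesDescriptor} returns \code{path} invisibly.
#' @export
readSeriesDescriptor <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$sections))
    stop("descriptor has no 'sections' list: ", path, call. = FALSE)
  secs <- lapply(doc$sections, function(s) {
    anc <- NULL
    if (!is.null(s$anchoring)) {
      v <- as.numeric(unlist(s$anchoring))
      if (length(v) != 9L)
        stop("anchoring of section ", s$nr, " must have 9 numbers",
             call. = FALSE)
      anc <- anchoring(v[1:3], v[4:6], v[7:9],
                       width = s$width, height = s$height, sectionNr = s$nr)
    }
    mk <- NULL
    if (!is.null(s$markers) && length(s$markers)) {
      mk <- do.call(rbind, lapply(s$markers, function(q) as.numeric(unlist(q))))
      if (ncol(mk) != 4L)
        stop("markers of section ", s$nr, " must be 4-number quadruples",
             call. = FALSE)
      colnames(mk) <- c("targetX", "targetY", "sourceX", "sourceY")
    }
    list(filename = as.character(s$filename), nr = as.integer(s$nr),
         width = as.integer(s$width), height = as.integer(s$height),
         anchoring = anc, markers = mk)
  })
  new("SectionSeries",
      atlasName = if (is.null(doc$atlas)) "" else as.character(doc$atlas),
      sections = secs)
}

#' @rdname readSeriesDescriptor
#' @export
writeSeriesDescriptor <- function(series, path) {
  secs <- lapply(series@sections, function(s) {
    rec <- list(filename = s$filename, nr = s$nr,
                width = s$width, height = s$height)
    if (!is.null(s$anchoring))
      rec$anchoring <- c(s$anchoring@o, s$anchoring@u, s$anchoring@v)
    if (!is.null(s$markers))
      rec$markers <- lapply(seq_len(nrow(s$markers)),
                            function(i) unname(s$markers[i, ]))
    rec
  })
  doc <- list(atlas = series@atlasName, sections = secs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Assemble a section series in code
#'
#' @param sections List of per-section lists with elements \code{filename},
#'   \code{nr} (optional; parsed from the filename when absent),
#'   \code{width}, \code{height}, and optional \code{anchoring} and
#'   \code{markers}.
#' @param atlasName Atlas name recorded in the descriptor.
#' @return A [SectionSeries-class] sorted by section number.
#' @export
sectionSeries <- function(sections, atlasName = "atlas") {
  sections <- lapply(sections, function(s) {
    if (is.null(s$nr)) s$nr <- parseSectionNumber(s$filename)
    s$nr <- as.integer(s$nr)
    s$width <- as.integer(s$width); s$height <- as.integer(s$height)
    if (is.null(s$anchoring)) s["anchoring"] <- list(NULL)
    if (is.null(s$markers)) s["markers"] <- list(NULL)
    s
  })
  ord <- order(vapply(sections, `[[`, integer(1), "nr"))
  new("SectionSeries", atlasName = atlasName, sections = sections[ord])
}

# ---- label map export ------------------------------------------------------

#' Export a label map as image files
#'
#' \code{writeLabelMapImage} writes the raw region ids as 16-bit grayscale
#' TIFF (lossless for ids up to 65535). \code{writeLabelMapOverlay} writes an
#' RGB PNG using the hierarchy's region colors (background black).
#'
#' @param lm Integer label map (height x width).
#' @param path Output file path.
#' @param hierarchy Hierarchy \code{data.frame} or [AtlasVolume-class]
#'   supplying region colors.
#' @return \code{path}, invisibly.
#' @export
writeLabelMapImage <- function(lm, path) {
  if (max(lm) > 65535L)
    stop("label ids exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(lm / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelMapImage
#' @export
readLabelMapImage <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(roundHalfAway(m * 65535)), nrow = nrow(m))
}

#' @rdname writeLabelMapImage
#' @export
writeLabelMapOverlay <- function(lm, hierarchy, path) {
  if (is(hierarchy, "AtlasVolume")) hierarchy <- hierarchy@hierarchy
  idx <- match(lm, hierarchy$id)
  rgb <- array(0, dim = c(nrow(lm), ncol(lm), 3))
  rgb[, , 1] <- ifelse(is.na(idx), 0, hierarchy$r[idx]) / 255
  rgb[, , 2] <- ifelse(is.na(idx), 0, hierarchy$g[idx]) / 255
  rgb[, , 3] <- ifelse(is.na(idx), 0, hierarchy$b[idx]) / 255
  png::writePNG(rgb, path)
  invisible(path)
}
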