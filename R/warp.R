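#' @include AllClasses.R
NULL

# ---- Delaunay triangulation (incremental Bowyer-Watson) --------------------
#
# Marker sets are tiny (corners + a handful of user anchor points), so an
# incremental insertion with a super-triangle is ample. The in-circumcircle
# predicate is evaluated on coordinates translated to the query point and
# scaled to O(1), with a strict tolerance so cocircular configurations (the
# four image corners are one) fall back to the current diagonal instead of
# producing overlapping triangles.

orient2d <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

inCircumcircle <- function(ax, ay, bx, by, cx, cy, dx, dy, scale) {
  a1 <- (ax - dx) / scale; a2 <- (ay - dy) / scale
  b1 <- (bx - dx) / scale; b2 <- (by - dy) / scale
  c1 <- (cx - dx) / scale; c2 <- (cy - dy) / scale
  a3 <- a1 * a1 + a2 * a2
  b3 <- b1 * b1 + b2 * b2
  c3 <- c1 * c1 + c2 * c2
  det <- a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
    a3 * (b1 * c2 - b2 * c1)
  if (orient2d(ax, ay, bx, by, cx, cy) < 0) det <- -det
  det > 1e-12
}

delaunayTriangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to triangulate", call. = FALSE)
  if (anyDuplicated(pts))
    stop("duplicate target points", call. = FALSE)
  # collinearity check over all points
  collinear <- TRUE
  for (k in 3:n) {
    if (abs(orient2d(pts[1, 1], pts[1, 2], pts[2, 1], pts[2, 2],
                     pts[k, 1], pts[k, 2])) > 1e-9) { collinear <- FALSE; break }
  }
  if (collinear) stop("all points are collinear", call. = FALSE)

  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  big <- 50 * span
  P <- rbind(pts,
             c(cx - big, cy - 0.6 * big),
             c(cx + big, cy - 0.6 * big),
             c(cx, cy + big))
  sv <- n + 1:3
  scale <- 2 * big
  tris <- list(sv)  # each an int triple into P

  for (i in seq_len(n)) {
    px <- P[i, 1]; py <- P[i, 2]
    bad <- logical(length(tris))
    for (t in seq_along(tris)) {
      tr <- tris[[t]]
      bad[t] <- inCircumcircle(P[tr[1], 1], P[tr[1], 2],
                               P[tr[2], 1], P[tr[2], 2],
                               P[tr[3], 1], P[tr[3], 2], px, py, scale)
    }
    if (!any(bad))
      stop("triangulation insertion failed for point ", i,
           " (degenerate configuration)", call. = FALSE)
    # cavity boundary: edges of bad triangles seen exactly once
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- key %in% names(which(table(key) == 1L))
    boundary <- edges[once, , drop = FALSE]
    tris <- tris[!bad]
    for (e in seq_len(nrow(boundary))) {
      tr <- c(boundary[e, 1], boundary[e, 2], i)
      if (orient2d(P[tr[1], 1], P[tr[1], 2], P[tr[2], 1], P[tr[2], 2],
                   P[tr[3], 1], P[tr[3], 2]) < 0)
        tr <- tr[c(1, 3, 2)]
      tris[[length(tris) + 1L]] <- tr
    }
  }
  keep <- vapply(tris, function(tr) all(tr <= n), logical(1))
  tri <- do.call(rbind, tris[keep])
  storage.mode(tri) <- "integer"
  # deterministic ordering: rotate each triple so the smallest vertex leads
  tri <- t(apply(tri, 1, function(tr) {
    k <- which.min(tr)
    tr[c(k:3, seq_len(k - 1))]
  }))
  tri <- tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
  storage.mode(tri) <- "integer"
  tri
}

# ---- warp field ------------------------------------------------------------

#' Build a piecewise-linear warp field from displacement markers
#'
#' Constructs the nonlinear in-plane refinement used to correct residual
#' anatomical mismatch after linear registration: a Delaunay triangulation is
#' computed over the marker target points (the positions anchor points were
#' dragged to). Four fixed corner markers (source = target) are auto-inserted
#' unless a user marker already occupies that corner target, so the
#' triangulation always covers the whole image. Markers whose source triangle
#' is orientation-inverted (a fold) are permitted — lookup stays well defined
#' because the triangulation lives in target space — but trigger a warning.
#'
#' @param markers Numeric n x 4 matrix (\code{targetX, targetY, sourceX,
#'   sourceY}, pixel units of the registration-resolution image), or
#'   \code{NULL} for the identity warp.
#' @param width,height Image dimensions in pixels.
#' @return A [WarpField-class].
#' @examples
#' w <- buildWarp(NULL, 11, 11)          # identity: 4 corners, 2 triangles
#' warpLookup(w, 5, 5)
#' @export
buildWarp <- function(markers, width, height) {
  width <- stopifnotScalarCount(width, "width", 2)
  height <- stopifnotScalarCount(height, "height", 2)
  if (is.null(markers)) markers <- matrix(numeric(0), 0, 4)
  markers <- as.matrix(markers)
  if (nrow(markers) && ncol(markers) != 4L)
    stop("markers must be an n x 4 matrix of ",
         "(targetX, targetY, sourceX, sourceY)", call. = FALSE)
  if (nrow(markers) && any(!is.finite(markers)))
    stop("marker coordinates must be finite", call. = FALSE)
  corners <- cbind(c(0, width - 1, 0, width - 1),
                   c(0, 0, height - 1, height - 1))
  cornerMk <- cbind(corners, corners)
  if (nrow(markers)) {
    occupied <- apply(cornerMk, 1, function(cm)
      any(markers[, 1] == cm[1] & markers[, 2] == cm[2]))
    cornerMk <- cornerMk[!occupied, , drop = FALSE]
  }
  all <- rbind(cornerMk, markers)
  colnames(all) <- c("targetX", "targetY", "sourceX", "sourceY")
  if (anyDuplicated(all[, 1:2, drop = FALSE]))
    stop("duplicate target points among markers", call. = FALSE)
  tri <- delaunayTriangulate(all[, 1:2, drop = FALSE])
  w <- new("WarpField", markers = all, triangles = tri,
           width = width, height = height)
  # fold detection: compare orientation of each target/source triangle pair
  folded <- FALSE
  for (i in seq_len(nrow(tri))) {
    tr <- tri[i, ]
    ot <- orient2d(all[tr[1], 1], all[tr[1], 2], all[tr[2], 1], all[tr[2], 2],
                   all[tr[3], 1], all[tr[3], 2])
    os <- orient2d(all[tr[1], 3], all[tr[1], 4], all[tr[2], 3], all[tr[2], 4],
                   all[tr[3], 3], all[tr[3], 4])
    if (ot * os < 0) { folded <- TRUE; break }
  }
  if (folded)
    warning("warp field is folded: at least one triangle's source image ",
            "has negative orientation", call. = FALSE)
  w
}

# Barycentric coordinates of queries (x, y) in triangle `tr` of field `w`.
baryCoords <- function(w, tr, x, y) {
  m <- w@markers
  ax <- m[tr[1], 1]; ay <- m[tr[1], 2]
  bx <- m[tr[2], 1]; by <- m[tr[2], 2]
  cx <- m[tr[3], 1]; cy <- m[tr[3], 2]
  d <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  b1 <- ((by - cy) * (x - cx) + (cx - bx) * (y - cy)) / d
  b2 <- ((cy - ay) * (x - cx) + (ax - cx) * (y - cy)) / d
  cbind(b1, b2, 1 - b1 - b2)
}

#' Look up the source position of target pixels
#'
#' For each target pixel, finds its containing triangle in the warp field's
#' target-space triangulation (ties on shared edges resolved to the lowest
#' triangle index; by barycentric continuity the result is the same), then
#' evaluates the same barycentric coordinates over the triangle's source
#' vertices. With identity markers this is the identity map.
#'
#' @param w A [WarpField-class].
#' @param x,y Numeric vectors of target pixel coordinates (0-based). Points
#'   outside the triangulation's convex hull (possible only for out-of-image
#'   queries) raise an error.
#' @return An n x 2 matrix of source pixel coordinates.
#' @export
warpLookup <- function(w, x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  triIdx <- rep(NA_integer_, n)
  B <- matrix(NA_real_, n, 3)
  eps <- 1e-9
  for (t in seq_len(nrow(w@triangles))) {
    todo <- which(is.na(triIdx))
    if (!length(todo)) break
    b <- baryCoords(w, w@triangles[t, ], x[todo], y[todo])
    inside <- b[, 1] >= -eps & b[, 2] >= -eps & b[, 3] >= -eps
    if (any(inside)) {
      triIdx[todo[inside]] <- t
      B[todo[inside], ] <- b[inside, , drop = FALSE]
    }
  }
  if (anyNA(triIdx))
    stop(sum(is.na(triIdx)), " query point(s) outside the triangulation hull",
         call. = FALSE)
  sx <- numeric(n); sy <- numeric(n)
  for (t in unique(triIdx)) {
    sel <- triIdx == t
    tr <- w@triangles[t, ]
    sx[sel] <- B[sel, , drop = FALSE] %*% w@markers[tr, 3]
    sy[sel] <- B[sel, , drop = FALSE] %*% w@markers[tr, 4]
  }
  cbind(sx, sy)
}

#' Extract a nonlinearly refined label map
#'
#' Samples the linear atlas slice through the warp field: each output pixel's
#' source position is found with [warpLookup()], mapped to atlas space with
#' the section's affine anchoring, and assigned the nearest voxel's label.
#' With no markers this reproduces [sliceAtlas()] exactly.
#'
#' @param atlas An [AtlasVolume-class].
#' @param a A [SectionAnchoring-class].
#' @param markers Marker matrix as in [buildWarp()], or \code{NULL}.
#' @return An integer label map, \code{height x width}.
#' @export
warpedLabelMap <- function(atlas, a, markers) {
  validObject(a)
  if (is.null(markers) || nrow(as.matrix(markers)) == 0L)
    return(sliceAtlas(atlas, a))
  w <- buildWarp(markers, a@width, a@height)
  gx <- rep(0:(a@width - 1), each = a@height)
  gy <- rep(0:(a@height - 1), times = a@width)
  src <- warpLookup(w, gx, gy)
  lab <- lookupLabels(atlas, pixelToAtlas(a, src[, 1], src[, 2]))
  matrix(lab, nrow = a@height, ncol = a@width)
}
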