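#' @include AllClasses.R atlas.R anchoring.R warp.R quantify.R
NULL

# id scheme of the synthetic atlas: left-hemisphere structures carry ids
# 10, 11, 20, 21, ...; the mirrored right-hemisphere twin of id k is k + 100.
SYNTH_RIGHT_OFFSET <- 100L

#' Generate a synthetic, mirror-symmetric label atlas
#'
#' Builds a deterministic test atlas emulating the gross layout of a rodent
#' brain reference volume: per hemisphere, a nested pair of ellipsoidal
#' shells ("cortex" outside, "subcortex" inside) plus \code{nNuclei}
#' spherical nuclei embedded in the subcortex at seeded positions. The
#' volume is exactly mirror-symmetric about the declared midsagittal plane
#' (axis 1 at coordinate \eqn{(X-1)/2}): voxel \eqn{(x,y,z)} with left-side
#' id \eqn{k} mirrors to \eqn{(X-1-x,y,z)} with id \eqn{k+100}. The
#' hierarchy is root - \{left, right\} - structures (depth 3) or root -
#' structures (depth 2). Generation is a pure function of the arguments.
#'
#' @param seed Integer seed.
#' @param dims Integer 3-vector of voxel dimensions, each >= 16.
#' @param nNuclei Nuclei per hemisphere (>= 0).
#' @param depth Hierarchy depth, 2 or 3.
#' @param voxelSizeUm Voxel size in micrometers (default 25, a common atlas
#'   resolution).
#' @param name Atlas name.
#' @return An [AtlasVolume-class].
#' @examples
#' atl <- synthAtlas(seed = 1, dims = c(24, 32, 24), nNuclei = 1)
#' atl
#' @export
synthAtlas <- function(seed = 1L, dims = c(64L, 80L, 56L), nNuclei = 3L,
                       depth = 3L, voxelSizeUm = 25, name = "synthetic") {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 16L))
    stop("dims must be 3 integers, each >= 16", call. = FALSE)
  if (!depth %in% c(2L, 3L)) stop("depth must be 2 or 3", call. = FALSE)
  nNuclei <- as.integer(nNuclei)
  X <- dims[1]; Y <- dims[2]; Z <- dims[3]
  hx <- X %/% 2L                       # left hemisphere: x in 0..hx-1

  ctr <- c((hx - 1) / 2, (Y - 1) / 2, (Z - 1) / 2)
  semi <- c(0.42 * hx, 0.42 * Y, 0.42 * Z)
  nucR <- max(2, round(0.15 * min(semi)))

  # normalized squared radius over the left half-grid
  xs <- (0:(hx - 1) - ctr[1]) / semi[1]
  ys <- (0:(Y - 1) - ctr[2]) / semi[2]
  zs <- (0:(Z - 1) - ctr[3]) / semi[3]
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)

  left <- array(0L, dim = c(hx, Y, Z))
  left[r2 <= 1] <- 10L                      # cortex shell
  left[r2 <= 0.49] <- 11L                   # subcortex core

  nucCenters <- NULL
  if (nNuclei > 0L) {
    # centers sampled inside the subcortex ellipsoid shrunk per axis by the
    # nucleus radius plus one voxel, so every nucleus lies strictly inside
    shrunk <- 0.7 * semi - nucR - 1
    if (any(shrunk < 0.5))
      stop("dims too small to host ", nNuclei, " nuclei of radius ", nucR,
           call. = FALSE)
    nucCenters <- withSeed(seed, {
      acc <- matrix(numeric(0), 0, 3)
      tries <- 0L
      while (nrow(acc) < nNuclei && tries < 5000L) {
        tries <- tries + 1L
        cand <- ctr + stats::runif(3, -1, 1) * shrunk
        if (sum(((cand - ctr) / shrunk)^2) > 1) next
        if (nrow(acc) &&
            min(sqrt(rowSums(sweep(acc, 2, cand)^2))) <= 2 * nucR + 1) next
        acc <- rbind(acc, cand)
      }
      if (nrow(acc) < nNuclei)
        stop("dims too small to host ", nNuclei, " non-overlapping nuclei",
             call. = FALSE)
      acc
    })
    gx <- rep(0:(hx - 1), times = Y * Z)
    gy <- rep(rep(0:(Y - 1), each = hx), times = Z)
    gz <- rep(0:(Z - 1), each = hx * Y)
    for (k in seq_len(nNuclei)) {
      inside <- (gx - nucCenters[k, 1])^2 + (gy - nucCenters[k, 2])^2 +
        (gz - nucCenters[k, 3])^2 <= nucR^2
      left[inside] <- 19L + k
    }
  }

  labels <- array(0L, dim = dims)
  labels[1:hx, , ] <- left
  right <- left[hx:1, , , drop = FALSE]     # mirror x
  right[right > 0L] <- right[right > 0L] + SYNTH_RIGHT_OFFSET
  labels[(X - hx + 1):X, , ] <- right

  leftIds <- c(10L, 11L, if (nNuclei > 0L) 19L + seq_len(nNuclei))
  leftNames <- c("cortex", "subcortex",
                 if (nNuclei > 0L) paste0("nucleus_", seq_len(nNuclei)))
  pal <- withSeed(seed + 7L,
                  matrix(sample(40:220, 2 * length(leftIds) * 3, TRUE),
                         ncol = 3))
  structRows <- data.frame(
    id = c(leftIds, leftIds + SYNTH_RIGHT_OFFSET),
    name = c(paste0("left_", leftNames), paste0("right_", leftNames)),
    parent_id = if (depth == 3L)
      rep(c(2L, 3L), each = length(leftIds)) else rep(1L, 2 * length(leftIds)),
    r = pal[, 1], g = pal[, 2], b = pal[, 3], stringsAsFactors = FALSE)
  topRows <- if (depth == 3L)
    data.frame(id = c(1L, 2L, 3L), name = c("brain", "left", "right"),
               parent_id = c(NA_integer_, 1L, 1L),
               r = c(200L, 120L, 120L), g = c(200L, 120L, 60L),
               b = c(200L, 200L, 60L), stringsAsFactors = FALSE)
  else
    data.frame(id = 1L, name = "brain", parent_id = NA_integer_,
               r = 200L, g = 200L, b = 200L, stringsAsFactors = FALSE)
  hierarchy <- rbind(topRows, structRows)

  new("AtlasVolume", name = name, labels = labels,
      voxelSize = rep(as.numeric(voxelSizeUm), 3),
      midlineAxis = 1L, midlineCoord = (X - 1) / 2,
      hierarchy = hierarchy)
}

#' Generate a serial section series with known anchorings
#'
#' Cuts the synthetic atlas into evenly spaced sections along its second
#' axis, emulating a serial coronal-like series. Anchorings are affine in
#' the section index; oblique mode adds a fixed in-plane tilt to the
#' spanning vectors. Grayscale section images are rendered from the region
#' ids with seeded Gaussian noise. The returned anchorings are the ground
#' truth against which registration operations can be checked; optional
#' random displacement markers (ground-truth warps) can be added per
#' section.
#'
#' @param atlas An [AtlasVolume-class].
#' @param nSections Number of sections (>= 1).
#' @param orientation \code{"coronal"} or \code{"oblique"}.
#' @param seed Integer seed for rendering noise and markers.
#' @param noiseSd Gaussian noise standard deviation on the 0..1 intensity
#'   scale.
#' @param nMarkers Random displacement markers per section (default 0:
#'   identity warp).
#' @param filePrefix Prefix for generated filenames
#'   (\code{<prefix>_sNNN.png}).
#' @return A list with elements \code{series} (a fully anchored
#'   [SectionSeries-class]), \code{images} (list of grayscale matrices),
#'   \code{labelMaps} (list of label maps the renderer used) and
#'   \code{positions} (numeric cutting-axis positions).
#' @export
synthSeries <- function(atlas, nSections = 5L, orientation = c("coronal", "oblique"),
                        seed = 1L, noiseSd = 0.02, nMarkers = 0L,
                        filePrefix = "sec") {
  orientation <- match.arg(orientation)
  nSections <- stopifnotScalarCount(nSections, "nSections")
  d <- atlasDims(atlas)
  W <- d[1]; H <- d[3]; Y <- d[2]
  tilt <- if (orientation == "oblique") c(4, 6) else c(0, 0)
  lo <- 0.2 * (Y - 1); hi <- 0.8 * (Y - 1)
  pos <- if (nSections == 1L) (lo + hi) / 2 else
    seq(lo, hi, length.out = nSections)
  if (any(pos < 0 | pos + sum(tilt) > Y - 1))
    stop("sections would fall outside the volume", call. = FALSE)

  ids <- sort(atlas@hierarchy$id)
  gray <- function(lm) {
    g <- matrix(0, nrow(lm), ncol(lm))
    fg <- lm > 0L
    g[fg] <- 0.2 + 0.75 * match(lm[fg], ids) / length(ids)
    g
  }
  out <- withSeed(seed, {
    secs <- vector("list", nSections)
    imgs <- vector("list", nSections)
    lms <- vector("list", nSections)
    for (i in seq_len(nSections)) {
      a <- anchoring(o = c(0, pos[i], 0),
                     u = c(W - 1, tilt[1], 0),
                     v = c(0, tilt[2], H - 1),
                     width = W, height = H, sectionNr = i)
      lm <- sliceAtlas(atlas, a)
      img <- gray(lm) + stats::rnorm(length(lm), sd = noiseSd)
      img <- pmin(1, pmax(0, img))
      dim(img) <- dim(lm)
      mk <- NULL
      if (nMarkers > 0L) {
        tx <- stats::runif(nMarkers, 0.2 * (W - 1), 0.8 * (W - 1))
        ty <- stats::runif(nMarkers, 0.2 * (H - 1), 0.8 * (H - 1))
        mk <- cbind(tx, ty,
                    tx + stats::rnorm(nMarkers, sd = 1.5),
                    ty + stats::rnorm(nMarkers, sd = 1.5))
        colnames(mk) <- c("targetX", "targetY", "sourceX", "sourceY")
      }
      secs[[i]] <- list(filename = sprintf("%s_s%03d.png", filePrefix, i),
                        nr = i, width = W, height = H,
                        anchoring = a, markers = mk)
      imgs[[i]] <- img
      lms[[i]] <- lm
    }
    list(secs = secs, imgs = imgs, lms = lms)
  })
  list(series = new("SectionSeries", atlasName = atlas@name,
                    sections = out$secs),
       images = out$imgs, labelMaps = out$lms, positions = pos)
}

# centers where a disk of the given margin-dilated footprint fits entirely
# inside region `id` of the label map (1-based matrix indices)
plantCandidates <- function(lm, id, marg) {
  H <- nrow(lm); W <- ncol(lm)
  R <- lm == id
  ok <- R
  for (j in seq_len(nrow(marg))) {
    dyy <- marg$dy[j]; dxx <- marg$dx[j]
    shifted <- matrix(FALSE, H, W)
    rs <- max(1, 1 - dyy):min(H, H - dyy)
    cs <- max(1, 1 - dxx):min(W, W - dxx)
    shifted[rs, cs] <- R[rs + dyy, cs + dxx]
    ok <- ok & shifted
    if (!any(ok)) break
  }
  which(ok)
}

diskOffsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

# dilate offsets by the 8-neighborhood so planted disks keep a 1-pixel
# in-region margin: nothing 8-adjacent to a disk pixel leaves the region,
# so split-mode and centroid-mode object counting agree on fixtures.
marginOffsets <- function(radius) {
  d <- diskOffsets(radius)
  g <- expand.grid(ex = -1:1, ey = -1:1)
  out <- unique(data.frame(
    dx = rep(d$dx, each = nrow(g)) + rep(g$ex, times = nrow(d)),
    dy = rep(d$dy, each = nrow(g)) + rep(g$ey, times = nrow(d))))
  out
}

#' Plant disk objects inside atlas regions
#'
#' Generates a binary segmentation with known ground truth: for each
#' requested region, non-overlapping disks of the given radius are planted
#' fully inside the region with a 1-pixel margin to the region boundary (so
#' no disk pixel is 8-adjacent to a pixel outside its region, and well
#' separated disks never merge). Placement is seeded rejection sampling;
#' an error is raised when a region cannot host its disks.
#'
#' @param lm Integer label map the disks are planted into.
#' @param counts Named integer vector: names are region ids, values the
#'   number of disks to plant in each.
#' @param radius Disk radius in pixels (a disk is the set of integer offsets
#'   with \eqn{dx^2 + dy^2 \le r^2}; radius 3 gives 29 pixels).
#' @param seed Integer seed.
#' @return A list with elements \code{segmentation} (0/1 integer matrix) and
#'   \code{truth} (a \code{data.frame} with columns \code{region_id, count,
#'   pixels}).
#' @export
synthSegmentation <- function(lm, counts, radius = 3, seed = 1L) {
  ids <- as.integer(names(counts))
  if (anyNA(ids)) stop("counts must be named by region id", call. = FALSE)
  disk <- diskOffsets(radius)
  marg <- marginOffsets(radius)
  nDisk <- nrow(disk)
  H <- nrow(lm); W <- ncol(lm)
  seg <- matrix(0L, H, W)
  centers <- withSeed(seed, {
    acc <- list()
    for (id in sort(ids)) {
      k <- counts[[as.character(id)]]
      if (k == 0L) { acc[[as.character(id)]] <- matrix(0L, 0, 2); next }
      cand <- plantCandidates(lm, id, marg)
      if (length(cand) < k)
        stop("region ", id, " cannot host ", k, " disks of radius ", radius,
             call. = FALSE)
      cand <- cand[sample.int(length(cand))]
      chosen <- matrix(0L, 0, 2)  # (row, col), 1-based
      for (p in cand) {
        if (nrow(chosen) == k) break
        ro <- (p - 1L) %% H + 1L; co <- (p - 1L) %/% H + 1L
        if (nrow(chosen) &&
            min(sqrt((chosen[, 1] - ro)^2 + (chosen[, 2] - co)^2)) <=
              2 * radius + 2) next
        chosen <- rbind(chosen, c(ro, co))
      }
      if (nrow(chosen) < k)
        stop("placement impossible: region ", id, " cannot fit ", k,
             " separated disks of radius ", radius, call. = FALSE)
      acc[[as.character(id)]] <- chosen
    }
    acc
  })
  for (id in names(centers)) {
    ch <- centers[[id]]
    for (i in seq_len(nrow(ch))) {
      rr <- ch[i, 1] + disk$dy; cc <- ch[i, 2] + disk$dx
      seg[cbind(rr, cc)] <- 1L
    }
  }
  truth <- data.frame(region_id = sort(ids),
                      count = as.integer(counts[as.character(sort(ids))]),
                      pixels = as.integer(counts[as.character(sort(ids))]) * nDisk,
                      stringsAsFactors = FALSE)
  list(segmentation = seg, truth = truth)
}

#' Write a complete synthetic fixture directory
#'
#' Generates and writes everything a pipeline run needs: atlas NIfTI +
#' hierarchy JSON, rendered grayscale section PNGs, the series descriptor
#' JSON, planted segmentation PNGs and a ground-truth JSON (true anchorings,
#' true markers and per-section planted object counts and pixel totals).
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed driving every generator.
#' @param dims,nNuclei Atlas parameters, see [synthAtlas()].
#' @param nSections,orientation,nMarkers Series parameters, see
#'   [synthSeries()].
#' @param radius,countsPerRegion Segmentation parameters: each hosting
#'   region (any region with enough room in a section) receives
#'   \code{countsPerRegion} planted disks of the given radius.
#' @return Invisibly, a list of the written paths plus the ground truth.
#' @export
simulateFixture <- function(dir, seed = 1L, dims = c(64L, 80L, 56L),
                            nNuclei = 3L, nSections = 5L,
                            orientation = "coronal", nMarkers = 0L,
                            radius = 3, countsPerRegion = 2L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- synthAtlas(seed = seed, dims = dims, nNuclei = nNuclei)
  volumePath <- file.path(dir, "atlas.nii.gz")
  hierPath <- file.path(dir, "hierarchy.json")
  writeAtlas(atlas, volumePath, hierPath)

  ss <- synthSeries(atlas, nSections = nSections, orientation = orientation,
                    seed = seed + 1L, nMarkers = nMarkers)
  for (i in seq_along(ss$images)) {
    png::writePNG(ss$images[[i]],
                  file.path(dir, ss$series@sections[[i]]$filename))
  }
  descPath <- file.path(dir, "descriptor.json")
  writeSeriesDescriptor(ss$series, descPath)

  marg <- marginOffsets(radius)
  minCand <- 60 * countsPerRegion  # generous room for separated placement
  segPaths <- character(nSections)
  truth <- vector("list", nSections)
  for (i in seq_len(nSections)) {
    sec <- ss$series@sections[[i]]
    lm <- warpedLabelMap(atlas, sec$anchoring, sec$markers)
    present <- sort(setdiff(unique(as.vector(lm)), 0L))
    host <- present[vapply(present, function(id)
      length(plantCandidates(lm, id, marg)) >= minCand, logical(1))]
    counts <- stats::setNames(rep(countsPerRegion, length(host)),
                              as.character(host))
    sg <- synthSegmentation(lm, counts, radius = radius, seed = seed + 10L + i)
    dir.create(file.path(dir, "segmentation"), showWarnings = FALSE)
    segPaths[i] <- file.path(dir, "segmentation",
                             sprintf("seg_s%03d.png", sec$nr))
    png::writePNG(matrix(as.numeric(sg$segmentation), nrow(sg$segmentation)),
                  segPaths[i])
    truth[[i]] <- list(
      nr = sec$nr,
      anchoring = c(sec$anchoring@o, sec$anchoring@u, sec$anchoring@v),
      markers = if (is.null(sec$markers)) NULL else
        lapply(seq_len(nrow(sec$markers)), function(j) unname(sec$markers[j, ])),
      regions = lapply(seq_len(nrow(sg$truth)), function(j)
        list(region_id = sg$truth$region_id[j], count = sg$truth$count[j],
             pixels = sg$truth$pixels[j])))
  }
  gtPath <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(seed = seed, sections = truth), gtPath,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, atlas = volumePath, hierarchy = hierPath,
                 descriptor = descPath, segmentations = segPaths,
                 groundTruth = gtPath, truth = truth))
}
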