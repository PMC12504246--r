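test_that("corner markers are auto-inserted and the rectangle splits in two", {
  w <- buildWarp(NULL, 11, 9)
  expect_identical(nrow(w@markers), 4L)
  expect_identical(nrow(w@triangles), 2L)
  expect_setequal(apply(w@markers[, 1:2], 1, paste, collapse = ","),
                  c("0,0", "10,0", "0,8", "10,8"))
  # source equals target for fixed corners
  expect_equal(w@markers[, 1:2], w@markers[, 3:4], ignore_attr = TRUE)
})

test_that("one central marker fans the rectangle into four triangles", {
  w <- buildWarp(matrix(c(5, 4, 5, 4), 1), 11, 9)
  expect_identical(nrow(w@triangles), 4L)
  # every triangle contains the center vertex (index 5, after 4 corners)
  expect_true(all(apply(w@triangles, 1, function(tr) 5L %in% tr)))
})

test_that("duplicate targets and degenerate geometry are rejected", {
  mk <- rbind(c(3, 3, 1, 1), c(3, 3, 2, 2))
  expect_error(buildWarp(mk, 11, 11), "duplicate")
  # a user marker on a corner target replaces the fixed corner
  w <- buildWarp(matrix(c(0, 0, 2, 2), 1), 11, 11)
  expect_identical(nrow(w@markers), 4L)
  expect_equal(unname(w@markers[w@markers[, 1] == 0 & w@markers[, 2] == 0,
                                3:4]), c(2, 2))
})

test_that("identity markers give the identity lookup", {
  mk <- cbind(c(3, 7, 5), c(3, 3, 8), c(3, 7, 5), c(3, 3, 8))
  w <- buildWarp(mk, 11, 11)
  withr::with_seed(5, {
    x <- runif(100, 0, 10); y <- runif(100, 0, 10)
  })
  src <- warpLookup(w, x, y)
  expect_equal(src[, 1], x, tolerance = 1e-12)
  expect_equal(src[, 2], y, tolerance = 1e-12)
})

test_that("each marker's target maps exactly to its source", {
  withr::with_seed(6, mk <- randomMarkers(6, 40, 30))
  w <- suppressWarnings(buildWarp(mk, 40, 30))  # folds are fine here
  src <- warpLookup(w, w@markers[, 1], w@markers[, 2])
  expect_equal(src[, 1], unname(w@markers[, 3]), tolerance = 1e-12)
  expect_equal(src[, 2], unname(w@markers[, 4]), tolerance = 1e-12)
})

test_that("lookup matches the per-triangle affine oracle", {
  withr::with_seed(8, {
    mk <- randomMarkers(6, 40, 30)
    x <- runif(50, 0, 39); y <- runif(50, 0, 29)
  })
  w <- buildWarp(mk, 40, 30)
  got <- warpLookup(w, x, y)
  want <- oracleWarpLookup(w, x, y)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("lookup is continuous across shared edges and piecewise affine", {
  withr::with_seed(9, mk <- randomMarkers(5, 30, 30))
  w <- buildWarp(mk, 30, 30)
  # edge continuity: points on shared edges give one result no matter the side
  tri <- w@triangles
  edgeKey <- function(a, b) paste(min(a, b), max(a, b))
  seen <- list()
  for (t in seq_len(nrow(tri))) {
    for (e in list(tri[t, 1:2], tri[t, 2:3], tri[t, c(3, 1)])) {
      k <- edgeKey(e[1], e[2])
      seen[[k]] <- c(seen[[k]], t)
    }
  }
  shared <- names(seen)[vapply(seen, length, integer(1)) == 2L]
  for (k in shared) {
    ab <- as.integer(strsplit(k, " ")[[1]])
    for (f in c(0.25, 0.5, 0.8)) {
      px <- (1 - f) * w@markers[ab[1], 1] + f * w@markers[ab[2], 1]
      py <- (1 - f) * w@markers[ab[1], 2] + f * w@markers[ab[2], 2]
      got <- warpLookup(w, px, py)
      want <- oracleWarpLookup(w, px, py)   # independent triangle choice
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
  # piecewise affinity: the lookup of a mean equals the mean of lookups for
  # points inside one triangle
  tr <- tri[1, ]
  wgt <- matrix(c(.6, .2, .2, .2, .6, .2, .2, .2, .6), 3, byrow = TRUE)
  pts <- wgt %*% w@markers[tr, 1:2]
  mid <- colMeans(pts)
  expect_equal(warpLookup(w, mid[1], mid[2])[1, ],
               colMeans(warpLookup(w, pts[, 1], pts[, 2])),
               tolerance = 1e-9)
})

test_that("out-of-hull queries raise and folds warn", {
  w <- buildWarp(NULL, 11, 11)
  expect_error(warpLookup(w, -5, -5), "outside")
  # a marker dragged past another inverts a source triangle
  mk <- rbind(c(3, 5, 8, 5), c(7, 5, 2, 5))
  expect_warning(buildWarp(mk, 11, 11), "folded")
})

test_that("warped label maps reduce to the linear slice without markers", {
  atl <- makeRandomAtlas(12)
  withr::with_seed(13, a <- randomAnchoring(width = 12L, height = 10L))
  expect_identical(warpedLabelMap(atl, a, NULL), sliceAtlas(atl, a))
  # identity markers leave the map bit-identical too
  mk <- cbind(c(4, 8), c(5, 3), c(4, 8), c(5, 3))
  expect_identical(warpedLabelMap(atl, a, mk), sliceAtlas(atl, a))
})

test_that("warped labels are a subset of the atlas labels and constants stay constant", {
  atl <- makeRandomAtlas(14)
  withr::with_seed(15, {
    a <- randomAnchoring(width = 15L, height = 12L)
    mk <- randomMarkers(4, 15, 12)
  })
  wlm <- suppressWarnings(warpedLabelMap(atl, a, mk))
  expect_true(all(wlm %in% c(0L, regionHierarchy(atl)$id)))
  lab <- array(2L, dim = c(16, 16, 16))
  const <- new("AtlasVolume", name = "c", labels = lab,
               voxelSize = c(1, 1, 1), midlineAxis = NA_integer_,
               midlineCoord = NA_real_, hierarchy = flatHierarchy(2))
  inA <- anchoring(c(2, 2, 2), c(11, 0, 1), c(0, 11, 0), 12, 12)
  expect_true(all(suppressWarnings(
    warpedLabelMap(const, inA, mk[, , drop = FALSE])) == 2L))
})

test_that("dragging a boundary marker shifts the boundary at the marker row", {
  # two-region volume split at x = 8 (atlas x < 8 -> region 1, else 2)
  lab <- array(2L, dim = c(16, 16, 16))
  lab[1:8, , ] <- 1L
  atl <- new("AtlasVolume", name = "two", labels = lab,
             voxelSize = c(1, 1, 1), midlineAxis = NA_integer_,
             midlineCoord = NA_real_, hierarchy = flatHierarchy(1:2))
  a <- anchoring(c(0, 0, 8), c(15, 0, 0), c(0, 15, 0), 16, 16)
  lin <- sliceAtlas(atl, a)
  row <- 8L  # pixel y = 7
  bLin <- max(which(lin[row, ] == 1L))
  k <- 3
  # drag: the pixel now at x=bLin+k should show what was at x=bLin
  mk <- matrix(c(bLin - 1 + k, 7, bLin - 1, 7), 1)
  wlm <- warpedLabelMap(atl, a, mk)
  bWarp <- max(which(wlm[row, ] == 1L))
  expect_equal(bWarp, bLin + k)
})
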