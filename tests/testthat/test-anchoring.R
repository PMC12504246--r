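test_that("section numbers parse from the _sXXX convention", {
  expect_identical(parseSectionNumber("rat42_s017.png"), 17L)
  expect_identical(parseSectionNumber("brain_s001_s002.tif"), 2L)
  expect_identical(parseSectionNumber("/some/dir/mouse_s003.png"), 3L)
  expect_error(parseSectionNumber("section7.png"), "_sXXX")
})

test_that("pixel-to-atlas mapping is the stated plane equation", {
  a <- anchoring(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), 11, 11)
  expect_equal(pixelToAtlas(a, 0, 0)[1, ], c(0, 0, 0))
  expect_equal(pixelToAtlas(a, 10, 10)[1, ], c(10, 10, 0))
  expect_equal(pixelToAtlas(a, 5, 2)[1, ], c(5, 2, 0))
  # extrapolation outside the image is linear
  expect_equal(pixelToAtlas(a, -5, 20)[1, ], c(-5, 20, 0))
})

test_that("the four corners map exactly to o, o+u, o+v, o+u+v", {
  withr::with_seed(11, {
    for (i in 1:50) {
      a <- randomAnchoring()
      W <- a@width; H <- a@height
      corners <- pixelToAtlas(a, c(0, W - 1, 0, W - 1), c(0, 0, H - 1, H - 1))
      expect_identical(corners[1, ], a@o)
      expect_identical(corners[2, ], a@o + a@u)
      expect_identical(corners[3, ], a@o + a@v)
      expect_identical(corners[4, ], a@o + a@u + a@v)
    }
  })
})

test_that("slicing matches the brute-force per-pixel oracle", {
  atl <- makeRandomAtlas(2)
  withr::with_seed(3, {
    for (i in 1:20) {
      a <- randomAnchoring()
      expect_identical(sliceAtlas(atl, a), oracleSliceAtlas(atl, a))
    }
  })
})

test_that("axis-aligned slices equal direct array plane extraction", {
  atl <- makeRandomAtlas(4)
  d <- atlasDims(atl)
  for (k in c(0L, 7L, 15L)) {
    a <- anchoring(c(0, 0, k), c(d[1] - 1, 0, 0), c(0, d[2] - 1, 0),
                   d[1], d[2])
    lm <- sliceAtlas(atl, a)
    # pixel (x, y) -> atlas (x, y, k); LabelMap is height x width
    expect_identical(lm, t(atl@labels[, , k + 1]))
  }
})

test_that("degenerate and out-of-volume anchorings are handled", {
  atl <- makeRandomAtlas(5)
  expect_error(anchoring(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 8, 8),
               "linearly independent")
  far <- anchoring(c(1e3, 1e3, 1e3), c(10, 0, 0), c(0, 10, 0), 8, 8)
  expect_true(all(sliceAtlas(atl, far) == 0L))
  # constant-label volume gives a constant map
  lab <- array(3L, dim = c(16, 16, 16))
  const <- new("AtlasVolume", name = "c", labels = lab,
               voxelSize = c(1, 1, 1), midlineAxis = NA_integer_,
               midlineCoord = NA_real_, hierarchy = flatHierarchy(3))
  a <- anchoring(c(2, 2, 2), c(10, 2, 1), c(0, 9, 2), 8, 8)
  expect_true(all(sliceAtlas(const, a) == 3L))
})

mkSeries <- function(anchors, nrs = seq_along(anchors), W = 10L, H = 10L) {
  sectionSeries(lapply(seq_along(nrs), function(i)
    list(filename = sprintf("t_s%03d.png", nrs[i]), nr = nrs[i],
         width = W, height = H, anchoring = anchors[[i]])))
}

test_that("propagation interpolates, extrapolates and replicates by section number", {
  a1 <- anchoring(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), 10, 10, 1)
  a3 <- anchoring(c(2, 4, 6), c(10, 2, 0), c(0, 10, 2), 10, 10, 3)
  s <- mkSeries(list(a1, NULL, a3, NULL, NULL), nrs = c(1L, 2L, 3L, 4L, 5L))
  p <- propagateSeries(s)
  getv <- function(series, i) {
    an <- series@sections[[i]]$anchoring
    c(an@o, an@u, an@v)
  }
  v1 <- getv(p, 1); v3 <- getv(p, 3)
  # interior section: componentwise mean
  expect_equal(getv(p, 2), (v1 + v3) / 2)
  # extrapolation: closed-form linear formula from the two nearest anchored
  expect_equal(getv(p, 4), v3 + (v3 - v1) * (4 - 3) / (3 - 1))
  expect_equal(getv(p, 5), v3 + (v3 - v1) * (5 - 3) / (3 - 1))
  # anchored sections unchanged
  expect_identical(p@sections[[1]]$anchoring, a1)
  expect_identical(p@sections[[3]]$anchoring, a3)
  # clamp replicates the nearest anchored section beyond the range
  pc <- propagateSeries(s, clamp = TRUE)
  expect_equal(getv(pc, 5), v3)
})

test_that("propagation replicates a single anchored section and rejects none", {
  a2 <- anchoring(c(1, 2, 3), c(5, 0, 0), c(0, 5, 0), 10, 10, 2)
  s <- mkSeries(list(NULL, a2, NULL), nrs = c(1L, 2L, 4L))
  p <- propagateSeries(s)
  for (i in 1:3)
    expect_equal(c(p@sections[[i]]$anchoring@o, p@sections[[i]]$anchoring@u,
                   p@sections[[i]]$anchoring@v), c(a2@o, a2@u, a2@v))
  empty <- mkSeries(list(NULL, NULL), nrs = c(1L, 2L))
  expect_error(propagateSeries(empty), "no anchored")
})

test_that("propagation is shift-equivariant in section number", {
  a1 <- anchoring(c(0, 1, 2), c(8, 0, 1), c(0, 8, 1), 10, 10, 1)
  a5 <- anchoring(c(4, 1, 0), c(8, 2, 1), c(1, 8, 0), 10, 10, 5)
  base <- propagateSeries(mkSeries(list(a1, NULL, a5), nrs = c(1L, 3L, 5L)))
  shift <- propagateSeries(mkSeries(list(a1, NULL, a5), nrs = c(11L, 13L, 15L)))
  for (i in 1:3) {
    bi <- base@sections[[i]]$anchoring; si <- shift@sections[[i]]$anchoring
    expect_equal(c(si@o, si@u, si@v), c(bi@o, bi@u, bi@v))
  }
})

test_that("anchorings are recovered from exact correspondences", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      a <- randomAnchoring()
      px <- cbind(c(0, a@width - 1, 0), c(0, 0, a@height - 1))
      co <- pixelToAtlas(a, px[, 1], px[, 2])
      est <- estimateAnchoring(px, co, a@width, a@height)
      err <- max(abs(c(est@o - a@o, est@u - a@u, est@v - a@v)))
      expect_lt(err, 1e-9)
    }
  })
})

test_that("noisy correspondences recover u and v within tolerance", {
  a <- anchoring(c(5, 40, 3), c(60, 4, 0), c(0, 6, 50), 64, 56)
  withr::with_seed(7, {
    px <- cbind(runif(20, 0, 63), runif(20, 0, 55))
    co <- pixelToAtlas(a, px[, 1], px[, 2]) +
      matrix(rnorm(60, sd = 0.5), ncol = 3)
  })
  est <- estimateAnchoring(px, co, 64, 56)
  # residual RMS bounded by the noise level
  pred <- pixelToAtlas(est, px[, 1], px[, 2])
  expect_lte(sqrt(mean((pred - co)^2)), 3 * 0.5)
  expect_lt(sqrt(sum((est@u - a@u)^2)) / sqrt(sum(a@u^2)), 0.05)
  expect_lt(sqrt(sum((est@v - a@v)^2)) / sqrt(sum(a@v^2)), 0.05)
})

test_that("collinear or insufficient correspondences are rejected", {
  px <- cbind(c(0, 5, 10), c(0, 5, 10))      # one line
  co <- matrix(runif(9), 3)
  expect_error(estimateAnchoring(px, co, 11, 11), "collinear|rank")
  expect_error(estimateAnchoring(px[1:2, ], co[1:2, ], 11, 11), "3")
})

test_that("series descriptors round-trip value-identically", {
  withr::with_seed(31, {
    secs <- lapply(1:4, function(i) {
      list(filename = sprintf("img_s%03d.png", i), nr = i,
           width = 20L, height = 16L,
           anchoring = if (i %% 2) randomAnchoring(width = 20L, height = 16L,
                                                   sectionNr = i) else NULL,
           markers = if (i == 3) randomMarkers(3, 20, 16) else NULL)
    })
  })
  s <- sectionSeries(secs, atlasName = "demo")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "desc.json")
  writeSeriesDescriptor(s, p)
  got <- readSeriesDescriptor(p)
  expect_identical(got@atlasName, "demo")
  expect_identical(nSections(got), nSections(s))
  for (i in 1:4) {
    g <- got@sections[[i]]; o <- s@sections[[i]]
    expect_identical(g$filename, o$filename)
    expect_identical(g$nr, o$nr)
    if (is.null(o$anchoring)) expect_null(g$anchoring)
    else expect_equal(c(g$anchoring@o, g$anchoring@u, g$anchoring@v),
                      c(o$anchoring@o, o$anchoring@u, o$anchoring@v))
    if (is.null(o$markers)) expect_null(g$markers)
    else expect_equal(unname(g$markers), unname(o$markers))
  }
})

test_that("label maps survive the 16-bit image round trip", {
  withr::with_seed(41, {
    lm <- matrix(sample(c(0L, 7L, 300L, 65535L), 80, TRUE), 10, 8)
  })
  dir <- withr::local_tempdir()
  p <- file.path(dir, "lm.tif")
  writeLabelMapImage(lm, p)
  expect_identical(readLabelMapImage(p), lm)
})
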