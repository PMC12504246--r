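# small deterministic label map: two regions side by side plus background rim
twoRegionMap <- function(H = 20L, W = 30L) {
  lm <- matrix(0L, H, W)
  lm[3:18, 2:14] <- 4L
  lm[3:18, 15:28] <- 5L
  lm
}

test_that("an empty segmentation yields all-zero object stats", {
  lm <- twoRegionMap()
  rep <- quantifySection(matrix(0L, nrow(lm), ncol(lm)), lm)
  s <- quantStats(rep)
  expect_true(all(s$object_pixels == 0L))
  expect_true(all(s$object_count == 0L))
  expect_true(all(s$load == 0))
  # region pixels + background = total pixels
  expect_identical(sum(s$region_pixels), length(lm))
})

test_that("a segmentation equal to one region has load 1 and one object", {
  lm <- twoRegionMap()
  seg <- matrix(as.integer(lm == 4L), nrow(lm))
  s <- quantStats(quantifySection(seg, lm))
  r4 <- s[s$region_id == 4L, ]
  expect_identical(r4$object_count, 1L)
  expect_equal(r4$load, 1.0)
  expect_identical(r4$object_pixels, r4$region_pixels)
})

test_that("split mode counts 8-connected fragments per region", {
  lm <- twoRegionMap()
  seg <- matrix(0L, nrow(lm), ncol(lm))
  # one blob straddling the region border at columns 13-16
  seg[5:7, 13:16] <- 1L
  # one diagonal pair inside region 4 (8-connected: one object)
  seg[12, 5] <- 1L; seg[13, 6] <- 1L
  s <- quantStats(quantifySection(seg, lm, mode = "split"))
  expect_identical(s$object_count[s$region_id == 4L], 2L)  # blob part + pair
  expect_identical(s$object_count[s$region_id == 5L], 1L)
  expect_identical(s$object_pixels[s$region_id == 4L], 6L + 2L)
  expect_identical(s$object_pixels[s$region_id == 5L], 6L)
  # centroid mode assigns the straddling blob wholly to one region
  sc <- quantStats(quantifySection(seg, lm, mode = "centroid"))
  expect_identical(sum(sc$object_count), 2L)
  expect_identical(sum(sc$object_pixels), sum(seg))
})

test_that("planted disks are recovered exactly", {
  atl <- synthAtlas(seed = 3)
  a <- anchoring(c(0, 40, 0), c(63, 0, 0), c(0, 0, 55), 64, 56, 1)
  lm <- sliceAtlas(atl, a)
  counts <- c("11" = 3L, "111" = 2L)
  sg <- synthSegmentation(lm, counts, radius = 3, seed = 3)
  for (mode in c("split", "centroid")) {
    s <- quantStats(quantifySection(sg$segmentation, lm, mode = mode))
    for (i in seq_len(nrow(sg$truth))) {
      id <- sg$truth$region_id[i]
      expect_identical(s$object_count[s$region_id == id], sg$truth$count[i])
      expect_identical(s$object_pixels[s$region_id == id], sg$truth$pixels[i])
    }
  }
})

test_that("pixel tallies conserve and are monotone in the segmentation", {
  atl <- makeRandomAtlas(30, nLabels = 4)
  a <- anchoring(c(0, 0, 7), c(15, 0, 0), c(0, 15, 0), 16, 16)
  lm <- sliceAtlas(atl, a)
  withr::with_seed(31, {
    for (i in 1:25) {
      seg <- matrix(rbinom(length(lm), 1, 0.3), nrow(lm))
      s <- quantStats(quantifySection(seg, lm))
      expect_identical(sum(s$object_pixels), sum(seg))
      expect_identical(sum(s$region_pixels), length(lm))
      # add pixels: no region's object pixels may decrease
      seg2 <- seg | matrix(rbinom(length(lm), 1, 0.1), nrow(lm))
      s2 <- quantStats(quantifySection(seg2, lm))
      m <- match(s$region_id, s2$region_id)
      expect_true(all(s2$object_pixels[m] >= s$object_pixels))
    }
  })
})

test_that("leaf-level stats summed into parents equal collapsed quantification", {
  atl <- synthAtlas(seed = 9)
  h <- regionHierarchy(atl)
  a <- anchoring(c(0, 35, 0), c(63, 0, 0), c(0, 0, 55), 64, 56)
  lm <- sliceAtlas(atl, a)
  withr::with_seed(32, seg <- matrix(rbinom(length(lm), 1, 0.2), nrow(lm)))
  mapping <- collapseHierarchy(h, c(2L, 3L))   # hemispheres as parents
  coll <- quantStats(quantifySection(seg, lm, mapping = mapping))
  leaf <- quantStats(quantifySection(seg, lm))
  leafParent <- unname(mapping[as.character(leaf$region_id)])
  leafParent[leaf$region_id == 0L] <- 0L
  for (id in coll$region_id) {
    sel <- leafParent == id
    expect_identical(sum(leaf$region_pixels[sel]),
                     coll$region_pixels[coll$region_id == id])
    expect_identical(sum(leaf$object_pixels[sel]),
                     coll$object_pixels[coll$region_id == id])
    # fragments can merge across sibling leaves: leaf counts are an upper bound
    expect_gte(sum(leaf$object_count[sel]),
               coll$object_count[coll$region_id == id])
  }
})

test_that("aggregation recomputes load from summed pixels", {
  lm1 <- matrix(0L, 5, 5); lm1[1:2, 1:5] <- 7L   # region 7: 10 px
  lm2 <- matrix(0L, 6, 5); lm2[1:6, 1:5] <- 7L   # region 7: 30 px
  seg1 <- matrix(0L, 5, 5); seg1[1, 1:2] <- 1L   # 2 px -> load 0.2
  seg2 <- matrix(0L, 6, 5); seg2[1:6, 1:4] <- 1L # 24 px -> load 0.8
  r1 <- quantifySection(seg1, lm1, sectionNr = 1)
  r2 <- quantifySection(seg2, lm2, sectionNr = 2)
  agg <- aggregateReports(list(r1, r2))
  expect_equal(agg$load[agg$region_id == 7L], (2 + 24) / 40)
  # identity and permutation invariance
  expect_equal(aggregateReports(list(r1))$load,
               quantStats(r1)$load[match(aggregateReports(list(r1))$region_id,
                                         quantStats(r1)$region_id)])
  expect_equal(aggregateReports(list(r2, r1)), agg)
  # mixed mappings refuse to aggregate
  lmBig <- matrix(7L, 5, 5)
  mix <- quantifySection(seg1, lm1,
                         mapping = collapseHierarchy(flatHierarchy(7), 7L))
  expect_error(aggregateReports(list(r1, mix)), "mapping")
})

test_that("hemisphere masks partition sections and balance at the midline", {
  atl <- synthAtlas(seed = 2)
  a <- anchoring(c(0, 40, 0), c(63, 0, 0), c(0, 0, 55), 64, 56)
  hm <- hemisphereMask(atl, a)
  expect_identical(leftMask(hm) | rightMask(hm),
                   matrix(TRUE, 56, 64))
  expect_false(any(leftMask(hm) & rightMask(hm)))
  # the symmetric atlas splits a midline-centered coronal section evenly
  expect_lte(abs(sum(leftMask(hm)) - sum(rightMask(hm))), 64)
  # a sagittal section entirely left of the midline
  sag <- anchoring(c(10, 0, 0), c(0, 79, 0), c(0, 0, 55), 80, 56)
  expect_true(all(leftMask(hemisphereMask(atl, sag))))
  # missing midline metadata errors
  bare <- makeRandomAtlas(1)
  bare@midlineAxis <- NA_integer_; bare@midlineCoord <- NA_real_
  expect_error(hemisphereMask(bare, a), "midline")
})

test_that("left plus right stats equal unmasked stats per region", {
  atl <- synthAtlas(seed = 4)
  a <- anchoring(c(0, 45, 0), c(63, 0, 0), c(0, 0, 55), 64, 56)
  lm <- sliceAtlas(atl, a)
  hm <- hemisphereMask(atl, a)
  withr::with_seed(33, seg <- matrix(rbinom(length(lm), 1, 0.25), nrow(lm)))
  sAll <- quantStats(quantifySection(seg, lm))
  sL <- quantStats(quantifySection(seg, lm, hemiMask = hm, side = "left"))
  sR <- quantStats(quantifySection(seg, lm, hemiMask = hm, side = "right"))
  for (id in sAll$region_id) {
    lpx <- if (id %in% sL$region_id) sL$region_pixels[sL$region_id == id] else 0L
    rpx <- if (id %in% sR$region_id) sR$region_pixels[sR$region_id == id] else 0L
    expect_identical(lpx + rpx, sAll$region_pixels[sAll$region_id == id])
    lob <- if (id %in% sL$region_id) sL$object_pixels[sL$region_id == id] else 0L
    rob <- if (id %in% sR$region_id) sR$object_pixels[sR$region_id == id] else 0L
    expect_identical(lob + rob, sAll$object_pixels[sAll$region_id == id])
  }
})

test_that("warped hemisphere masks follow the deformation near the midline", {
  atl <- synthAtlas(seed = 2)
  a <- anchoring(c(0, 40, 0), c(63, 0, 0), c(0, 0, 55), 64, 56)
  # drag the pixel column at the midline 4 px to the right at mid-height
  mk <- matrix(c(35.5, 27, 31.5, 27), 1)
  hm0 <- hemisphereMask(atl, a)
  hm1 <- hemisphereMask(atl, a, mk)
  # at the marker's pixel the warped mask is left (its source is on-plane -> right edge shifts)
  expect_identical(sum(leftMask(hm1)) > sum(leftMask(hm0)), TRUE)
})

test_that("segmentation resampling preserves binarity and dims must match when disabled", {
  lm <- twoRegionMap()
  seg <- matrix(0L, 10, 15); seg[3:5, 4:6] <- 1L
  rep <- quantifySection(seg, lm)               # resampled up to 20 x 30
  expect_identical(sum(quantStats(rep)$region_pixels), length(lm))
  expect_error(quantifySection(seg, lm, resample = FALSE), "dims")
})
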