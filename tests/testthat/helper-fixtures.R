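# Fixture builders and independent oracles used across the suite.
# Oracles are written from the definitions (explicit arithmetic), not by
# calling the implementation paths they check.

flatHierarchy <- function(ids) {
  data.frame(id = as.integer(ids), name = paste0("reg", ids),
             parent_id = NA_integer_,
             r = 100L + as.integer(ids), g = 50L, b = 200L,
             stringsAsFactors = FALSE)
}

# random label volume with a flat hierarchy (every label is a root)
makeRandomAtlas <- function(seed, dims = c(16L, 16L, 16L), nLabels = 5L) {
  labels <- withr::with_seed(seed,
    array(sample(0:nLabels, prod(dims), replace = TRUE), dim = dims))
  storage.mode(labels) <- "integer"
  new("AtlasVolume", name = "random", labels = labels,
      voxelSize = c(25, 25, 25), midlineAxis = 1L,
      midlineCoord = (dims[1] - 1) / 2,
      hierarchy = flatHierarchy(seq_len(nLabels)))
}

randomAnchoring <- function(dims = c(16, 16, 16), width = 10L, height = 8L,
                            sectionNr = 0L) {
  # random plane through the volume's interior; u, v independent w.h.p.
  repeat {
    o <- runif(3, -2, dims - 1 + 2)
    u <- runif(3, -1, 1) * dims
    v <- runif(3, -1, 1) * dims
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    if (sqrt(sum(cr^2)) > 1e-6) break
  }
  anchoring(o, u, v, width, height, sectionNr)
}

# brute-force per-pixel slicer: cut-plane formula + round-half-away lookup
oracleSliceAtlas <- function(atlas, a) {
  d <- dim(atlas@labels)
  out <- matrix(0L, a@height, a@width)
  rha <- function(x) sign(x) * floor(abs(x) + 0.5)
  for (y in 0:(a@height - 1)) {
    for (x in 0:(a@width - 1)) {
      p <- a@o + a@u * x / (a@width - 1) + a@v * y / (a@height - 1)
      i <- rha(p) + 1
      if (all(i >= 1) && all(i <= d))
        out[y + 1, x + 1] <- atlas@labels[i[1], i[2], i[3]]
    }
  }
  out
}

# per-triangle affine warp oracle: solve each target triangle's affine map to
# its source triangle, locate the query by signed areas, apply the map
oracleWarpLookup <- function(w, x, y) {
  m <- w@markers
  tri <- w@triangles
  signedArea <- function(ax, ay, bx, by, cx, cy)
    0.5 * ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  out <- matrix(NA_real_, length(x), 2)
  for (q in seq_along(x)) {
    for (t in seq_len(nrow(tri))) {
      tr <- tri[t, ]
      A <- signedArea(m[tr[1], 1], m[tr[1], 2], m[tr[2], 1], m[tr[2], 2],
                      m[tr[3], 1], m[tr[3], 2])
      a1 <- signedArea(x[q], y[q], m[tr[2], 1], m[tr[2], 2],
                       m[tr[3], 1], m[tr[3], 2]) / A
      a2 <- signedArea(m[tr[1], 1], m[tr[1], 2], x[q], y[q],
                       m[tr[3], 1], m[tr[3], 2]) / A
      a3 <- signedArea(m[tr[1], 1], m[tr[1], 2], m[tr[2], 1], m[tr[2], 2],
                       x[q], y[q]) / A
      if (a1 >= -1e-9 && a2 >= -1e-9 && a3 >= -1e-9) {
        # affine map via the 3 vertex correspondences
        Tm <- rbind(c(m[tr[1], 1], m[tr[1], 2], 1),
                    c(m[tr[2], 1], m[tr[2], 2], 1),
                    c(m[tr[3], 1], m[tr[3], 2], 1))
        coef <- solve(Tm, m[tr, 3:4])
        out[q, ] <- c(x[q], y[q], 1) %*% coef
        break
      }
    }
  }
  out
}

# well-separated random in-image markers with bounded displacements
randomMarkers <- function(n, width, height, maxShift = 2) {
  repeat {
    tx <- runif(n, 0.15 * (width - 1), 0.85 * (width - 1))
    ty <- runif(n, 0.15 * (height - 1), 0.85 * (height - 1))
    if (n < 2 || min(dist(cbind(tx, ty))) > 1) break
  }
  cbind(tx, ty, tx + runif(n, -maxShift, maxShift),
        ty + runif(n, -maxShift, maxShift))
}

# three-level test tree: 1 root; 2,3 mid; leaves 4..7 under 2, 8,9 under 3
threeLevelTree <- function() {
  data.frame(
    id = 1:9,
    name = c("root", "midA", "midB", paste0("leaf", 4:9)),
    parent_id = c(NA, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L),
    r = 1L, g = 2L, b = 3L, stringsAsFactors = FALSE)
}
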