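test_that("band schema derives half-open, non-overlapping edges", {
  sc <- band_schema()
  expect_equal(sc$low, sc$midpoints_hz - 0.04)
  expect_equal(sc$high, sc$midpoints_hz + 0.04)
  expect_error(band_schema(c(0.2, 0.1)), "increasing")
  expect_error(band_schema(c(0.04, 0.08)), "overlap")
})

test_that("band powers match an independent brute-force DFT oracle", {
  set.seed(42)
  for (T in c(128, 257, 512)) {
    x <- rnorm(T) + 0.3 * seq_len(T)
    got <- band_powers(x, tr_seconds = 0.5)
    want <- oracle_band_powers(x, tr = 0.5)
    expect_lt(max(abs(got - want) / pmax(want, 1e-12)), 1e-10)
  }
})

test_that("a constant series has zero power in every bin", {
  expect_equal(band_powers(rep(3.7, 64), 0.5), rep(0, 8), tolerance = 1e-20)
})

test_that("a pure tone concentrates its power in the right bin", {
  T <- 512; tr <- 0.5
  # tone on the DFT grid at the ordinate nearest 0.12 Hz -> bin 2
  k <- round(0.12 * T * tr)
  x <- sin(2 * pi * k * seq_len(T) / T)
  bp <- band_powers(x, tr)
  expect_gt(bp[2] / sum(bp), 0.999)
  # off-grid 0.12 Hz tone: spectral leakage, but bin 2 still dominates
  x2 <- sin(2 * pi * 0.12 * seq_len(T) * tr)
  bp2 <- band_powers(x2, tr)
  expect_gt(bp2[2] / sum(bp2), 0.95)
  expect_equal(which.max(bp2), 2L)
})

test_that("the one-sided periodogram satisfies Parseval's identity", {
  set.seed(7)
  for (T in c(500, 1024)) {
    x <- rnorm(T)
    pg <- rsfCBF:::periodogram_onesided(x, 0.5)
    detr <- stats::lm.fit(cbind(1, seq_len(T)), x)$residuals
    expect_lt(abs(sum(pg$power) - sum(detr^2)) / sum(detr^2), 1e-6)
  }
})

test_that("band powers are trend-invariant and scale quadratically", {
  set.seed(8)
  x <- rnorm(200)
  base <- band_powers(x, 0.5)
  shifted <- band_powers(x + 5 - 0.1 * seq_len(200), 0.5)
  expect_equal(shifted, base, tolerance = 1e-8)
  expect_equal(band_powers(3 * x, 0.5), 9 * base, tolerance = 1e-10)
})

test_that("Nyquist handling: error without allow_partial, zero-fill with", {
  x <- rnorm(240)
  expect_error(band_powers(x, tr_seconds = 0.8), "allow_partial")
  bp <- band_powers(x, tr_seconds = 0.8, allow_partial = TRUE)
  expect_true(all(bp >= 0))
  expect_match(attr(bp, "partial_bins"), "bin8")
  # tr so long that whole bins sit above Nyquist: those bins are zero
  bp2 <- band_powers(rnorm(128), tr_seconds = 2, allow_partial = TRUE)
  expect_equal(bp2[5:8], rep(0, 4))
  expect_error(band_powers(rnorm(8), 0.5), "T >= 16")
})

test_that("feature extraction matches per-voxel brute force with neighbours", {
  set.seed(13)
  d <- c(3, 3, 3); T <- 64; tr <- 0.5
  freqs <- seq(0.05, 0.6, length.out = 27)
  bold_a <- array(0, c(d, T))
  for (i in 1:27) {
    ix <- arrayInd(i, d)
    bold_a[ix[1], ix[2], ix[3], ] <-
      sin(2 * pi * freqs[i] * seq_len(T) * tr) + rnorm(T, sd = 0.1)
  }
  bold <- vol4d(bold_a, tr_seconds = tr)
  mask <- vol3d(array(1, d))
  occ <- vol3d(array(runif(27), d))
  ft <- extract_features(bold, mask, occ, mode = "pva_corrected")
  expect_identical(dim(ft$features), c(27L, 57L))

  offs <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  for (row in c(1L, 14L, 27L)) {
    vi <- ft$voxel_index[row, ]
    own <- oracle_band_powers(bold_a[vi[1], vi[2], vi[3], ], tr)
    expect_equal(unname(ft$features[row, 1:8]), own, tolerance = 1e-10)
    for (j in seq_along(offs)) {
      nb <- vi + offs[[j]]
      want <- if (all(nb >= 1) && all(nb <= 3))
        oracle_band_powers(bold_a[nb[1], nb[2], nb[3], ], tr) else own
      expect_equal(unname(ft$features[row, 8 * j + 1:8]), want,
                   tolerance = 1e-10)
    }
    expect_equal(unname(ft$features[row, 57]), occ$data[vi[1], vi[2], vi[3]])
  }
})

test_that("identical time series everywhere give identical spectral rows", {
  T <- 64
  x <- sin(2 * pi * 0.2 * seq_len(T) * 0.5)
  bold <- vol4d(array(rep(x, each = 8), c(2, 2, 2, T)), tr_seconds = 0.5)
  mask <- vol3d(array(1, c(2, 2, 2)))
  ft <- extract_features(bold, mask, NULL, mode = "original")
  expect_equal(apply(ft$features[, 1:56], 2, function(col)
    max(col) - min(col)), rep(0, 56), ignore_attr = TRUE)
})

test_that("a lone in-mask voxel replicates its own bands for neighbours", {
  set.seed(3)
  d <- c(3, 3, 3)
  bold <- vol4d(array(rnorm(27 * 64), c(d, 64)), tr_seconds = 0.5)
  mask_a <- array(0, d); mask_a[2, 2, 2] <- 1
  ft <- extract_features(bold, vol3d(mask_a), NULL, mode = "original")
  expect_identical(nrow(ft$features), 1L)
  own <- ft$features[1, 1:8]
  for (j in 1:6)
    expect_equal(unname(ft$features[1, 8 * j + 1:8]), unname(own))
  # zero-fill policy instead
  ft0 <- extract_features(bold, vol3d(mask_a), NULL, mode = "original",
                          neighbor_policy = "zero")
  expect_equal(unname(ft0$features[1, 9:56]), rep(0, 48))
})

test_that("original and corrected features differ only in the occupancy column", {
  set.seed(4)
  d <- c(4, 4, 3)
  bold <- vol4d(array(rnorm(prod(d) * 64), c(d, 64)), tr_seconds = 0.5)
  mask <- vol3d(array(1, d))
  occ <- vol3d(array(runif(prod(d)), d))
  fc <- extract_features(bold, mask, occ, mode = "pva_corrected")
  fo <- extract_features(bold, mask, occ, mode = "original")
  expect_identical(fc$features[, 1:56], fo$features[, 1:56])
  expect_equal(unname(fo$features[, 57]), rep(0, prod(d)))
  expect_equal(fc$features[, 57], occ$data[which(mask$data != 0)],
               ignore_attr = TRUE)
  # mode switching reproduces extraction, both ways
  expect_equal(set_feature_mode(fc, "original"), fo)
  expect_equal(set_feature_mode(fo, "pva_corrected", occupancy = occ), fc)
  # determinism: re-extraction is bit-identical
  expect_identical(fc$features,
                   extract_features(bold, mask, occ,
                                    mode = "pva_corrected")$features)
})

test_that("occupancy preparation preserves constants, bounds and mass", {
  const <- vol3d(array(0.7, c(20, 20, 20)), voxel_size_mm = c(1, 1, 1))
  sm <- prepare_occupancy(const)
  expect_equal(dim(sm$data), c(10, 10, 10))
  expect_equal(range(sm$data), c(0.7, 0.7), tolerance = 1e-12)
  expect_equal(sm$voxel_size_mm, c(2, 2, 2))

  # ribbon away from the edges: mass conserved within 1%
  a <- array(0, c(40, 40, 40))
  r <- sqrt((slice.index(a, 1) - 20.5)^2 + (slice.index(a, 2) - 20.5)^2 +
              (slice.index(a, 3) - 20.5)^2)
  a[r > 10 & r < 14] <- 0.9
  occ <- vol3d(a, voxel_size_mm = c(1, 1, 1))
  sm2 <- prepare_occupancy(occ)
  expect_true(all(sm2$data >= 0 & sm2$data <= 1))
  expect_lt(abs(sum(sm2$data) * 8 - sum(a)) / sum(a), 0.01)

  expect_error(prepare_occupancy(vol3d(array(0.5, c(3, 3, 3)),
                                       voxel_size_mm = c(1, 1, 1)),
                                 target_mm = 10),
               "coarser")
  expect_error(prepare_occupancy(vol3d(array(1.5, c(4, 4, 4)) - 0.2)),
               "outside")
})
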