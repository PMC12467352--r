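test_that("regional averaging matches hand-computed means", {
  at <- toy_atlas()
  # constant map: every region equals the constant
  const <- toy_map(rep(42, 32))
  rt <- regionalize(const, at)
  expect_equal(rt$mean, c(42, 42))

  # regionA voxels (labels 1 and 3): {1, 2, 3, 3}; regionB: {3, 3, 1, 2}
  a <- array(0, c(4, 4, 2))
  a[1, 1, 1] <- 1; a[2, 1, 1] <- 2; a[3, 1, 1] <- 3; a[4, 1, 1] <- 3
  a[1, 2, 1] <- 3; a[2, 2, 1] <- 3; a[1, 3, 1] <- 1; a[3, 2, 1] <- 2
  m <- vol3d(a)
  rt2 <- regionalize(m, at)
  expect_equal(rt2$mean[rt2$region == "regionA"], mean(c(1, 2, 3, 3)))
  expect_equal(rt2$mean[rt2$region == "regionB"], mean(c(3, 3, 1, 2)))

  # empty region is reported by name
  msk <- array(1, c(4, 4, 2)); msk[at$labels == 4L] <- 0
  msk[at$labels == 2L] <- 0
  expect_error(regionalize(m, at, vol3d(msk)), "regionB")
})

test_that("bilateral pooling is the voxel-count-weighted hemisphere mean", {
  ph <- default_phantom()
  set.seed(31)
  m <- vol3d(array(rnorm(prod(ph$spec$shape), 50, 10), ph$spec$shape))
  bi <- regionalize(m, ph$atlas, ph$mask, bilateral = TRUE)
  uni <- regionalize(m, ph$atlas, ph$mask, bilateral = FALSE)
  for (rg in bi$region) {
    u <- uni[uni$region == rg, ]
    expect_equal(bi$mean[bi$region == rg],
                 sum(u$mean * u$n_voxels) / sum(u$n_voxels))
  }
  expect_identical(nrow(uni), 2L * nrow(bi))
})

test_that("regionalization is linear in the input map", {
  ph <- default_phantom()
  set.seed(32)
  A <- vol3d(array(rnorm(prod(ph$spec$shape)), ph$spec$shape))
  B <- vol3d(array(rnorm(prod(ph$spec$shape)), ph$spec$shape))
  combo <- vol3d(2 * A$data - 3 * B$data)
  expect_equal(regionalize(combo, ph$atlas, ph$mask)$mean,
               2 * regionalize(A, ph$atlas, ph$mask)$mean -
                 3 * regionalize(B, ph$atlas, ph$mask)$mean)
})

test_that("predicted-vs-measured correlation behaves across subjects", {
  rg <- paste0("r", 1:5)
  set.seed(33)
  meas <- matrix(rnorm(200 * 5, 50, 8), 200, 5,
                 dimnames = list(paste0("s", 1:200), rg))
  # identical tables: r = 1 everywhere
  out <- predicted_vs_measured(meas, meas)
  expect_equal(out$r, rep(1, 5))

  # bivariate normal with rho = 0.5: estimate inside the 95% CI of 0.5
  rho <- 0.5
  pred <- rho * scale(meas) + sqrt(1 - rho^2) * matrix(rnorm(1000), 200, 5)
  dimnames(pred) <- dimnames(meas)
  out2 <- predicted_vs_measured(pred, meas)
  ci_half <- 1.96 / sqrt(200 - 3)          # Fisher-z CI half-width
  expect_true(all(abs(atanh(out2$r) - atanh(rho)) < ci_half + 0.15))
  # p from the exact t-transform
  ct <- cor.test(pred[, 1], meas[, 1])
  expect_equal(out2$p[1], ct$p.value)

  # whole-brain row comes first when supplied
  out3 <- predicted_vs_measured(pred, meas, pred[, 1], meas[, 1])
  expect_identical(out3$region[1], "whole_brain")
  expect_error(predicted_vs_measured(meas[1:3, ], meas[1:3, ]), "at least 4")
})

test_that("Fisher r-to-z difference matches its closed form and symmetry", {
  # whole-brain comparison at n = 100 per arm
  fz <- fisher_z_difference(0.68, 100, 0.50, 100)
  expect_equal(round(fz$Z, 2), 1.95)
  expect_equal(round(fz$p, 2), 0.05)

  fz2 <- fisher_z_difference(0.41, 100, 0.13, 100)
  expect_equal(round(fz2$Z, 2), 2.12)

  # antisymmetry and zero at equality
  a <- fisher_z_difference(0.3, 40, 0.6, 60)
  b <- fisher_z_difference(0.6, 60, 0.3, 40)
  expect_equal(a$Z, -b$Z)
  expect_equal(a$p, b$p)
  eq <- fisher_z_difference(0.42, 50, 0.42, 50)
  expect_equal(eq$Z, 0)
  expect_equal(eq$p, 1)
  expect_error(fisher_z_difference(1, 10, 0.5, 10), "infinite")
  expect_error(fisher_z_difference(0.5, 3, 0.5, 10), "n > 3")
})

test_that("Bonferroni flags match threshold counting and are monotone", {
  expect_length(bonferroni_mask(numeric(0)), 0L)
  p <- c(0.001, 0.0015, 0.00146, 0.2)
  fl <- bonferroni_mask(p)
  expect_equal(attr(fl, "threshold"), 0.05 / 34)
  expect_equal(as.logical(fl), p < 0.05 / 34)
  # monotone in alpha
  for (al in c(0.01, 0.05, 0.1, 0.5)) {
    lo <- bonferroni_mask(p, alpha = al)
    hi <- bonferroni_mask(p, alpha = al * 2)
    expect_true(all(hi | !lo))
  }
  expect_error(bonferroni_mask(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("model comparison table is consistent with the pairwise form", {
  r_o <- c(a = 0.1, b = 0.3)
  r_c <- c(a = 0.5, b = 0.3)
  cmp <- compare_models(r_o, r_c, n = 50)
  expect_identical(cmp$region, c("a", "b"))
  fz <- fisher_z_difference(0.5, 50, 0.1, 50)
  expect_equal(cmp$Z[1], fz$Z)
  expect_equal(cmp$Z[2], 0)
})
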