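# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Default ribbon phantom, memoised (deterministic given its spec).
default_phantom <- function() {
  if (is.null(.fixture_env$phantom))
    .fixture_env$phantom <- make_phantom(phantom_spec(seed = 1L))
  .fixture_env$phantom
}

# A tiny two-region bilateral atlas on a 4x4x2 grid.
toy_atlas <- function() {
  lab <- array(0L, c(4, 4, 2))
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L       # regionA L
  lab[3, 1, 1] <- 3L; lab[4, 1, 1] <- 3L       # regionA R
  lab[1, 2, 1] <- 2L; lab[2, 2, 1] <- 2L; lab[1, 3, 1] <- 2L  # regionB L
  lab[3, 2, 1] <- 4L                            # regionB R
  lut <- data.frame(label = 1:4,
                    region_name = c("regionA", "regionB",
                                    "regionA", "regionB"),
                    hemisphere = c("L", "L", "R", "R"),
                    stringsAsFactors = FALSE)
  label_atlas(lab, lut, voxel_size_mm = c(2, 2, 2))
}

toy_map <- function(values) {
  a <- array(0, c(4, 4, 2))
  a[seq_along(values)] <- values
  vol3d(a, voxel_size_mm = c(2, 2, 2))
}

# Independent brute-force band-power oracle: direct DFT sums, no shared
# code with the package implementation.
oracle_band_powers <- function(x, tr, mid = c(0.04, 0.12, 0.20, 0.28,
                                              0.36, 0.44, 0.52, 0.60),
                               width = 0.08) {
  n <- length(x)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), x)
  x <- fit$residuals
  kmax <- floor(n / 2)
  pows <- vapply(seq_len(kmax), function(k) {
    re <- sum(x * cos(2 * pi * k * tt / n))
    im <- sum(x * sin(2 * pi * k * tt / n))
    w <- if (n %% 2 == 0 && k == kmax) 1 else 2
    w * (re^2 + im^2) / n
  }, 0)
  freqs <- seq_len(kmax) / (n * tr)
  vapply(seq_along(mid), function(i) {
    lo <- mid[i] - width / 2
    hi <- mid[i] + width / 2
    sum(pows[freqs >= lo - 1e-12 & freqs < hi - 1e-12])
  }, 0)
}

# Regional means of a map on the default phantom, as a named vector.
phantom_region_means <- function(map, phantom = default_phantom()) {
  rt <- regionalize(map, phantom$atlas, phantom$mask)
  stats::setNames(rt$mean, rt$region)
}

# Subjects x regions matrix of measured regional CBF for a cohort.
cohort_region_matrix <- function(cohort, what = "measured_cbf",
                                 phantom = default_phantom()) {
  t(vapply(cohort$subjects,
           function(s) phantom_region_means(s[[what]], phantom),
           phantom_region_means(cohort$subjects[[1]][[what]], phantom)))
}

# Predictions in target units from a raw feature matrix.
predict_cbf_matrix_for_test <- function(model, x) {
  rsfCBF:::predict_cbf_matrix(model, x)
}
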