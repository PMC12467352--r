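#' Phantom specification
#'
#' Describes the cortical-ribbon phantom: an ellipsoidal shell inside a
#' small grid, with gray-matter occupancy peaking mid-ribbon and decaying
#' to 0 at its edges, partitioned into K bilateral parcels by hemisphere
#' and angular sector.
#'
#' @param shape grid dimensions (voxels).
#' @param voxel_size_mm voxel size.
#' @param ribbon_halfwidth ribbon half-thickness, as a fraction of the
#'   ellipsoid radius (0.25 gives a shell roughly 2 voxels thick on the
#'   long axes).
#' @param thickness_mod relative amplitude of the angular (region-wise)
#'   modulation of ribbon thickness, emulating regional cortical-thickness
#'   variation; this is what makes the partial-volume artifact differ by
#'   region.
#' @param n_parcels number of bilateral parcel pairs.
#' @param seed seed for the phantom's latent band-power template.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(24, 24, 12), voxel_size_mm = c(2, 2, 2),
                         ribbon_halfwidth = 0.25, thickness_mod = 0.35,
                         n_parcels = 8, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L), ribbon_halfwidth > 0,
            thickness_mod >= 0, thickness_mod < 1, n_parcels >= 2L)
  structure(list(shape = as.integer(shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 ribbon_halfwidth = ribbon_halfwidth,
                 thickness_mod = thickness_mod,
                 n_parcels = as.integer(n_parcels),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generative model parameters
#'
#' Parameters of the forward model linking latent voxel band powers to
#' gray-matter CBF and to the measured (partial-volume-mixed) CBF:
#' `true_gm_cbf = a0 + alpha * sum_b a_b L_b(v)` with `a0`/`alpha`
#' calibrated on the phantom template so the in-ribbon population has mean
#' `gm_cbf_mean` and SD `gm_cbf_sd`, and
#' `measured = occ * true_gm_cbf + (1 - occ) * wm_cbf + noise`.
#' Between-subject regional variability and any case-control effect are
#' injected multiplicatively into the band-power fields, so group
#' differences are carried by the rsfMRI features as well as by CBF.
#'
#' @param band_weights length-8 weights `a_b` linking band powers to CBF
#'   (stronger coupling at low frequencies).
#' @param band_mu mean latent power per band (1/f-like decay).
#' @param gm_cbf_mean,gm_cbf_sd population mean/SD of gray-matter CBF
#'   (mL/100g/min).
#' @param wm_cbf white-matter CBF entering the mixing model.
#' @param noise_sd measurement noise SD as a fraction of `gm_cbf_sd`.
#' @param subject_sd between-subject SD of regional CBF (mL/100g/min);
#'   also the reference SD in which `effect_map` d-values are expressed.
#' @param latent_jitter_sd SD of the subject-specific log-scale smooth
#'   modulation of the latent fields.
#' @param band_jitter_sd SD of the subject-specific per-band log jitter.
#' @param occ_jitter_sd SD of the subject-specific log occupancy exponent
#'   (anatomical thickness variation).
#' @param broadband_frac broadband (white) noise floor in the synthetic
#'   BOLD series, as a fraction of total injected band power.
#' @param effect_map named numeric vector (region -> Cohen's d units)
#'   applied to cases; negative values lower case CBF.
#' @param tr_seconds,n_timepoints BOLD sampling.
#' @param smooth_vox Gaussian smoothing (voxels) of the latent fields, so
#'   neighbouring voxels carry correlated signal.
#' @return an object of class `"generative_params"`.
#' @export
generative_params <- function(band_weights = c(1, 0.9, 0.75, 0.6,
                                               0.45, 0.3, 0.2, 0.1),
                              band_mu = 40 * (c(1, 3, 5, 7, 9, 11, 13, 15))^-0.8,
                              gm_cbf_mean = 60, gm_cbf_sd = 12, wm_cbf = 20,
                              noise_sd = 0.2, subject_sd = 6,
                              latent_jitter_sd = 0.1, band_jitter_sd = 0.05,
                              occ_jitter_sd = 0.1, broadband_frac = 0.08,
                              effect_map = NULL, tr_seconds = 0.8,
                              n_timepoints = 240, smooth_vox = 3) {
  stopifnot(length(band_weights) == length(band_mu), noise_sd >= 0,
            wm_cbf >= 0, gm_cbf_sd > 0, n_timepoints >= 32, tr_seconds > 0)
  structure(list(band_weights = band_weights, band_mu = band_mu,
                 gm_cbf_mean = gm_cbf_mean, gm_cbf_sd = gm_cbf_sd,
                 wm_cbf = wm_cbf, noise_sd = noise_sd,
                 subject_sd = subject_sd,
                 latent_jitter_sd = latent_jitter_sd,
                 band_jitter_sd = band_jitter_sd,
                 occ_jitter_sd = occ_jitter_sd,
                 broadband_frac = broadband_frac,
                 effect_map = effect_map, tr_seconds = tr_seconds,
                 n_timepoints = as.integer(n_timepoints),
                 smooth_vox = smooth_vox),
            class = "generative_params")
}

#' Build the cortical-ribbon phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `mask` ([vol3d()], occupancy > 0.1), `occupancy`
#'   ([vol3d()]), `atlas` ([label_atlas()]), `spec`, and the internal
#'   normalized radius field.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  d <- spec$shape
  ctr <- (d + 1) / 2
  ax <- 0.38 * d
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r <- sqrt(((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
              ((g$z - ctr[3]) / ax[3])^2)
  # region-wise thickness variation (bilaterally symmetric in the angular
  # coordinate) so partial-volume depression differs across parcels
  ang0 <- atan2(g$z - ctr[3], g$y - ctr[2])
  w <- spec$ribbon_halfwidth * (1 + spec$thickness_mod * cos(ang0 - 0.7))
  # thin ribbon => sub-voxel gray matter => lower peak occupancy, the
  # mechanism behind the regional partial-volume artifact
  amp <- pmin(1, w / spec$ribbon_halfwidth)
  occ <- amp * pmax(0, 1 - ((r - 1) / w)^2)
  occ_a <- array(occ, d)
  mask_a <- array(occ > 0.1, d) * 1
  if (sum(mask_a) < 20L)
    stop("phantom shape too small for the requested ribbon thickness")

  K <- spec$n_parcels
  theta <- atan2(g$z - ctr[3], g$y - ctr[2])          # angular sector
  sector <- pmin(K, 1L + floor((theta + pi) / (2 * pi) * K))
  hemi_R <- g$x >= ctr[1]
  lab <- ifelse(mask_a > 0, sector + ifelse(hemi_R, K, 0L), 0L)
  lab_a <- array(as.integer(lab), d)
  lut <- data.frame(label = c(seq_len(K), K + seq_len(K)),
                    region_name = rep(sprintf("parcel_%02d", seq_len(K)), 2),
                    hemisphere = rep(c("L", "R"), each = K),
                    stringsAsFactors = FALSE)
  counts <- table(factor(lab_a[lab_a > 0], levels = lut$label))
  if (any(counts == 0))
    stop("phantom parcel(s) received no voxels; enlarge the grid")
  sid <- default_space_id(spec$voxel_size_mm)
  list(mask = vol3d(mask_a, spec$voxel_size_mm, space_id = sid),
       occupancy = vol3d(occ_a, spec$voxel_size_mm, space_id = sid),
       atlas = label_atlas(lab_a, lut, spec$voxel_size_mm, space_id = sid),
       spec = spec, radius = array(r, d))
}

# Latent band-power template shared by all subjects drawn on one phantom:
# per band, a smoothed log-normal field with mean band_mu[b]; plus the
# CBF calibration (alpha, a0) and per-region template means used to
# translate regional CBF shifts into band-power scale factors.
phantom_template <- function(phantom, params) {
  d <- phantom$spec$shape
  nb <- length(params$band_mu)
  nvox <- prod(d)
  L <- with_seed(substream_seed(phantom$spec$seed, "template"), {
    out <- matrix(0, nvox, nb)
    for (b in seq_len(nb)) {
      f <- gaussian_smooth3d(array(stats::rnorm(nvox), d), params$smooth_vox)
      f <- (f - mean(f)) / stats::sd(f) * 0.4
      out[, b] <- params$band_mu[b] * exp(f - 0.4^2 / 2)
    }
    out
  })
  s <- as.numeric(L %*% params$band_weights)
  inmask <- phantom$mask$data != 0
  alpha <- params$gm_cbf_sd / stats::sd(s[inmask])
  a0 <- params$gm_cbf_mean - alpha * mean(s[inmask])
  lut <- phantom$atlas$lut
  regvox <- split(which(inmask),
                  lut$region_name[match(phantom$atlas$labels[inmask],
                                        lut$label)])
  region_mean_s <- vapply(regvox, function(ix) mean(s[ix]), 0)
  list(L = L, s = s, alpha = alpha, a0 = a0,
       region_mean_s = region_mean_s, region_voxels = regvox)
}

# Synthesize T x nvox BOLD series whose one-sided band powers equal the
# columns of P (nvox x nb): random cos/sin amplitudes on the DFT grid
# inside each bin, rescaled per voxel so each bin's periodogram sum hits
# its target exactly, plus a white broadband floor.
synth_bold_matrix <- function(P, tr, Tn, schema, broadband_sd) {
  nvox <- nrow(P)
  kmax <- floor(Tn / 2)
  nyq <- 1 / (2 * tr)
  freq <- seq_len(kmax) / (Tn * tr)
  tt <- seq_len(Tn)
  X <- matrix(stats::rnorm(Tn * nvox, sd = broadband_sd), Tn, nvox)
  for (b in seq_along(schema$low)) {
    sel <- which(freq >= schema$low[b] - 1e-12 &
                   freq < schema$high[b] - 1e-12 & seq_len(kmax) < Tn / 2)
    if (!length(sel)) next
    nk <- length(sel)
    A <- matrix(stats::rnorm(nk * nvox), nk, nvox)
    B <- matrix(stats::rnorm(nk * nvox), nk, nvox)
    # one-sided periodogram power of A cos + B sin at an exact DFT
    # frequency is T (A^2 + B^2) / 2; scale so the bin sums to P[, b]
    cur <- Tn * (colSums(A^2) + colSums(B^2)) / 2
    sc <- sqrt(pmax(P[, b], 0) / pmax(cur, .Machine$double.eps))
    A <- sweep(A, 2, sc, "*"); B <- sweep(B, 2, sc, "*")
    ang <- 2 * pi * outer(tt, sel) / Tn      # k-th DFT harmonic
    Bc <- cos(ang)
    Bs <- sin(ang)
    X <- X + Bc %*% A + Bs %*% B
  }
  X
}

#' Simulate one synthetic subject
#'
#' Draws a subject on the phantom: subject-modulated latent band-power
#' fields, the BOLD-like time series they generate, the true gray-matter
#' CBF implied by the power-to-CBF link, a subject-specific occupancy map
#' (thickness jitter), and the measured CBF from the forward
#' partial-volume mixing model
#' `measured = occ * true + (1 - occ) * wm_cbf + noise`
#' (exact when `noise_sd = 0`). Cases additionally receive the regional
#' effect map: region r of a case is shifted by
#' `effect_map[r] * subject_sd` mL/100g/min, injected into the band-power
#' fields so the shift is visible to the rsfMRI features.
#'
#' @param phantom from [make_phantom()].
#' @param params a [generative_params()].
#' @param group `"control"` or `"case"`.
#' @param seed subject seed.
#' @param template optional precomputed template (from an internal cache;
#'   recomputed deterministically from the phantom seed when `NULL`).
#' @param with_bold generate the BOLD series (skip for CBF-only cohorts).
#' @param occupancy_power extra exponent applied to the occupancy map
#'   (values > 1 thin the ribbon; used to probe the partial-volume
#'   artifact).
#' @return an object of class `"synthetic_subject"`: list with `bold`
#'   (or `NULL`), `occupancy`, `true_gm_cbf`, `measured_cbf`, `group`,
#'   `seed`.
#' @export
simulate_subject <- function(phantom, params = generative_params(),
                             group = c("control", "case"), seed = 1L,
                             template = NULL, with_bold = TRUE,
                             occupancy_power = 1) {
  group <- match.arg(group)
  if (is.null(template)) template <- phantom_template(phantom, params)
  d <- phantom$spec$shape
  nvox <- prod(d)
  nb <- length(params$band_mu)
  schema <- band_schema()
  if (nb != length(schema$midpoints_hz))
    schema <- band_schema(midpoints_hz = seq(0.04, by = 0.08,
                                             length.out = nb))

  sub <- with_seed(seed, {
    jit <- gaussian_smooth3d(array(stats::rnorm(nvox), d), params$smooth_vox)
    jit <- (jit - mean(jit)) / stats::sd(jit) * params$latent_jitter_sd
    bandjit <- exp(stats::rnorm(nb, 0, params$band_jitter_sd))
    u <- stats::rnorm(length(template$region_mean_s), 0, params$subject_sd)
    names(u) <- names(template$region_mean_s)
    kappa <- exp(stats::rnorm(1, 0, params$occ_jitter_sd))
    noise <- stats::rnorm(nvox)
    list(jit = jit, bandjit = bandjit, u = u, kappa = kappa, noise = noise)
  })

  L <- template$L * exp(as.numeric(sub$jit) - params$latent_jitter_sd^2 / 2)
  L <- sweep(L, 2, sub$bandjit, "*")

  shift <- sub$u
  if (group == "case" && !is.null(params$effect_map)) {
    em <- params$effect_map
    hit <- intersect(names(em), names(shift))
    shift[hit] <- shift[hit] + em[hit] * params$subject_sd
  }
  f_r <- pmax(1 + shift /
                (template$alpha * template$region_mean_s[names(shift)]),
              0.1)
  fvox <- rep(1, nvox)
  for (rg in names(f_r)) fvox[template$region_voxels[[rg]]] <- f_r[[rg]]
  L <- L * fvox

  s <- as.numeric(L %*% params$band_weights)
  true_cbf <- template$a0 + template$alpha * s
  inmask <- phantom$mask$data != 0
  if (mean(true_cbf[inmask] < 0) > 0.01)
    stop("parameters produce negative CBF in more than 1% of ribbon voxels")

  occ <- phantom$occupancy$data ^ (sub$kappa * occupancy_power)
  occ[phantom$occupancy$data == 0] <- 0
  noise_abs <- params$noise_sd * params$gm_cbf_sd
  measured <- occ * true_cbf + (1 - occ) * params$wm_cbf +
    noise_abs * sub$noise

  sid <- phantom$mask$space_id
  bold <- NULL
  if (with_bold) {
    bb_sd <- sqrt(params$broadband_frac * sum(params$band_mu) /
                    params$n_timepoints)
    Xb <- with_seed(substream_seed(seed, "bold"),
                    synth_bold_matrix(L, params$tr_seconds,
                                      params$n_timepoints, schema, bb_sd))
    bold <- vol4d(array(t(Xb), c(d, params$n_timepoints)),
                  phantom$spec$voxel_size_mm,
                  tr_seconds = params$tr_seconds, space_id = sid)
  }
  structure(list(bold = bold,
                 occupancy = vol3d(occ, phantom$spec$voxel_size_mm,
                                   space_id = sid),
                 true_gm_cbf = vol3d(array(true_cbf, d),
                                     phantom$spec$voxel_size_mm,
                                     space_id = sid),
                 measured_cbf = vol3d(array(measured, d),
                                      phantom$spec$voxel_size_mm,
                                      space_id = sid),
                 latent_powers = L,
                 group = group, seed = seed),
            class = "synthetic_subject")
}

#' Simulate a two-group cohort
#'
#' Independent subjects with per-subject seeds derived from one master
#' seed; ages and sexes are drawn from overlapping distributions in both
#' groups so that balanced train/test splitting is exercisable.
#'
#' @param n_case,n_control group sizes (>= 2 each... or >= 1 for pure
#'   phantom work).
#' @param phantom from [make_phantom()].
#' @param params a [generative_params()].
#' @param seed master seed.
#' @param with_bold generate BOLD series (see [simulate_subject()]).
#' @return list with `subjects` (named list of `synthetic_subject`),
#'   `manifest` (data frame `subject_id`, `age`, `sex`, `group`),
#'   `phantom`.
#' @export
simulate_cohort <- function(n_case, n_control, phantom = make_phantom(),
                            params = generative_params(), seed = 1L,
                            with_bold = TRUE) {
  stopifnot(n_case >= 0L, n_control >= 2L, n_case + n_control >= 2L)
  template <- phantom_template(phantom, params)
  groups <- c(rep("case", n_case), rep("control", n_control))
  ids <- sprintf("sub-%03d", seq_along(groups))
  demo <- with_seed(substream_seed(seed, "demographics"), {
    data.frame(subject_id = ids,
               age = round(pmin(90, pmax(18, stats::rnorm(length(ids), 45, 15))), 1),
               sex = sample(c("M", "F"), length(ids), replace = TRUE),
               group = groups, stringsAsFactors = FALSE)
  })
  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  for (i in seq_along(ids)) {
    subjects[[i]] <- simulate_subject(
      phantom, params, group = groups[i],
      seed = substream_seed(seed, paste0("subject:", ids[i])),
      template = template, with_bold = with_bold)
  }
  list(subjects = subjects, manifest = demo, phantom = phantom)
}
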