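#' Per-region case-control effect sizes
#'
#' For each region, Cohen's d with the pooled standard deviation,
#' `d = (mean_case - mean_control) / s_pooled`,
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`,
#' together with the Student (pooled-variance) t statistic and its
#' two-tailed p-value. Negative d means lower CBF in cases
#' (hypoperfusion). Welch's unequal-variance t is available via
#' `welch = TRUE`; no covariate adjustment is applied unless `covariates`
#' residualization is requested.
#'
#' @param cases subjects x regions matrix of regional values for cases.
#' @param controls same, for controls (same region columns).
#' @param welch use Welch's t instead of Student's t for the p-value.
#' @param covariates optional data frame (rows = all subjects, cases first
#'   then controls) whose columns are regressed out of every region before
#'   the comparison.
#' @param alpha,m Bonferroni parameters for the significance flag.
#' @return data frame `region`, `d`, `t`, `p`, `n_case`, `n_control`,
#'   `significant`.
#' @export
cohens_d_table <- function(cases, controls, welch = FALSE,
                           covariates = NULL, alpha = 0.05, m = NULL) {
  cases <- as.matrix(cases); controls <- as.matrix(controls)
  if (!identical(colnames(cases), colnames(controls)))
    stop("cases and controls must cover the same regions")
  n1 <- nrow(cases); n2 <- nrow(controls)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n1 + n2)
    all_v <- rbind(cases, controls)
    X <- stats::model.matrix(~ ., data = covariates)
    all_v <- stats::resid(stats::lm.fit(X, all_v)) +
      matrix(colMeans(all_v), n1 + n2, ncol(all_v), byrow = TRUE)
    cases <- all_v[seq_len(n1), , drop = FALSE]
    controls <- all_v[n1 + seq_len(n2), , drop = FALSE]
  }
  if (is.null(m)) m <- ncol(cases)
  rows <- lapply(colnames(cases), function(rg) {
    a <- cases[, rg]; b <- controls[, rg]
    sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                 (n1 + n2 - 2))
    if (sp == 0) stop("zero pooled SD for region ", rg)
    d <- (mean(a) - mean(b)) / sp
    tt <- stats::t.test(a, b, var.equal = !welch)
    data.frame(region = rg, d = d, t = unname(tt$statistic), p = tt$p.value,
               n_case = n1, n_control = n2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- as.logical(bonferroni_mask(out$p, alpha = alpha, m = m))
  rownames(out) <- NULL
  out
}

#' Cross-cohort / cross-modality effect-size agreement
#'
#' Pearson correlation of two cohorts' per-region effect sizes across the
#' shared regions, with a two-tailed p-value from the t-transform with
#' `#regions - 2` degrees of freedom. Invariant to affine rescaling of
#' either vector.
#'
#' @param table_a,table_b effect-size tables from [cohens_d_table()]
#'   (matched on `region`), or plain numeric vectors of equal length.
#' @return list with `r`, `p`, `n_regions`, and the paired `d` values.
#' @export
effect_size_agreement <- function(table_a, table_b) {
  if (is.data.frame(table_a)) {
    if (!setequal(table_a$region, table_b$region))
      stop("the two tables must cover the same regions")
    ord <- match(table_a$region, table_b$region)
    da <- table_a$d
    db <- table_b$d[ord]
    regions <- table_a$region
  } else {
    stopifnot(length(table_a) == length(table_b))
    da <- as.numeric(table_a); db <- as.numeric(table_b)
    regions <- names(table_a) %||% paste0("region_", seq_along(da))
  }
  if (length(da) < 4L) stop("need at least 4 regions")
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    stop("zero variance in an effect-size vector")
  ct <- stats::cor.test(da, db)
  list(r = unname(ct$estimate), p = ct$p.value, n_regions = length(da),
       pairs = data.frame(region = regions, d_a = da, d_b = db,
                          stringsAsFactors = FALSE))
}
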