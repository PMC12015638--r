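#' Estimate task > rest beta values by ordinary least squares
#'
#' Regresses each ROI's series on an intercept, a linear drift, and the
#' task regressor (the design, optionally convolved with the canonical
#' HRF); the beta is the regressor coefficient.
#'
#' @param ts An `fcg_timeseries`.
#' @param design Binary design vector of length T.
#' @param hrf Convolve the design with [canonical_hrf()] (default TRUE).
#' @return A tibble with columns `subject_id`, `roi_id`, `beta`.
#' @export
estimate_betas <- function(ts, design, hrf = TRUE) {
  stopifnot(inherits(ts, "fcg_timeseries"))
  design <- as.numeric(design)
  T_n <- ncol(ts$data)
  if (length(design) != T_n) {
    stop("design length does not match the series", call. = FALSE)
  }
  if (stats::var(design) == 0) stop("design is constant", call. = FALSE)
  reg <- if (hrf) hrf_regressor(design, ts$sampling_interval_s) else design
  X <- cbind(
    intercept = 1,
    drift = seq_len(T_n) - (T_n + 1) / 2,
    task = reg
  )
  fit <- stats::lm.fit(X, t(ts$data))
  betas <- fit$coefficients["task", ]
  tibble::tibble(
    subject_id = ts$subject_id,
    roi_id = rownames(ts$data) %||% sprintf("ROI%04d", seq_len(nrow(ts$data))),
    beta = unname(betas)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Loading scores of task activation on a reference gradient
#'
#' Per ROI, the loading is the beta value times the reference gradient
#' value; per network, the voxel-count-weighted mean of the ROI loadings.
#' A higher loading means the activation profile conforms more to the
#' gradient.
#'
#' @param betas A tibble with `roi_id` and `beta` (e.g. from
#'   [estimate_betas()]) or a named numeric vector.
#' @param gradient An `fcg_gradient` or numeric vector (reference gradient,
#'   parcellation order).
#' @param parcellation An `fcg_parcellation`.
#' @return A list with `roi` (tibble `roi_id`, `network`, `loading`) and
#'   `network` (tibble `network`, `value`).
#' @export
loading_scores <- function(betas, gradient, parcellation) {
  stopifnot(inherits(parcellation, "fcg_parcellation"))
  if (is.numeric(betas) && !is.null(names(betas))) {
    betas <- tibble::tibble(roi_id = names(betas), beta = unname(betas))
  }
  g <- principal_gradient(gradient)
  if (length(g) != nrow(parcellation)) {
    stop("gradient length does not match parcellation", call. = FALSE)
  }
  b <- betas$beta[match(parcellation$roi_id, betas$roi_id)]
  if (anyNA(b)) stop("betas missing for some parcellation ROIs", call. = FALSE)
  roi <- tibble::tibble(
    roi_id = parcellation$roi_id,
    network = parcellation$network,
    loading = b * g
  )
  net <- network_weighted_mean(roi, parcellation, value = "loading")
  list(roi = roi, network = net)
}

#' Correlation between activation and a gradient
#'
#' @param betas Numeric vector (e.g. group-mean betas) or tibble with
#'   `beta`, in parcellation order.
#' @param gradient An `fcg_gradient` or numeric vector.
#' @return A tibble with `r`, `p`, `n`.
#' @export
activation_gradient_correlation <- function(betas, gradient) {
  b <- if (is.data.frame(betas)) betas$beta else as.numeric(betas)
  gradient_similarity(b, gradient)
}

mean_betas_matrix <- function(betas_tbl) {
  wide <- tidyr::pivot_wider(
    betas_tbl[, c("subject_id", "roi_id", "beta")],
    names_from = "subject_id", values_from = "beta"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$roi_id
  m
}

#' Permutation test of group differences in activation-gradient coupling
#'
#' Statistic: `r(mean betas of A, g) - r(mean betas of B, g)`. The null is
#' generated by shuffling subject group labels; the two-sided p-value uses
#' the add-one rule `(1 + #{|dr*| >= |dr|}) / (1 + n_perm)`.
#'
#' @param betas A tibble with columns `subject_id`, `roi_id`, `beta` for
#'   all subjects of both groups.
#' @param groups Named character vector or tibble mapping `subject_id` to
#'   group; exactly two groups, each with at least 2 subjects.
#' @param gradient Reference gradient (`fcg_gradient` or numeric vector in
#'   the same ROI order as `betas`).
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param seed Optional seed for the permutations.
#' @return A list of class `fcg_perm`: `statistic` (observed delta r),
#'   `p.value`, `r_A`, `r_B`, `groups`, `n_perm`.
#' @export
group_coupling_permutation_test <- function(betas, groups, gradient,
                                            n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$subject_id)
  }
  B <- mean_betas_matrix(betas)
  grp <- groups[colnames(B)]
  if (anyNA(grp)) stop("group labels missing for some subjects", call. = FALSE)
  lv <- unique(grp)
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  if (min(table(grp)) < 2) stop("each group needs at least 2 subjects", call. = FALSE)
  g <- principal_gradient(gradient)
  stat <- function(labels) {
    stats::cor(rowMeans(B[, labels == lv[1], drop = FALSE]), g) -
      stats::cor(rowMeans(B[, labels == lv[2], drop = FALSE]), g)
  }
  obs <- stat(grp)
  perm <- function() {
    d <- numeric(n_perm)
    for (i in seq_len(n_perm)) d[i] <- stat(sample(grp))
    d
  }
  d <- if (is.null(seed)) perm() else with_local_seed(seed, perm())
  p <- (1 + sum(abs(d) >= abs(obs))) / (1 + n_perm)
  structure(
    list(
      statistic = obs, p.value = p,
      r_A = stats::cor(rowMeans(B[, grp == lv[1], drop = FALSE]), g),
      r_B = stats::cor(rowMeans(B[, grp == lv[2], drop = FALSE]), g),
      groups = lv, n_perm = n_perm, null_sd = stats::sd(d)
    ),
    class = "fcg_perm"
  )
}

#' Paired permutation test of gradient preference
#'
#' Tests whether an activation pattern correlates more with gradient `g1`
#' than with gradient `g2`: statistic `r(b, g1) - r(b, g2)`, null generated
#' by swapping `g1[i]` and `g2[i]` per ROI (sign-exchange of the paired
#' difference), two-sided add-one p-value.
#'
#' @param betas Mean beta vector (or tibble with `subject_id`, `roi_id`,
#'   `beta`, averaged over subjects).
#' @param g1,g2 Gradients (`fcg_gradient` or numeric vectors, same length).
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param seed Optional seed.
#' @return A list of class `fcg_perm` with `statistic` (delta r),
#'   `p.value`, `r_g1`, `r_g2`, `n_perm`.
#' @export
gradient_preference_test <- function(betas, g1, g2, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  b <- if (is.data.frame(betas)) {
    bm <- mean_betas_matrix(betas)
    rowMeans(bm)
  } else {
    as.numeric(betas)
  }
  v1 <- principal_gradient(g1)
  v2 <- principal_gradient(g2)
  if (length(v1) != length(v2) || length(v1) != length(b)) {
    stop("betas and gradients must share length", call. = FALSE)
  }
  obs <- stats::cor(b, v1) - stats::cor(b, v2)
  perm <- function() {
    d <- numeric(n_perm)
    R <- length(b)
    for (i in seq_len(n_perm)) {
      swap <- stats::runif(R) < 0.5
      a1 <- ifelse(swap, v2, v1)
      a2 <- ifelse(swap, v1, v2)
      d[i] <- stats::cor(b, a1) - stats::cor(b, a2)
    }
    d
  }
  d <- if (is.null(seed)) perm() else with_local_seed(seed, perm())
  p <- (1 + sum(abs(d) >= abs(obs))) / (1 + n_perm)
  structure(
    list(
      statistic = obs, p.value = p,
      r_g1 = stats::cor(b, v1), r_g2 = stats::cor(b, v2),
      n_perm = n_perm, null_sd = stats::sd(d)
    ),
    class = "fcg_perm"
  )
}

#' @export
print.fcg_perm <- function(x, ...) {
  cat(sprintf(
    "<fcg_perm> delta r = %.4f, p = %.4g (%d permutations)\n",
    x$statistic, x$p.value, x$n_perm
  ))
  invisible(x)
}
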