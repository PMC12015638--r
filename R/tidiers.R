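#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gradient into a long tibble
#'
#' @param x An `fcg_gradient`.
#' @param ... Unused.
#' @return A tibble with columns `roi_id`, `component`, `value`.
#' @exportS3Method generics::tidy
tidy.fcg_gradient <- function(x, ...) {
  comp <- x$components
  tibble::tibble(
    roi_id = rep(rownames(comp) %||% as.character(seq_len(nrow(comp))), ncol(comp)),
    component = rep(seq_len(ncol(comp)), each = nrow(comp)),
    value = as.vector(comp)
  )
}

#' One-row summary of a gradient
#'
#' @param x An `fcg_gradient`.
#' @param ... Unused.
#' @return A tibble with ROI count, component count, leading eigenvalues,
#'   window label and alignment target.
#' @exportS3Method generics::glance
glance.fcg_gradient <- function(x, ...) {
  tibble::tibble(
    n_roi = nrow(x$components),
    n_components = ncol(x$components),
    eigenvalue1 = x$eigenvalues[1],
    eigenvalue2 = if (length(x$eigenvalues) > 1) x$eigenvalues[2] else NA_real_,
    window = as.character(x$window_index),
    aligned_to = x$aligned_to
  )
}

#' Tidy an allegiance matrix into pairwise records
#'
#' @param x An `fcg_allegiance`.
#' @param ... Unused.
#' @return A tibble of upper-triangle pairs: `roi_i`, `roi_j`,
#'   `allegiance`.
#' @exportS3Method generics::tidy
tidy.fcg_allegiance <- function(x, ...) {
  m <- as.matrix(x)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tibble::tibble(
    roi_i = ids[ut[, 1]],
    roi_j = ids[ut[, 2]],
    allegiance = m[ut]
  )
}

#' One-row summary of a static-null comparison
#'
#' @param x An `fcg_ks`.
#' @param ... Unused.
#' @return A tibble with the KS statistic, p-value, dispersions and sample
#'   sizes.
#' @exportS3Method generics::glance
glance.fcg_ks <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p.value,
    sd_real = x$sd_real,
    sd_null = x$sd_null,
    widespread = x$widespread,
    n_real = x$n_real,
    n_null = x$n_null
  )
}

#' One-row summary of a permutation test
#'
#' @param x An `fcg_perm`.
#' @param ... Unused.
#' @return A tibble with the observed statistic, p-value and permutation
#'   count.
#' @exportS3Method generics::glance
glance.fcg_perm <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p.value,
    n_perm = x$n_perm,
    null_sd = x$null_sd
  )
}

#' Tidy pipeline results
#'
#' @param x An `fcg_result`.
#' @param ... Unused.
#' @return The per-network comparison table (one row per measure family
#'   and network).
#' @exportS3Method generics::tidy
tidy.fcg_result <- function(x, ...) {
  tibble::as_tibble(x$comparisons)
}

#' One-row summary of a pipeline run
#'
#' @param x An `fcg_result`.
#' @param ... Unused.
#' @return A tibble with the headline quantities of the run.
#' @exportS3Method generics::glance
glance.fcg_result <- function(x, ...) {
  tibble::tibble(
    ks_D = x$ks$statistic,
    ks_p = x$ks$p.value,
    coupling_delta_r = x$coupling$statistic,
    coupling_p = x$coupling$p.value,
    preference_delta_r = x$preference$statistic,
    preference_p = x$preference$p.value,
    n_significant_fdr = sum(x$comparisons$p_fdr < 0.05),
    timing_s = x$timing_s
  )
}
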