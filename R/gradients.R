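#' Normalized-angle affinity between connectivity profiles
#'
#' Cosine similarity between rows of the (row-sparsified) connectivity
#' matrix, mapped through `1 - acos(rho) / pi` so values lie in [0, 1]
#' (1 = identical profiles, 0.5 = orthogonal, 0 = opposite).
#'
#' @param m Square matrix with sparsified rows (e.g. the output of
#'   [binarize_density()]).
#' @return Symmetric R x R affinity matrix with unit diagonal.
#' @export
normalized_angle_affinity <- function(m) {
  m <- as.matrix(m)
  G <- tcrossprod(m)
  nrm <- sqrt(diag(G))
  zero <- which(nrm == 0)
  if (length(zero) > 0) {
    ids <- rownames(m)[zero]
    if (is.null(ids)) ids <- as.character(zero)
    stop(
      "ROI(s) with no retained edges: ",
      paste(utils::head(ids, 5), collapse = ", "),
      call. = FALSE
    )
  }
  rho <- G / outer(nrm, nrm)
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  a <- 1 - acos(rho) / pi
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Applies anisotropic normalization `W = D^-alpha A D^-alpha`, row-
#' normalizes to a Markov transition matrix, and eigendecomposes it (via
#' the conjugate symmetric matrix for stability). The trivial constant
#' eigenvector is dropped; component j is the eigenvector `psi_j` (scaled
#' so the trivial one is all ones) times its diffusion scaling —
#' `lambda / (1 - lambda)` for `diffusion_time = 0` (automatic time), else
#' `lambda^t`. Columns are ordered by decreasing eigenvalue; signs are
#' fixed so each component's largest-magnitude entry is positive.
#'
#' @param affinity Symmetric non-negative affinity matrix describing a
#'   connected graph.
#' @param k Number of components to keep (default 2; component 1 is the
#'   principal gradient).
#' @param alpha Anisotropic diffusion normalization (default 0.5).
#' @param diffusion_time Diffusion time; 0 selects the automatic scaling
#'   `lambda / (1 - lambda)`.
#' @param window_index Optional label (`"static"` or a window number)
#'   carried on the result.
#' @return An object of class `fcg_gradient`: list with `components`
#'   (R x k matrix, ROI row names preserved), `eigenvalues` (the k retained
#'   non-trivial eigenvalues, non-increasing), `lambdas` (all eigenvalues),
#'   `window_index`, `aligned_to` (NA until [align_gradients()]).
#' @export
diffusion_embedding <- function(affinity, k = 2, alpha = 0.5,
                                diffusion_time = 0, window_index = "static") {
  A <- as.matrix(affinity)
  R <- nrow(A)
  stopifnot(ncol(A) == R, k >= 1, k < R)
  if (any(A < 0)) stop("affinity must be non-negative", call. = FALSE)
  if (max(abs(A - t(A))) > 1e-8) stop("affinity must be symmetric", call. = FALSE)
  d <- rowSums(A)
  if (any(d == 0)) stop("affinity has isolated nodes", call. = FALSE)
  W <- A / outer(d^alpha, d^alpha)
  dw <- rowSums(W)
  # Symmetric conjugate of the Markov matrix M = Dw^-1 W:
  # S = Dw^-1/2 W Dw^-1/2 shares eigenvalues; psi = Dw^-1/2 u.
  s <- 1 / sqrt(dw)
  S <- W * outer(s, s)
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$values
  if (sum(lam > 1 - 1e-10) > 1) {
    stop("affinity graph appears disconnected; lower the sparsity", call. = FALSE)
  }
  # Eigenvectors of M, normalized against the stationary distribution
  # (psi_j' diag(pi) psi_j = 1); the trivial eigenvector is then exactly 1.
  psi <- eg$vectors * s * sqrt(sum(dw))
  keep <- 2:(k + 1)
  lam_k <- lam[keep]
  scale_f <- if (diffusion_time == 0) lam_k / (1 - lam_k) else lam_k^diffusion_time
  comp <- psi[, keep, drop = FALSE]
  for (j in seq_len(ncol(comp))) {
    mx <- which.max(abs(comp[, j]))
    if (comp[mx, j] < 0) comp[, j] <- -comp[, j]
  }
  comp <- sweep(comp, 2, scale_f, `*`)
  rownames(comp) <- rownames(A)
  if (k > 1 && min(diff(rev(lam_k))) < 1e-10) {
    warning("near-degenerate eigenvalues; components defined up to rotation",
      call. = FALSE
    )
  }
  structure(
    list(
      components = comp,
      eigenvalues = lam_k,
      lambdas = lam,
      window_index = window_index,
      aligned_to = NA_character_
    ),
    class = "fcg_gradient"
  )
}

#' @export
print.fcg_gradient <- function(x, ...) {
  cat(sprintf(
    "<fcg_gradient> %d ROIs x %d components (window %s)%s\n",
    nrow(x$components), ncol(x$components), as.character(x$window_index),
    if (!is.na(x$aligned_to)) paste0(", aligned to ", x$aligned_to) else ""
  ))
  invisible(x)
}

#' Principal gradient values
#'
#' @param g An `fcg_gradient` or a numeric vector (returned as is).
#' @return Numeric vector of principal-gradient values per ROI.
#' @export
principal_gradient <- function(g) {
  if (inherits(g, "fcg_gradient")) g$components[, 1] else as.numeric(g)
}

#' Procrustes alignment of gradient components
#'
#' Rotates (orthogonal transform, reflections allowed, no scaling) the
#' source components onto the reference, resolving the arbitrary sign and
#' rotation of eigenvector bases across windows and subjects.
#'
#' @param source,reference `fcg_gradient` objects with equal dimensions.
#' @param label Identifier recorded in `aligned_to` (default
#'   `reference$window_index`).
#' @return The source `fcg_gradient` with rotated components.
#' @export
align_gradients <- function(source, reference, label = NULL) {
  stopifnot(inherits(source, "fcg_gradient"), inherits(reference, "fcg_gradient"))
  S <- source$components
  Rf <- reference$components
  if (!all(dim(S) == dim(Rf))) {
    stop(sprintf(
      "shape mismatch: source %dx%d vs reference %dx%d",
      nrow(S), ncol(S), nrow(Rf), ncol(Rf)
    ), call. = FALSE)
  }
  sv <- svd(crossprod(S, Rf))
  Q <- sv$u %*% t(sv$v)
  out <- source
  out$components <- S %*% Q
  rownames(out$components) <- rownames(S)
  out$aligned_to <- if (is.null(label)) as.character(reference$window_index) else label
  out
}

#' Discretize a gradient into equal-count bins
#'
#' ROIs are sorted by ascending principal-gradient value (ties broken by
#' ROI index) and split into K consecutive runs of `ceiling(R/K)` or
#' `floor(R/K)` ROIs (larger bins first), so bin sizes differ by at most
#' one and binning is invariant to strictly monotone transforms.
#'
#' @param g An `fcg_gradient` or numeric vector of gradient values.
#' @param K Number of bins (default 20; sensitivity analyses use 7).
#' @return Integer vector of bin ids in `[0, K)` per ROI, named by ROI.
#' @export
bin_gradient <- function(g, K = 20) {
  v <- principal_gradient(g)
  R <- length(v)
  stopifnot(K >= 2, K <= R)
  ord <- order(v, seq_len(R))
  base <- R %/% K
  rem <- R %% K
  sizes <- c(rep(base + 1L, rem), rep(base, K - rem))
  bins <- integer(R)
  bins[ord] <- rep.int(0:(K - 1L), sizes)
  names(bins) <- names(v)
  bins
}

#' Correlation between two gradients
#'
#' Pearson correlation of the principal components across ROIs, with a
#' two-sided p-value.
#'
#' @param a,b `fcg_gradient` objects or numeric vectors of equal length.
#' @return A tibble with columns `r`, `p`, `n`.
#' @export
gradient_similarity <- function(a, b) {
  x <- principal_gradient(a)
  y <- principal_gradient(b)
  if (length(x) != length(y)) stop("gradients differ in length", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-network gradient distributions
#'
#' Summaries of principal-gradient values within each network, used for
#' contraction/expansion comparisons (span = max - min).
#'
#' @param g An `fcg_gradient` or numeric vector (parcellation order).
#' @param parcellation An `fcg_parcellation`.
#' @return A tibble with one row per network: `network`, `n_roi`, `median`,
#'   `q25`, `q75`, `iqr`, `span`, and a list-column `values`.
#' @export
network_gradient_distribution <- function(g, parcellation) {
  stopifnot(inherits(parcellation, "fcg_parcellation"))
  v <- principal_gradient(g)
  if (length(v) != nrow(parcellation)) {
    stop("gradient length does not match parcellation", call. = FALSE)
  }
  tibble::tibble(network = parcellation$network, value = v) |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(
      n_roi = dplyr::n(),
      median = stats::median(.data$value),
      q25 = stats::quantile(.data$value, 0.25, names = FALSE),
      q75 = stats::quantile(.data$value, 0.75, names = FALSE),
      iqr = .data$q75 - .data$q25,
      span = max(.data$value) - min(.data$value),
      values = list(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(factor(.data$network, levels = yeo7_networks()))
}

#' Static gradient of one connectivity matrix
#'
#' Convenience chain: density binarization, normalized-angle affinity,
#' diffusion embedding.
#'
#' @param m Weighted connectivity matrix.
#' @param density Row density retained (default 0.10).
#' @param k Components (default 2).
#' @param window_index Label for the result.
#' @return An `fcg_gradient`.
#' @export
gradient_from_matrix <- function(m, density = 0.10, k = 2, window_index = "static") {
  b <- binarize_density(m, density)
  a <- normalized_angle_affinity(b)
  diffusion_embedding(a, k = k, window_index = window_index)
}
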