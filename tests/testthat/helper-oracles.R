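# Independent reference implementations used as oracles. These deliberately
# take the naive route (dense nonsymmetric eigen, triple loops, exhaustive
# enumeration) so they share no code with the package internals.

# Dense diffusion-map reference: build the Markov matrix explicitly and
# eigendecompose it as a general (nonsymmetric) matrix.
dense_embedding_oracle <- function(A, k = 2, alpha = 0.5) {
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  M <- W / rowSums(W)
  eg <- eigen(M)
  ord <- order(Re(eg$values), decreasing = TRUE)
  vals <- Re(eg$values)[ord]
  vecs <- Re(eg$vectors)[, ord, drop = FALSE]
  pi_w <- rowSums(W) / sum(rowSums(W))
  psi <- apply(vecs, 2, function(v) v / sqrt(sum(pi_w * v^2)))
  keep <- 2:(k + 1)
  comp <- psi[, keep, drop = FALSE]
  comp <- sweep(comp, 2, vals[keep] / (1 - vals[keep]), `*`)
  list(components = comp, eigenvalues = vals[keep])
}

# Frobenius residual after optimally rotating (orthogonal, with reflections)
# one component set onto another; used to compare embeddings whose bases are
# only defined up to sign/rotation.
procrustes_residual <- function(S, R) {
  sv <- svd(crossprod(S, R))
  norm(S %*% (sv$u %*% t(sv$v)) - R, "F")
}

# Brute-force allegiance: count same-bin events pair by pair.
allegiance_bruteforce <- function(arr) {
  d <- dim(arr)
  P <- matrix(0, d[1], d[1])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[1])) {
      cnt <- 0
      for (s in seq_len(d[3])) {
        for (w in seq_len(d[2])) {
          if (arr[i, w, s] == arr[j, w, s]) cnt <- cnt + 1
        }
      }
      P[i, j] <- cnt / (d[2] * d[3])
    }
  }
  P
}

# Brute-force recruitment for one subject's R x W assignment matrix.
recruitment_bruteforce <- function(mat, labels) {
  R <- nrow(mat)
  W <- ncol(mat)
  out <- rep(NA_real_, R)
  for (i in seq_len(R)) {
    partners <- setdiff(which(labels == labels[i]), i)
    if (length(partners) == 0) next
    tot <- 0
    for (w in seq_len(W)) {
      for (j in partners) tot <- tot + (mat[i, w] == mat[j, w])
    }
    out[i] <- tot / (W * length(partners))
  }
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mann_whitney_enumeration <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  Uobs <- sum(outer(x, y, ">"))
  cmb <- utils::combn(length(pool), n1)
  Us <- apply(cmb, 2, function(ix) sum(outer(pool[ix], pool[-ix], ">")))
  list(U = Uobs, p = mean(abs(Us - mu) >= abs(Uobs - mu)))
}

# Small synthetic parcellation covering all seven networks.
toy_parcellation <- function(n_per_network = 2, voxel_counts = NULL) {
  nets <- yeo7_networks()
  n <- n_per_network * length(nets)
  parcellation(
    roi_id = sprintf("R%02d", seq_len(n)),
    network = rep(nets, each = n_per_network),
    voxel_count = if (is.null(voxel_counts)) rep(10L, n) else voxel_counts
  )
}

# Random symmetric affinity in [0,1] with unit diagonal and a connected graph.
random_affinity <- function(R, seed) {
  set.seed(seed)
  B <- matrix(runif(R * R), R)
  A <- (B + t(B)) / 2
  diag(A) <- 1
  A
}

# Assemble an fcg_bin_stack from a plain array for direct metric tests.
stack_from_array <- function(arr, K) {
  structure(
    list(
      assignments = arr,
      K = as.integer(K),
      roi_ids = sprintf("R%02d", seq_len(dim(arr)[1])),
      subject_ids = sprintf("S%02d", seq_len(dim(arr)[3])),
      windows = NULL
    ),
    class = "fcg_bin_stack"
  )
}
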