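#' Windowed, aligned bin assignments for a set of subjects
#'
#' For each subject and each sliding window: Pearson correlation over the
#' window, row-density binarization, normalized-angle affinity, diffusion
#' embedding, Procrustes alignment to a common reference gradient, and
#' equal-count binning of the principal gradient. The common reference makes
#' bins comparable across windows and subjects.
#'
#' @param ts_list List of `fcg_timeseries` (same parcellation order).
#' @param scheme An `fcg_window_scheme`.
#' @param reference `fcg_gradient` used as the alignment template (typically
#'   the control-group static gradient); `NULL` disables alignment.
#' @param K Number of bins (default 20).
#' @param density Row density for binarization (default 0.10).
#' @param k Number of embedding components (default 2).
#' @param align Align each window gradient to `reference` before binning
#'   (default TRUE).
#' @return An object of class `fcg_bin_stack`: list with `assignments`
#'   (R x W x S integer array of bin ids), `K`, `roi_ids`, `subject_ids`,
#'   `windows` (the window plan).
#' @export
bin_stack <- function(ts_list, scheme, reference = NULL, K = 20,
                      density = 0.10, k = 2, align = TRUE) {
  stopifnot(length(ts_list) >= 1, inherits(scheme, "fcg_window_scheme"))
  wins <- plan_windows(scheme)
  R <- nrow(ts_list[[1]]$data)
  W <- nrow(wins)
  S <- length(ts_list)
  arr <- array(NA_integer_, dim = c(R, W, S))
  for (s in seq_len(S)) {
    X <- ts_list[[s]]$data
    for (w in seq_len(W)) {
      m <- correlation_matrix(X, wins$start[w], wins$end[w])
      g <- gradient_from_matrix(m, density = density, k = k, window_index = w)
      if (align && !is.null(reference)) g <- align_gradients(g, reference)
      arr[, w, s] <- bin_gradient(g, K)
    }
  }
  structure(
    list(
      assignments = arr,
      K = as.integer(K),
      roi_ids = rownames(ts_list[[1]]$data),
      subject_ids = vapply(ts_list, function(t) t$subject_id, character(1)),
      windows = wins
    ),
    class = "fcg_bin_stack"
  )
}

#' @export
print.fcg_bin_stack <- function(x, ...) {
  d <- dim(x$assignments)
  cat(sprintf(
    "<fcg_bin_stack> %d ROIs x %d windows x %d subjects, K = %d\n",
    d[1], d[2], d[3], x$K
  ))
  invisible(x)
}

same_bin_indicator <- function(bins) {
  outer(bins, bins, "==") * 1
}

#' Allegiance matrix of a bin-assignment stack
#'
#' The probability, over all (subject, window) pairs in the stack, that two
#' ROIs fall in the same gradient bin.
#'
#' @param stack An `fcg_bin_stack` (or R x W integer matrix for one
#'   subject).
#' @return An R x R matrix of class `fcg_allegiance` with attribute
#'   `n_observations` = subjects x windows; entries are exact fractions
#'   with that denominator; diagonal 1.
#' @export
allegiance <- function(stack) {
  arr <- stack_array(stack)
  d <- dim(arr)
  if (prod(d[2:3]) == 0) stop("empty assignment stack", call. = FALSE)
  R <- d[1]
  acc <- matrix(0, R, R)
  for (s in seq_len(d[3])) {
    for (w in seq_len(d[2])) {
      b <- arr[, w, s]
      acc <- acc + (outer(b, b, "==") * 1)
    }
  }
  P <- acc / prod(d[2:3])
  if (is.list(stack) && !is.null(stack$roi_ids)) {
    dimnames(P) <- list(stack$roi_ids, stack$roi_ids)
  }
  structure(P, n_observations = prod(d[2:3]), class = c("fcg_allegiance", "matrix", "array"))
}

#' @export
as.matrix.fcg_allegiance <- function(x, ...) {
  m <- unclass(x)
  attr(m, "n_observations") <- NULL
  m
}

stack_array <- function(stack) {
  if (inherits(stack, "fcg_bin_stack")) {
    stack$assignments
  } else if (is.array(stack) && length(dim(stack)) == 3) {
    stack
  } else if (is.matrix(stack)) {
    array(stack, dim = c(dim(stack), 1))
  } else {
    stop("expected an fcg_bin_stack or an R x W (x S) integer array", call. = FALSE)
  }
}

#' Per-subject, per-ROI flexibility
#'
#' The fraction of contiguous window transitions in which an ROI changes
#' bin: `#(bin(w) != bin(w-1)) / (W - 1)`.
#'
#' @param stack An `fcg_bin_stack`.
#' @return A tibble with columns `subject_id`, `roi_id`, `flexibility`.
#' @export
flexibility <- function(stack) {
  arr <- stack_array(stack)
  d <- dim(arr)
  if (d[2] < 2) stop("flexibility requires at least 2 windows", call. = FALSE)
  roi_ids <- stack_roi_ids(stack, d[1])
  subj <- stack_subject_ids(stack, d[3])
  purrr::map_dfr(seq_len(d[3]), function(s) {
    ch <- arr[, 2:d[2], s, drop = FALSE] != arr[, 1:(d[2] - 1), s, drop = FALSE]
    tibble::tibble(
      subject_id = subj[s],
      roi_id = roi_ids,
      flexibility = rowSums(ch) / (d[2] - 1)
    )
  })
}

stack_roi_ids <- function(stack, R) {
  if (is.list(stack) && !is.null(stack$roi_ids)) stack$roi_ids else sprintf("ROI%04d", seq_len(R))
}

stack_subject_ids <- function(stack, S) {
  if (is.list(stack) && !is.null(stack$subject_ids)) stack$subject_ids else sprintf("S%03d", seq_len(S))
}

#' Per-subject, per-ROI recruitment
#'
#' The probability, averaged over windows and over same-network partner
#' ROIs, that an ROI shares a bin with ROIs of its own network. Singleton
#' networks have no partners; their ROIs are reported as `NA` with a
#' warning and should be excluded from network means.
#'
#' @param stack An `fcg_bin_stack`.
#' @param parcellation An `fcg_parcellation` aligned to the stack ROIs.
#' @return A tibble with columns `subject_id`, `roi_id`, `network`,
#'   `recruitment`.
#' @export
recruitment <- function(stack, parcellation) {
  stopifnot(inherits(parcellation, "fcg_parcellation"))
  arr <- stack_array(stack)
  d <- dim(arr)
  if (nrow(parcellation) != d[1]) {
    stop("parcellation does not match stack ROI count", call. = FALSE)
  }
  labels <- parcellation$network
  net_sizes <- table(labels)
  if (any(net_sizes < 2)) {
    warning(
      "singleton network(s): ",
      paste(names(net_sizes)[net_sizes < 2], collapse = ", "),
      "; recruitment reported as NA there",
      call. = FALSE
    )
  }
  subj <- stack_subject_ids(stack, d[3])
  net_idx <- split(seq_len(d[1]), labels)
  purrr::map_dfr(seq_len(d[3]), function(s) {
    rec <- rep(NA_real_, d[1])
    for (idx in net_idx) {
      n <- length(idx)
      if (n < 2) next
      acc <- numeric(n)
      for (w in seq_len(d[2])) {
        b <- arr[idx, w, s]
        same <- outer(b, b, "==")
        acc <- acc + (rowSums(same) - 1) / (n - 1)
      }
      rec[idx] <- acc / d[2]
    }
    tibble::tibble(
      subject_id = subj[s],
      roi_id = stack_roi_ids(stack, d[1]),
      network = labels,
      recruitment = rec
    )
  })
}

#' Voxel-count-weighted network means of per-ROI values
#'
#' Because ROIs differ in size, a network's measure is the voxel-number-
#' weighted mean of its ROIs' measures; missing ROI values are excluded
#' from both numerator and denominator.
#'
#' @param values A tibble with columns `roi_id`, a value column, and
#'   optionally `subject_id` (grouped per subject when present); or a named
#'   numeric vector.
#' @param parcellation An `fcg_parcellation`.
#' @param value Name of the value column (default: the last non-id column).
#' @return A tibble with columns (`subject_id`,) `network`, `value`.
#' @export
network_weighted_mean <- function(values, parcellation, value = NULL) {
  stopifnot(inherits(parcellation, "fcg_parcellation"))
  if (is.numeric(values) && !is.null(names(values))) {
    values <- tibble::tibble(roi_id = names(values), value = unname(values))
  }
  if (is.null(value)) {
    cand <- setdiff(names(values), c("subject_id", "roi_id", "network"))
    value <- cand[length(cand)]
  }
  tbl <- dplyr::left_join(
    values,
    tibble::as_tibble(unclass_parcellation(parcellation))[, c("roi_id", "network", "voxel_count")],
    by = "roi_id", suffix = c(".x", "")
  )
  grp_vars <- intersect(c("subject_id", "network"), names(tbl))
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    dplyr::summarise(
      value = {
        v <- .data[[value]]
        w <- .data$voxel_count
        ok <- !is.na(v)
        if (!any(ok)) NA_real_ else sum(v[ok] * w[ok]) / sum(w[ok])
      },
      .groups = "drop"
    )
}

#' Compare real allegiance with static-null allegiance
#'
#' Two-sample Kolmogorov-Smirnov test on the upper-triangle allegiance
#' values of the real stack versus those pooled over the null (surrogate)
#' allegiance matrices. Entries of an allegiance matrix are weakly
#' dependent, so the effect size D is the primary quantity; dispersions of
#' both samples are reported so that "more widespread" dynamics are
#' directly visible.
#'
#' @param real An `fcg_allegiance` (or square matrix).
#' @param nulls A list of `fcg_allegiance` matrices from static surrogates.
#' @return A list of class `fcg_ks`: `statistic` (D), `p.value`,
#'   `sd_real`, `sd_null`, `n_real`, `n_null`, `widespread` (TRUE when the
#'   real distribution has larger dispersion).
#' @export
compare_to_static_null <- function(real, nulls) {
  if (!is.list(nulls) || length(nulls) == 0) {
    stop("need at least one null allegiance matrix", call. = FALSE)
  }
  real <- as.matrix(real)
  ut <- upper.tri(real)
  for (nm in nulls) {
    if (!all(dim(as.matrix(nm)) == dim(real))) {
      stop("null allegiance shape does not match the real matrix", call. = FALSE)
    }
  }
  x <- real[ut]
  y <- unlist(lapply(nulls, function(nm) as.matrix(nm)[ut]))
  ks <- suppressWarnings(stats::ks.test(x, y))
  structure(
    list(
      statistic = unname(ks$statistic),
      p.value = ks$p.value,
      sd_real = stats::sd(x),
      sd_null = stats::sd(y),
      n_real = length(x),
      n_null = length(y),
      widespread = stats::sd(x) > stats::sd(y)
    ),
    class = "fcg_ks"
  )
}

#' @export
print.fcg_ks <- function(x, ...) {
  cat(sprintf(
    "<fcg_ks> D = %.4f, p = %.3g (real sd %.4f vs null sd %.4f, %s)\n",
    x$statistic, x$p.value, x$sd_real, x$sd_null,
    if (x$widespread) "real more widespread" else "real not more widespread"
  ))
  invisible(x)
}
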