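#' Define a sliding-window scheme
#'
#' @param window_s Window length in seconds (default 40).
#' @param step_s Step between window starts in seconds (default 20).
#' @param total_s Total series duration in seconds.
#' @param sampling_interval_s Sampling interval in seconds (default 1).
#' @return A validated list of class `fcg_window_scheme`.
#' @export
window_scheme <- function(window_s = 40, step_s = 20, total_s,
                          sampling_interval_s = 1) {
  stopifnot(
    window_s > 0, step_s > 0, total_s > 0, sampling_interval_s > 0
  )
  if (window_s > total_s) {
    stop(sprintf(
      "window length (%g s) exceeds series duration (%g s)",
      window_s, total_s
    ), call. = FALSE)
  }
  to_n <- function(x) {
    n <- x / sampling_interval_s
    if (abs(n - round(n)) > 1e-9) {
      stop("window/step/total must be multiples of the sampling interval",
        call. = FALSE
      )
    }
    as.integer(round(n))
  }
  structure(
    list(
      window_s = window_s, step_s = step_s, total_s = total_s,
      sampling_interval_s = sampling_interval_s,
      window_n = to_n(window_s), step_n = to_n(step_s), total_n = to_n(total_s)
    ),
    class = "fcg_window_scheme"
  )
}

#' Plan sliding windows as half-open sample ranges
#'
#' Windows start at sample 0 and advance by the step; the count is
#' `floor((total - window) / step) + 1`, so the last window ends at or
#' before the end of the series. With the default 40 s windows in 20 s
#' steps on a 300 s series this yields 14 windows.
#'
#' @param scheme An `fcg_window_scheme`.
#' @return A tibble with columns `window` (1-based index), `start`, `end`
#'   (0-based, half-open sample range `[start, end)`).
#' @export
plan_windows <- function(scheme) {
  stopifnot(inherits(scheme, "fcg_window_scheme"))
  n_win <- (scheme$total_n - scheme$window_n) %/% scheme$step_n + 1L
  starts <- (seq_len(n_win) - 1L) * scheme$step_n
  tibble::tibble(
    window = seq_len(n_win),
    start = starts,
    end = starts + scheme$window_n
  )
}

slice_window <- function(data, start, end) {
  data[, (start + 1L):end, drop = FALSE]
}

#' Pearson correlation matrix over a sample range
#'
#' Series are de-meaned within the range (implicit in Pearson correlation).
#'
#' @param ts An `fcg_timeseries` or an ROI-by-time numeric matrix.
#' @param start,end Optional 0-based half-open sample range; the full series
#'   when omitted.
#' @return Symmetric R x R correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts, start = NULL, end = NULL) {
  data <- if (inherits(ts, "fcg_timeseries")) ts$data else as.matrix(ts)
  if (!is.null(start)) {
    data <- slice_window(data, start, if (is.null(end)) ncol(data) else end)
  }
  if (ncol(data) < 3) {
    stop("correlation window must contain at least 3 samples", call. = FALSE)
  }
  sds <- apply(data, 1, stats::sd)
  zero <- which(sds == 0)
  if (length(zero) > 0) {
    ids <- rownames(data)[zero]
    if (is.null(ids)) ids <- as.character(zero)
    stop(
      "zero-variance ROI(s) in window: ",
      paste(utils::head(ids, 5), collapse = ", "),
      call. = FALSE
    )
  }
  m <- stats::cor(t(data))
  diag(m) <- 1
  m
}

#' Row-wise density thresholding of a weighted connectivity matrix
#'
#' Keeps, per row, the top `ceiling(density * (R - 1))` off-diagonal entries
#' by value (ties broken by lower column index) and zeroes the rest,
#' matching a row sparsity of `1 - density`. The result need not be
#' symmetric; the diagonal is excluded and set to 0.
#'
#' @param m Weighted square matrix.
#' @param density Fraction of off-diagonal entries to retain per row,
#'   in (0, 1] (default 0.10).
#' @return Binary matrix of the same dimension (row sums all equal
#'   `ceiling(density * (R - 1))`).
#' @export
binarize_density <- function(m, density = 0.10) {
  m <- as.matrix(m)
  R <- nrow(m)
  if (ncol(m) != R) stop("matrix must be square", call. = FALSE)
  if (!is.numeric(density) || density <= 0 || density > 1) {
    stop("density must be in (0, 1]", call. = FALSE)
  }
  keep <- as.integer(ceiling(density * (R - 1)))
  out <- matrix(0, R, R, dimnames = dimnames(m))
  for (i in seq_len(R)) {
    vals <- m[i, ]
    vals[i] <- -Inf
    ord <- order(-vals, seq_len(R)) # ties broken by lower column index
    out[i, ord[seq_len(keep)]] <- 1
  }
  out
}

#' Entrywise mean of connectivity matrices
#'
#' @param ms Non-empty list of same-shaped numeric matrices.
#' @return Matrix of entrywise means.
#' @export
group_average <- function(ms) {
  if (length(ms) == 0) stop("empty matrix list", call. = FALSE)
  dims <- vapply(ms, dim, integer(2))
  if (any(dims != dims[, 1])) stop("matrices must share dimensions", call. = FALSE)
  Reduce(`+`, ms) / length(ms)
}

#' Multivariate phase-randomized surrogate of an ROI time series
#'
#' Adds one common conjugate-symmetric random phase vector to every ROI's
#' discrete Fourier transform. Each series' amplitude spectrum and all
#' pairwise cross-spectra are preserved exactly, hence so is the full-length
#' correlation structure, while genuine nonstationarity (window-to-window
#' reconfiguration) is destroyed — the static null model.
#'
#' @param ts An `fcg_timeseries`.
#' @param seed Optional integer seed for the random phases.
#' @return An `fcg_timeseries` surrogate (subject id suffixed `_surr`).
#' @export
phase_randomized_surrogate <- function(ts, seed = NULL) {
  stopifnot(inherits(ts, "fcg_timeseries"))
  X <- ts$data
  n <- ncol(X)
  if (n < 4) stop("need at least 4 samples for phase randomization", call. = FALSE)
  draw <- function() {
    ph <- numeric(n)
    half <- (n - 1) %/% 2
    if (half >= 1) {
      r <- stats::runif(half, 0, 2 * pi)
      ph[2:(half + 1)] <- r
      ph[n:(n - half + 1)] <- -r
    }
    if (n %% 2 == 0) ph[n / 2 + 1] <- sample(c(0, pi), 1)
    ph
  }
  ph <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  rot <- exp(1i * ph)
  F <- stats::mvfft(t(X))
  Xs <- t(Re(stats::mvfft(F * rot, inverse = TRUE)) / n)
  dimnames(Xs) <- dimnames(X)
  roi_timeseries(paste0(ts$subject_id, "_surr"), Xs, ts$sampling_interval_s)
}

#' Zero-phase frequency-domain bandpass filter
#'
#' Zeroes Fourier components outside `[low_hz, high_hz]` (the DC component
#' is kept so series retain their mean). Intended for real data; the
#' synthetic pipeline leaves it off.
#'
#' @param ts An `fcg_timeseries`.
#' @param low_hz,high_hz Pass band in Hz (defaults 0.009 and 0.10).
#' @return A filtered `fcg_timeseries`.
#' @export
bandpass_filter <- function(ts, low_hz = 0.009, high_hz = 0.10) {
  stopifnot(inherits(ts, "fcg_timeseries"), low_hz < high_hz)
  X <- ts$data
  n <- ncol(X)
  freqs <- (seq_len(n) - 1) / (n * ts$sampling_interval_s)
  freqs <- pmin(freqs, 1 / ts$sampling_interval_s - freqs) # two-sided
  keep <- (freqs >= low_hz & freqs <= high_hz) | seq_len(n) == 1
  F <- stats::mvfft(t(X))
  F[!keep, ] <- 0
  Xf <- t(Re(stats::mvfft(F, inverse = TRUE)) / n)
  dimnames(Xf) <- dimnames(X)
  roi_timeseries(ts$subject_id, Xf, ts$sampling_interval_s)
}
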