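#' Parameters of the synthetic cohort generator
#'
#' The generator emulates a two-group verbal-fluency-style block-design fMRI
#' study at the parcel level: a latent unimodal-to-transmodal axis generates
#' the connectivity structure, window-to-window jitter of latent positions
#' creates genuine gradient dynamics, and group effects (gradient contraction
#' of the DMN, reduced within-network coherence of selected networks) are
#' injected into the patient group so downstream analyses have recoverable
#' ground truth.
#'
#' @param n_roi Number of ROIs (default 400).
#' @param voxel_count_range Integer range voxel counts are drawn from.
#' @param n_subjects Named integer vector, subjects per group
#'   (default `c(HC = 29, TLE = 30)`).
#' @param n_blocks Number of rest+task blocks (default 5).
#' @param rest_s,task_s Rest and task module durations in seconds
#'   (default 30 each; rest first within each block).
#' @param sampling_interval_s Sampling interval in seconds (default 1).
#' @param axis_corr_scale Exponential decay scale of baseline correlation
#'   with latent-axis distance (default 0.15 on a unit axis).
#' @param within_network_boost Additive covariance for same-network pairs
#'   (default 0.05).
#' @param state_switch_rate Per-segment probability that a network's ROIs
#'   jitter along the axis (default 0.3); the source of true dynamics.
#' @param axis_jitter_sd SD of the per-ROI latent jitter (default 0.1).
#' @param switch_interval_s Length in seconds of the covariance segments at
#'   whose boundaries switches may occur (default 20).
#' @param dmn_contraction_factor Factor in (0, 1] shrinking the patient
#'   group's DMN latent positions toward the network's mean position
#'   (default 0.7; 1 = no effect).
#' @param recruitment_deficit_networks Networks whose within-network boost is
#'   reduced in the patient group (default `c("SMC", "LIM")`).
#' @param coherence_reduction Multiplier in (0, 1] on the within-network
#'   boost of `recruitment_deficit_networks` in the patient group
#'   (default 0.1; 1 = no effect).
#' @param deficit_jitter_sd SD of the extra independent per-segment axis
#'   jitter applied to the patient group's deficit-network ROIs
#'   (default 0.12; 0 = no effect) — reduced within-network dynamic
#'   coherence.
#' @param beta_gain Slope tying true task activation to latent position
#'   (default 1).
#' @param beta_network_offset_sd SD of the per-network activation offset
#'   (default 0.1).
#' @param noise_sd SD of additive white measurement noise (default 0.5).
#' @param seed Master seed; all randomness in [simulate_cohort()] derives
#'   from it.
#' @return A validated list of class `fcg_synth_params`.
#' @export
synth_params <- function(n_roi = 400,
                         voxel_count_range = c(50L, 500L),
                         n_subjects = c(HC = 29L, TLE = 30L),
                         n_blocks = 5,
                         rest_s = 30,
                         task_s = 30,
                         sampling_interval_s = 1,
                         axis_corr_scale = 0.15,
                         within_network_boost = 0.05,
                         state_switch_rate = 0.3,
                         axis_jitter_sd = 0.1,
                         switch_interval_s = 20,
                         dmn_contraction_factor = 0.7,
                         recruitment_deficit_networks = c("SMC", "LIM"),
                         coherence_reduction = 0.1,
                         deficit_jitter_sd = 0.12,
                         beta_gain = 1,
                         beta_network_offset_sd = 0.1,
                         noise_sd = 0.5,
                         seed = 1L) {
  p <- list(
    n_roi = as.integer(n_roi),
    n_networks = 7L,
    voxel_count_range = as.integer(voxel_count_range),
    n_subjects = n_subjects,
    n_blocks = as.integer(n_blocks),
    rest_s = rest_s,
    task_s = task_s,
    sampling_interval_s = sampling_interval_s,
    axis_corr_scale = axis_corr_scale,
    within_network_boost = within_network_boost,
    state_switch_rate = state_switch_rate,
    axis_jitter_sd = axis_jitter_sd,
    switch_interval_s = switch_interval_s,
    dmn_contraction_factor = dmn_contraction_factor,
    recruitment_deficit_networks = recruitment_deficit_networks,
    coherence_reduction = coherence_reduction,
    deficit_jitter_sd = deficit_jitter_sd,
    beta_gain = beta_gain,
    beta_network_offset_sd = beta_network_offset_sd,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (p$n_roi < p$n_networks) {
    stop(sprintf("n_roi (%d) must be at least the number of networks (%d)",
      p$n_roi, p$n_networks), call. = FALSE)
  }
  if (p$state_switch_rate < 0 || p$state_switch_rate > 1) {
    stop("state_switch_rate must be in [0, 1]", call. = FALSE)
  }
  stopifnot(
    p$dmn_contraction_factor > 0, p$dmn_contraction_factor <= 1,
    p$coherence_reduction > 0, p$coherence_reduction <= 1,
    p$deficit_jitter_sd >= 0,
    p$axis_corr_scale > 0, p$noise_sd >= 0, p$axis_jitter_sd >= 0,
    p$sampling_interval_s > 0, p$n_blocks >= 1,
    all(p$n_subjects >= 1), length(p$n_subjects) == 2,
    !is.null(names(p$n_subjects))
  )
  p$n_time <- as.integer(round(p$n_blocks * (p$rest_s + p$task_s) / p$sampling_interval_s))
  class(p) <- "fcg_synth_params"
  p
}

# Deterministic sub-seed stream: all generator randomness flows from the
# master seed through fixed offsets, so cohorts are bit-reproducible.
seed_stream <- function(master, k) {
  as.integer((as.double(master) * 7919 + k * 104729) %% 2147483647)
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic parcellation
#'
#' ROIs are assigned to the seven networks in contiguous near-equal blocks
#' ordered along the unimodal-to-transmodal axis; voxel counts are drawn
#' uniformly from `voxel_count_range`.
#'
#' @param params An `fcg_synth_params`.
#' @return An `fcg_parcellation` with `n_roi` rows.
#' @export
make_parcellation <- function(params) {
  stopifnot(inherits(params, "fcg_synth_params"))
  nets <- yeo7_networks()
  sizes <- diff(round(seq(0, params$n_roi, length.out = length(nets) + 1)))
  labels <- rep(nets, times = sizes)
  vc <- with_local_seed(
    seed_stream(params$seed, 1),
    sample(params$voxel_count_range[1]:params$voxel_count_range[2],
      params$n_roi,
      replace = TRUE
    )
  )
  parcellation(
    roi_id = sprintf("ROI%04d", seq_len(params$n_roi)),
    network = labels,
    voxel_count = vc
  )
}

#' Build the block task design
#'
#' Each block is a rest module followed by a task module; the design is the
#' concatenation of `n_blocks` such blocks sampled at `sampling_interval_s`.
#'
#' @param params An `fcg_synth_params` (or anything with `n_blocks`,
#'   `rest_s`, `task_s`, `sampling_interval_s`).
#' @return Integer vector of length T with 0 = rest, 1 = task.
#' @export
make_design <- function(params) {
  rest_n <- as.integer(round(params$rest_s / params$sampling_interval_s))
  task_n <- as.integer(round(params$task_s / params$sampling_interval_s))
  if (rest_n + task_n < 1) stop("block length must be positive", call. = FALSE)
  rep(c(rep(0L, rest_n), rep(1L, task_n)), times = params$n_blocks)
}

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (shapes `peak` and `undershoot`, rate 1)
#' with undershoot weight `1/ratio`, normalized to unit sum so that a
#' sustained block regressor plateaus near 1.
#'
#' @param t Time points in seconds (non-negative).
#' @param peak Gamma shape of the response peak (default 6).
#' @param undershoot Gamma shape of the undershoot (default 16).
#' @param ratio Response-to-undershoot ratio (default 6).
#' @return Numeric vector of HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h / sum(h)
}

#' Convolve a design with the canonical HRF
#'
#' @param design Binary design vector.
#' @param sampling_interval_s Sampling interval in seconds.
#' @param span_s Length of the HRF kernel in seconds (default 32).
#' @return Numeric regressor of the same length as `design`.
#' @export
hrf_regressor <- function(design, sampling_interval_s = 1, span_s = 32) {
  tt <- seq(0, span_s, by = sampling_interval_s)
  h <- canonical_hrf(tt)
  n <- length(design)
  full <- stats::convolve(as.numeric(design), rev(h), type = "open")
  full[seq_len(n)]
}

net_boosts <- function(params, group_idx) {
  nets <- yeo7_networks()
  b <- rep(params$within_network_boost, length(nets))
  names(b) <- nets
  if (group_idx == 2) {
    hit <- nets %in% params$recruitment_deficit_networks
    b[hit] <- b[hit] * params$coherence_reduction
  }
  b
}

latent_axis <- function(params) {
  nets <- yeo7_networks()
  sizes <- diff(round(seq(0, params$n_roi, length.out = length(nets) + 1)))
  g <- numeric(0)
  for (m in seq_along(nets)) {
    lo <- (m - 1) / length(nets)
    hi <- m / length(nets)
    g <- c(g, seq(lo, hi, length.out = sizes[m] + 2)[2:(sizes[m] + 1)])
  }
  g
}

# Gradient contraction: the patient group's DMN latent positions shrink
# toward the network's own mean position, compressing the network's range
# on the axis without relocating it among neighbouring networks.
group_axis <- function(g, labels, params, group_idx) {
  if (group_idx == 2 && params$dmn_contraction_factor < 1) {
    dmn <- labels == "DMN"
    ctr <- mean(g[dmn])
    g[dmn] <- ctr + params$dmn_contraction_factor * (g[dmn] - ctr)
  }
  g
}

# Small nugget keeps the Cholesky stable when jittered positions nearly
# coincide; it is three orders below the measurement noise.
axis_covariance <- function(g, labels, boosts, scale, nugget = 1e-6) {
  C <- exp(-abs(outer(g, g, "-")) / scale)
  same <- outer(labels, labels, "==")
  bmat <- outer(boosts[labels], boosts[labels], pmin)
  C + same * bmat + diag(nugget, length(g))
}

# Reflect excursions at the axis boundaries so jittered positions stay in
# [0, 1] without piling up at the endpoints.
reflect_unit <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

safe_chol <- function(C) {
  out <- tryCatch(chol(C), error = function(e) NULL)
  ridge <- 1e-8
  while (is.null(out) && ridge < 1e-2) {
    warning("covariance not positive definite; adding diagonal loading ",
      ridge,
      call. = FALSE
    )
    out <- tryCatch(chol(C + diag(ridge, nrow(C))), error = function(e) NULL)
    ridge <- ridge * 10
  }
  if (is.null(out)) {
    stop("covariance could not be made positive definite; reduce within_network_boost",
      call. = FALSE
    )
  }
  out
}

#' Simulate a synthetic two-group cohort
#'
#' Draws each subject's ROI-by-time series from a latent-factor model:
#' baseline covariance decays exponentially with latent-axis distance plus a
#' within-network boost; at segment boundaries each network's latent
#' positions jitter with probability `state_switch_rate` (the source of
#' genuine window dynamics); the patient group receives a DMN axis
#' contraction and reduced within-network coherence for the deficit
#' networks; block-design activation proportional to latent position is
#' added after HRF convolution, plus white noise.
#'
#' @param params An `fcg_synth_params`.
#' @return A list of class `fcg_cohort` with elements `timeseries` (list of
#'   [roi_timeseries()]), `subjects` (tibble with group and covariates),
#'   `parcellation`, `design`, and `ground_truth` (latent axis per group,
#'   true betas per group, per-segment latent positions, parameters).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "fcg_synth_params"))
  parc <- make_parcellation(params)
  labels <- parc$network
  design <- make_design(params)
  reg <- hrf_regressor(design, params$sampling_interval_s)
  T_n <- params$n_time
  seg_n <- max(1L, as.integer(round(params$switch_interval_s / params$sampling_interval_s)))
  seg_starts <- seq(1L, T_n, by = seg_n)

  g_base <- latent_axis(params)
  groups <- names(params$n_subjects)
  nets <- yeo7_networks()

  # Per-network activation offsets, shared across the cohort.
  offsets <- with_local_seed(
    seed_stream(params$seed, 2),
    stats::rnorm(length(nets), 0, params$beta_network_offset_sd)
  )
  names(offsets) <- nets

  axis_by_group <- list()
  betas_by_group <- list()
  for (gi in seq_along(groups)) {
    g_g <- group_axis(g_base, labels, params, gi)
    axis_by_group[[groups[gi]]] <- g_g
    betas_by_group[[groups[gi]]] <-
      params$beta_gain * g_g + offsets[labels]
  }

  subjects <- list()
  ts_list <- list()
  seg_positions <- list()
  subj_idx <- 0L
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    boosts <- net_boosts(params, gi)
    g_g <- axis_by_group[[grp]]
    tb <- betas_by_group[[grp]]
    for (si in seq_len(params$n_subjects[gi])) {
      subj_idx <- subj_idx + 1L
      sid <- sprintf("%s%03d", grp, si)
      dat <- with_local_seed(seed_stream(params$seed, 100 + subj_idx), {
        X <- matrix(0, params$n_roi, T_n)
        g_cur <- g_g
        pos <- matrix(NA_real_, params$n_roi, length(seg_starts))
        L <- NULL
        for (k in seq_along(seg_starts)) {
          changed <- FALSE
          if (k > 1 && params$state_switch_rate > 0) {
            g_new <- g_g
            for (m in nets) {
              if (stats::runif(1) < params$state_switch_rate) {
                idx <- which(labels == m)
                g_new[idx] <- reflect_unit(
                  g_g[idx] + stats::rnorm(length(idx), 0, params$axis_jitter_sd)
                )
              }
            }
            changed <- !identical(g_new, g_cur)
            g_cur <- g_new
          }
          # Patient-group deficit networks lose within-network dynamic
          # coherence: their ROIs take independent excursions every segment.
          if (gi == 2 && params$deficit_jitter_sd > 0 && k > 1) {
            idx <- which(labels %in% params$recruitment_deficit_networks)
            if (length(idx) > 0) {
              g_cur[idx] <- reflect_unit(
                g_cur[idx] + stats::rnorm(length(idx), 0, params$deficit_jitter_sd)
              )
              changed <- TRUE
            }
          }
          pos[, k] <- g_cur
          if (is.null(L) || changed) {
            C <- axis_covariance(g_cur, labels, boosts, params$axis_corr_scale)
            L <- safe_chol(C)
          }
          t0 <- seg_starts[k]
          t1 <- min(T_n, t0 + seg_n - 1L)
          len <- t1 - t0 + 1L
          X[, t0:t1] <- crossprod(L, matrix(stats::rnorm(params$n_roi * len), params$n_roi))
        }
        act <- outer(tb, reg)
        X <- X + act
        if (params$noise_sd > 0) {
          X <- X + matrix(
            stats::rnorm(params$n_roi * T_n, 0, params$noise_sd),
            params$n_roi
          )
        }
        list(X = X, pos = pos)
      })
      seg_positions[[sid]] <- dat$pos
      ts_list[[sid]] <- roi_timeseries(sid, dat$X, params$sampling_interval_s,
        roi_ids = parc$roi_id
      )
      subjects[[subj_idx]] <- tibble::tibble(subject_id = sid, group = grp)
    }
  }

  subj_tbl <- dplyr::bind_rows(subjects)
  n_total <- nrow(subj_tbl)
  cov_tbl <- with_local_seed(seed_stream(params$seed, 3), tibble::tibble(
    age = round(stats::runif(n_total, 18, 60)),
    sex = stats::rbinom(n_total, 1, 0.5),
    education = round(stats::runif(n_total, 6, 18)),
    moca = round(pmin(30, pmax(10, stats::rnorm(
      n_total,
      ifelse(subj_tbl$group == groups[2], 26, 28), 2
    ))))
  ))
  subj_tbl <- dplyr::bind_cols(subj_tbl, cov_tbl)

  structure(
    list(
      timeseries = ts_list,
      subjects = subj_tbl,
      parcellation = parc,
      design = design,
      ground_truth = list(
        latent_axis = stats::setNames(g_base, parc$roi_id),
        axis_by_group = axis_by_group,
        true_betas = betas_by_group,
        network_offsets = offsets,
        segment_positions = seg_positions,
        params = params
      )
    ),
    class = "fcg_cohort"
  )
}

#' @export
print.fcg_cohort <- function(x, ...) {
  cat(sprintf(
    "<fcg_cohort> %d subjects (%s), %d ROIs x %d samples\n",
    length(x$timeseries),
    paste(sprintf("%s=%d", names(table(x$subjects$group)), table(x$subjects$group)),
      collapse = ", "
    ),
    nrow(x$parcellation), length(x$design)
  ))
  invisible(x)
}
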