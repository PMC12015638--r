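test_that("window planning matches the closed-form count and ranges", {
  ws <- window_scheme(40, 20, 300, 1)
  plan <- plan_windows(ws)
  expect_equal(nrow(plan), 14)
  expect_equal(plan$start[1], 0)
  expect_equal(plan$end[1], 40)
  expect_equal(plan$start[14], 260)
  expect_equal(plan$end[14], 300)

  expect_equal(nrow(plan_windows(window_scheme(40, 20, 40, 1))), 1)
  p100 <- plan_windows(window_scheme(40, 20, 100, 1))
  expect_equal(nrow(p100), 4)
  expect_equal(p100$end[4], 100)

  expect_error(window_scheme(400, 20, 300, 1), "exceeds")
})

test_that("window counts agree with explicit enumeration over random schemes", {
  set.seed(42)
  for (i in 1:25) {
    win <- sample(5:60, 1)
    step <- sample(1:30, 1)
    total <- win + sample(0:200, 1)
    plan <- plan_windows(window_scheme(win, step, total, 1))
    starts <- seq(0, total - win, by = step) # enumeration oracle
    expect_equal(plan$start, starts)
    expect_true(all(plan$end <= total))
  }
})

test_that("correlation matrices behave at the textbook extremes", {
  base <- rnorm(40)
  m <- correlation_matrix(rbind(a = base, b = base, c = -base + 5))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))

  flat <- rbind(a = rnorm(10), b = rep(2, 10))
  expect_error(correlation_matrix(flat), "zero-variance.*b")
  expect_error(correlation_matrix(matrix(rnorm(4), 2, 2)), "at least 3")
})

test_that("correlation matches a two-pass covariance/sd computation", {
  set.seed(7)
  X <- matrix(rnorm(5 * 40), 5, 40)
  got <- correlation_matrix(X)
  manual <- matrix(0, 5, 5)
  for (i in 1:5) {
    for (j in 1:5) {
      xi <- X[i, ] - mean(X[i, ])
      xj <- X[j, ] - mean(X[j, ])
      manual[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  diag(manual) <- 1
  expect_equal(unname(got), manual, tolerance = 1e-12)
})

test_that("correlation is invariant to positive affine rescaling per ROI", {
  set.seed(8)
  X <- matrix(rnorm(6 * 50), 6, 50)
  Y <- X * runif(6, 0.5, 3) + rnorm(6)
  expect_equal(correlation_matrix(X), correlation_matrix(Y), tolerance = 1e-10)
})

test_that("density binarization keeps exact row counts with stable ties", {
  set.seed(3)
  m <- matrix(rnorm(400 * 400), 400)
  m <- (m + t(m)) / 2
  b <- binarize_density(m, 0.10)
  expect_true(all(rowSums(b) == 40))
  expect_true(all(diag(b) == 0))

  flat <- matrix(1, 6, 6)
  bf <- binarize_density(flat, 0.5)
  keep <- ceiling(0.5 * 5)
  for (i in 1:6) {
    expected <- setdiff(1:6, i)[seq_len(keep)]
    expect_equal(which(bf[i, ] == 1), expected)
  }

  expect_error(binarize_density(flat, 0), "density")
  expect_error(binarize_density(flat, 1.2), "density")
})

test_that("binarization matches a brute-force per-row sort", {
  set.seed(11)
  m <- matrix(rnorm(25), 5, 5)
  b <- binarize_density(m, 0.5)
  keep <- ceiling(0.5 * 4)
  for (i in 1:5) {
    vals <- m[i, -i]
    cols <- setdiff(1:5, i)
    expected <- cols[order(-vals)][seq_len(keep)]
    expect_setequal(which(b[i, ] == 1), expected)
  }
})

test_that("group averaging is the entrywise mean", {
  m <- matrix(rnorm(16), 4)
  expect_equal(group_average(list(m)), m)
  z <- group_average(list(m, -m))
  expect_equal(z, matrix(0, 4, 4))
  ms <- replicate(3, matrix(rnorm(16), 4), simplify = FALSE)
  expect_equal(group_average(ms), (ms[[1]] + ms[[2]] + ms[[3]]) / 3)
  expect_error(group_average(list()), "empty")
})

test_that("phase randomization preserves spectra and static correlation", {
  set.seed(5)
  ts <- roi_timeseries("s", matrix(rnorm(8 * 120), 8, 120), 1)
  surr <- phase_randomized_surrogate(ts, seed = 99)
  amp <- function(X) abs(t(stats::mvfft(t(X))))
  expect_equal(amp(surr$data), amp(ts$data), tolerance = 1e-8)
  expect_equal(
    correlation_matrix(surr$data),
    correlation_matrix(ts$data),
    tolerance = 1e-8
  )
  surr2 <- phase_randomized_surrogate(ts, seed = 99)
  expect_identical(surr$data, surr2$data)
  surr3 <- phase_randomized_surrogate(ts, seed = 100)
  expect_false(identical(surr$data, surr3$data))
})

test_that("surrogates flatten window-to-window correlation variability", {
  p <- synth_params(
    n_roi = 40, n_subjects = c(HC = 1L, TLE = 1L), seed = 21,
    state_switch_rate = 0.5, beta_gain = 0.01
  )
  co <- simulate_cohort(p)
  wins <- plan_windows(window_scheme(40, 20, 300, 1))
  wsd <- function(ts) {
    cors <- lapply(seq_len(nrow(wins)), function(w) {
      correlation_matrix(ts, wins$start[w], wins$end[w])
    })
    arr <- simplify2array(cors)
    mean(apply(arr, c(1, 2), stats::sd)[upper.tri(cors[[1]])])
  }
  real <- co$timeseries[[1]]
  surr <- phase_randomized_surrogate(real, seed = 1)
  expect_lte(wsd(surr), wsd(real))
})

test_that("the bandpass filter separates in-band from out-of-band signal", {
  t <- 0:299
  slow <- sin(2 * pi * 0.05 * t) # in band
  fast <- sin(2 * pi * 0.3 * t) # out of band
  ts <- roi_timeseries("s", rbind(slow, fast), 1)
  f <- bandpass_filter(ts)
  expect_gt(stats::sd(f$data[1, ]), 0.5)
  expect_lt(stats::sd(f$data[2, ]), 0.05)
})
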