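test_that("allegiance equals the same-bin indicator in degenerate stacks", {
  arr <- array(c(0L, 0L, 1L), dim = c(3, 1, 1))
  P <- allegiance(stack_from_array(arr, 2))
  expect_equal(unname(as.matrix(P)), rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))

  arr2 <- array(rep(c(0L, 1L, 1L), 4), dim = c(3, 2, 2)) # identical everywhere
  P2 <- allegiance(stack_from_array(arr2, 2))
  expect_equal(unname(as.matrix(P2)), rbind(c(1, 0, 0), c(0, 1, 1), c(0, 1, 1)))
})

test_that("allegiance matches brute-force pair counting", {
  arr <- array(c(
    0L, 1L, 0L, 0L, 0L, 1L, # subject 1, windows 1-2
    1L, 1L, 0L, 2L, 1L, 1L # subject 2, windows 1-2
  ), dim = c(3, 2, 2))
  P <- allegiance(stack_from_array(arr, 3))
  expect_equal(unname(as.matrix(P)), allegiance_bruteforce(arr))
  expect_equal(attr(P, "n_observations"), 4)

  set.seed(31)
  for (i in 1:5) {
    arr <- array(sample(0L:3L, 8 * 3 * 2, replace = TRUE), dim = c(8, 3, 2))
    expect_equal(
      unname(as.matrix(allegiance(stack_from_array(arr, 4)))),
      allegiance_bruteforce(arr)
    )
  }
})

test_that("flexibility counts contiguous bin changes", {
  constant <- array(2L, dim = c(4, 14, 1))
  f <- flexibility(stack_from_array(constant, 20))
  expect_equal(f$flexibility, rep(0, 4))

  alt <- array(rep(c(0L, 1L), each = 4, times = 7), dim = c(4, 14, 1))
  expect_equal(flexibility(stack_from_array(alt, 2))$flexibility, rep(1, 4))

  one <- array(0L, dim = c(1, 14, 1))
  one[1, 8, 1] <- 1L
  # one transition into, one out of the deviant window: 2 changes / 13
  expect_equal(flexibility(stack_from_array(one, 2))$flexibility, 2 / 13)
  one[1, 14, 1] <- 1L
  one[1, 8, 1] <- 0L
  expect_equal(flexibility(stack_from_array(one, 2))$flexibility, 1 / 13)

  expect_error(flexibility(stack_from_array(array(0L, c(2, 1, 1)), 2)), "2 windows")
})

test_that("recruitment matches exhaustive enumeration and handles singletons", {
  parc <- parcellation(
    sprintf("r%d", 1:5),
    c("SMC", "SMC", "SMC", "SMC", "DMN"),
    rep(1, 5)
  )
  set.seed(17)
  mat <- matrix(sample(0L:2L, 5 * 3, replace = TRUE), 5, 3)
  arr <- array(mat, dim = c(5, 3, 1))
  expect_warning(
    r <- recruitment(stack_from_array(arr, 3), parc),
    "singleton"
  )
  expect_equal(r$recruitment[1:4], recruitment_bruteforce(mat, parc$network)[1:4])
  expect_true(is.na(r$recruitment[5]))

  all_same <- array(1L, dim = c(5, 3, 1))
  expect_warning(r1 <- recruitment(stack_from_array(all_same, 2), parc))
  expect_equal(r1$recruitment[1:4], rep(1, 4))

  distinct <- array(rep(0L:4L, 3), dim = c(5, 3, 1))
  expect_warning(r0 <- recruitment(stack_from_array(distinct, 5), parc))
  expect_equal(r0$recruitment[1:4], rep(0, 4))
})

test_that("recruitment equals the network-restricted per-subject allegiance", {
  parc <- toy_parcellation(n_per_network = 3)
  set.seed(23)
  arr <- array(sample(0L:4L, 21 * 6 * 1, replace = TRUE), dim = c(21, 6, 1))
  P <- as.matrix(allegiance(stack_from_array(arr, 5)))
  r <- recruitment(stack_from_array(arr, 5), parc)
  for (i in seq_len(21)) {
    partners <- setdiff(which(parc$network == parc$network[i]), i)
    expect_equal(r$recruitment[i], mean(P[i, partners]))
  }
})

test_that("dynamic measures ignore bin relabeling within windows", {
  parc <- toy_parcellation(n_per_network = 2)
  set.seed(5)
  arr <- array(sample(0L:3L, 14 * 5 * 2, replace = TRUE), dim = c(14, 5, 2))
  relab <- arr
  for (s in 1:2) {
    for (w in 1:5) {
      perm <- sample(0:3)
      relab[, w, s] <- perm[arr[, w, s] + 1L]
    }
  }
  expect_equal(
    as.matrix(allegiance(stack_from_array(arr, 4))),
    as.matrix(allegiance(stack_from_array(relab, 4)))
  )
  expect_equal(
    recruitment(stack_from_array(arr, 4), parc)$recruitment,
    recruitment(stack_from_array(relab, 4), parc)$recruitment
  )
  # flexibility compares across windows, so only a relabeling shared by all
  # windows leaves it unchanged
  common <- sample(0:3)
  relab2 <- array(common[arr + 1L], dim = dim(arr))
  expect_equal(
    flexibility(stack_from_array(arr, 4))$flexibility,
    flexibility(stack_from_array(relab2, 4))$flexibility
  )
})

test_that("voxel-weighted network means reduce to the documented cases", {
  parc <- parcellation(
    c("a", "b", "c"), c("SMC", "SMC", "SMC"), c(1, 2, 3)
  )
  v <- stats::setNames(c(0, 1, 1), c("a", "b", "c"))
  out <- network_weighted_mean(v, parc)
  expect_equal(out$value, 5 / 6)

  eq <- parcellation(c("a", "b", "c"), rep("DMN", 3), c(7, 7, 7))
  expect_equal(network_weighted_mean(v, eq)$value, mean(v))

  dom <- parcellation(c("a", "b", "c"), rep("VIS", 3), c(1, 1, 100000))
  expect_equal(network_weighted_mean(v, dom)$value, 1, tolerance = 1e-4)

  # missing values drop out of numerator and denominator
  vm <- stats::setNames(c(0, NA, 1), c("a", "b", "c"))
  expect_equal(network_weighted_mean(vm, parc)$value, 3 / 4)
})

test_that("the static-null comparison hits its distributional extremes", {
  set.seed(9)
  P <- matrix(runif(64), 8)
  P <- (P + t(P)) / 2
  diag(P) <- 1
  same <- compare_to_static_null(P, list(P))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1, tolerance = 1e-9)

  lo <- matrix(0.1, 8, 8)
  hi <- matrix(0.9, 8, 8)
  disjoint <- compare_to_static_null(lo, list(hi))
  expect_equal(disjoint$statistic, 1)

  expect_error(compare_to_static_null(P, list(matrix(0, 4, 4))), "shape")
  expect_error(compare_to_static_null(P, list()), "at least one")
})

test_that("static cohorts show flexibility comparable to their surrogates", {
  diffs <- vapply(1:20, function(seed) {
    p <- synth_params(
      n_roi = 35, n_subjects = c(HC = 2L, TLE = 1L), seed = seed,
      state_switch_rate = 0, beta_gain = 0.01,
      dmn_contraction_factor = 1, coherence_reduction = 1, deficit_jitter_sd = 0
    )
    co <- simulate_cohort(p)
    hc <- co$timeseries[1:2]
    scheme <- window_scheme(40, 20, 300, 1)
    tmpl <- gradient_from_matrix(group_average(lapply(hc, correlation_matrix)))
    surr <- lapply(seq_along(hc), function(s) {
      phase_randomized_surrogate(hc[[s]], seed = seed * 100 + s)
    })
    f_real <- mean(flexibility(bin_stack(hc, scheme, tmpl, K = 10))$flexibility)
    f_surr <- mean(flexibility(bin_stack(surr, scheme, tmpl, K = 10))$flexibility)
    f_real - f_surr
  }, numeric(1))
  expect_gt(stats::t.test(diffs)$p.value, 0.05)
})
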