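test_that("OLS betas recover an exact noiseless task amplitude", {
  design <- make_design(synth_params())
  reg <- hrf_regressor(design, 1)
  X <- rbind(a = 2 * reg, b = -0.5 * reg + 3 + 0.001 * seq_along(reg))
  ts <- roi_timeseries("s", X, 1)
  b <- estimate_betas(ts, design)
  expect_equal(b$beta, c(2, -0.5), tolerance = 1e-8)

  expect_error(estimate_betas(ts, rep(1, 300)), "constant")
  expect_error(estimate_betas(ts, design[-1]), "length")
})

test_that("betas on pure noise are centered at zero", {
  set.seed(44)
  design <- make_design(synth_params())
  ts <- roi_timeseries("s", matrix(rnorm(300 * 300), 300, 300), 1)
  b <- estimate_betas(ts, design)
  expect_lt(abs(mean(b$beta)), 0.05)
  expect_gt(stats::t.test(b$beta)$p.value, 0.01)
})

test_that("loading scores reproduce the hand-worked fixture", {
  parc <- parcellation(c("a", "b", "c"), rep("DMN", 3), c(5, 5, 5))
  b <- tibble::tibble(roi_id = c("a", "b", "c"), beta = c(1, -1, 2))
  g <- c(0.5, 0.5, -1)
  ls <- loading_scores(b, g, parc)
  expect_equal(ls$roi$loading, c(0.5, -0.5, -2))
  expect_equal(ls$network$value, -2 / 3)

  zero <- loading_scores(
    tibble::tibble(roi_id = c("a", "b", "c"), beta = c(0, 0, 0)), g, parc
  )
  expect_equal(zero$roi$loading, rep(0, 3))
  expect_equal(zero$network$value, 0)
})

test_that("network loadings are recomputable from ROI loadings and weights", {
  parc <- toy_parcellation(3, voxel_counts = sample(50:500, 21))
  set.seed(2)
  b <- tibble::tibble(roi_id = parc$roi_id, beta = rnorm(21))
  g <- rnorm(21)
  ls <- loading_scores(b, g, parc)
  manual <- tapply(seq_len(21), parc$network, function(ix) {
    sum(ls$roi$loading[ix] * parc$voxel_count[ix]) / sum(parc$voxel_count[ix])
  })
  expect_equal(
    ls$network$value[match(names(manual), ls$network$network)],
    as.numeric(manual),
    tolerance = 1e-12
  )

  # betas equal to the gradient with equal weights: network mean of g^2
  eqp <- toy_parcellation(3)
  ls2 <- loading_scores(
    tibble::tibble(roi_id = eqp$roi_id, beta = g), g, eqp
  )
  m2 <- tapply(g^2, eqp$network, mean)
  expect_equal(
    ls2$network$value[match(names(m2), ls2$network$network)],
    as.numeric(m2),
    tolerance = 1e-12
  )
})

test_that("activation-gradient correlation behaves at its anchors", {
  set.seed(3)
  g <- rnorm(80)
  expect_equal(activation_gradient_correlation(g, g)$r, 1)
  b <- rnorm(80)
  b_orth <- residuals(lm(b ~ g))
  expect_lt(abs(activation_gradient_correlation(b_orth, g)$r), 1e-10)
})

test_that("group coupling permutation test is calibrated and symmetric", {
  set.seed(6)
  g <- rnorm(40)
  mk_betas <- function(ids, noise = 1) {
    purrr::map_dfr(ids, function(id) {
      tibble::tibble(
        subject_id = id, roi_id = sprintf("r%02d", 1:40),
        beta = g + rnorm(40, sd = noise)
      )
    })
  }
  betas_a <- mk_betas(sprintf("A%d", 1:5))
  betas_b <- betas_a
  betas_b$subject_id <- sub("A", "B", betas_b$subject_id)
  groups <- stats::setNames(
    rep(c("A", "B"), each = 5),
    c(sprintf("A%d", 1:5), sprintf("B%d", 1:5))
  )
  dup <- group_coupling_permutation_test(
    rbind(betas_a, betas_b), groups, g,
    n_perm = 200, seed = 1
  )
  expect_equal(dup$statistic, 0)
  expect_equal(dup$p.value, 1)

  # p-values carry the add-one correction and live in (0, 1]
  betas_b2 <- mk_betas(sprintf("B%d", 1:5), noise = 3)
  res <- group_coupling_permutation_test(
    rbind(betas_a, betas_b2), groups, g,
    n_perm = 200, seed = 2
  )
  expect_gte(res$p.value, 1 / 201)
  expect_lte(res$p.value, 1)
  expect_error(
    group_coupling_permutation_test(rbind(betas_a, betas_b2), groups, g, n_perm = 10),
    "n_perm"
  )
})

test_that("planted decoupling is detected by the coupling test", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    R <- 70
    net <- rep(1:7, each = 10)
    g <- seq(0, 1, length.out = R) + rnorm(R, sd = 0.05)
    ids_a <- sprintf("A%02d", 1:30)
    ids_b <- sprintf("B%02d", 1:30)
    mk <- function(id, decouple) {
      b <- g + rnorm(R, sd = 0.4)
      if (decouple) {
        for (m in 1:7) {
          ix <- which(net == m)
          b[ix] <- b[sample(ix)]
        }
      }
      tibble::tibble(subject_id = id, roi_id = sprintf("r%02d", 1:R), beta = b)
    }
    betas <- dplyr::bind_rows(
      purrr::map_dfr(ids_a, mk, decouple = FALSE),
      purrr::map_dfr(ids_b, mk, decouple = TRUE)
    )
    groups <- stats::setNames(rep(c("A", "B"), each = 30), c(ids_a, ids_b))
    group_coupling_permutation_test(betas, groups, g,
      n_perm = 500, seed = seed
    )$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("gradient preference test handles identical and swapped gradients", {
  set.seed(11)
  b <- rnorm(60)
  g1 <- b + rnorm(60, sd = 0.3)
  same <- gradient_preference_test(b, g1, g1, n_perm = 200, seed = 3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  g2 <- b + rnorm(60, sd = 3)
  fwd <- gradient_preference_test(b, g1, g2, n_perm = 400, seed = 4)
  rev <- gradient_preference_test(b, g2, g1, n_perm = 400, seed = 4)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p.value, rev$p.value)
  expect_gt(fwd$statistic, 0)
  expect_lt(fwd$p.value, 0.05)
})

test_that("correlation statistics ignore positive affine rescaling of betas", {
  set.seed(13)
  g <- rnorm(50)
  b <- g + rnorm(50)
  r1 <- activation_gradient_correlation(b, g)
  r2 <- activation_gradient_correlation(3 * b + 10, g)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)

  p1 <- gradient_preference_test(b, g, rev(g), n_perm = 200, seed = 5)
  p2 <- gradient_preference_test(2 * b + 1, g, rev(g), n_perm = 200, seed = 5)
  expect_equal(p1$statistic, p2$statistic, tolerance = 1e-12)
  expect_equal(p1$p.value, p2$p.value)
})
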