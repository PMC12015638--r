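#' Quade-style nonparametric ANCOVA
#'
#' Ranks the response and each covariate across all subjects, residualizes
#' the ranked response on the ranked covariates by least squares, and runs
#' a one-way ANOVA F test on the residuals by group (df k-1, n-k). With no
#' covariates this reduces to a one-way ANOVA on ranks.
#'
#' @param y Numeric response, one value per subject.
#' @param group Group labels (2 or more groups, each with at least 2
#'   subjects).
#' @param covariates Optional numeric matrix or data frame of covariates
#'   (complete cases required).
#' @return A tibble with `statistic` (F), `df1`, `df2`, `p`.
#' @export
quade_ancova <- function(y, group, covariates = NULL) {
  y <- as.numeric(y)
  group <- factor(group)
  n <- length(y)
  if (anyNA(y)) stop("response contains missing values", call. = FALSE)
  if (stats::var(y) == 0) stop("response is constant", call. = FALSE)
  if (nlevels(group) < 2 || min(table(group)) < 2) {
    stop("need at least 2 groups with at least 2 subjects each", call. = FALSE)
  }
  ry <- rank(y)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(as.data.frame(covariates))
    if (nrow(cv) != n) stop("covariate rows must match subjects", call. = FALSE)
    if (anyNA(cv)) stop("covariates contain missing values", call. = FALSE)
    rc <- apply(cv, 2, rank)
    res <- stats::lm.fit(cbind(1, rc), ry)$residuals
  } else {
    res <- ry - mean(ry)
  }
  fit <- stats::lm(res ~ group)
  an <- stats::anova(fit)
  k <- nlevels(group)
  Fv <- an$`F value`[1]
  tibble::tibble(
    statistic = Fv,
    df1 = k - 1,
    df2 = n - k,
    p = stats::pf(Fv, k - 1, n - k, lower.tail = FALSE)
  )
}

#' Mann-Whitney U test
#'
#' Exact two-sided test when both groups have at most 12 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. The reported U counts pairs where an `x` exceeds
#' a `y`.
#'
#' @param x,y Numeric samples.
#' @return A tibble with `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 12 && length(y) <= 12
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    U = unname(wt$statistic),
    p = min(1, wt$p.value),
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Covariate-adjusted Pearson correlation
#'
#' Residualizes both variables on an intercept plus the covariates by least
#' squares, correlates the residuals, and tests with
#' `n - #covariates - 2` degrees of freedom. With no covariates this is the
#' plain Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix or data frame.
#' @return A tibble with `r`, `p`, `df`, `n`.
#' @export
adjusted_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  q <- 0
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(cv) == n)
    q <- ncol(cv)
    X <- cbind(1, cv)
    x <- stats::lm.fit(X, x)$residuals
    y <- stats::lm.fit(X, y)$residuals
  }
  if (n <= q + 2) stop("too few observations for the covariate count", call. = FALSE)
  df <- n - q - 2
  # a variable fully explained by the covariates has no residual variation
  if (stats::sd(x) < 1e-10 || stats::sd(y) < 1e-10) {
    return(tibble::tibble(r = 0, p = 1, df = df, n = n))
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df, n = n)
}

#' Per-network group comparison with FDR control
#'
#' Runs a covariate-adjusted rank ANCOVA ([quade_ancova()]) per network and
#' adjusts the raw p-values across the networks of one measure family by
#' Benjamini-Hochberg.
#'
#' @param values A tibble with columns `subject_id`, `network`, `value`
#'   (one value per subject and network).
#' @param subjects Subject table with `subject_id`, `group`, and covariate
#'   columns.
#' @param measure Name of the measure family (recorded in the output).
#' @param covariates Character vector of covariate column names in
#'   `subjects` (default `c("age", "sex", "education", "moca")`); use
#'   `character(0)` for unadjusted comparisons.
#' @return A tibble of class `fcg_comparison` with one row per network:
#'   `measure`, `network`, `statistic`, `df1`, `df2`, `p_unc`, `p_fdr`,
#'   group sizes, and the covariates used.
#' @export
compare_networks <- function(values, subjects, measure = "measure",
                             covariates = c("age", "sex", "education", "moca")) {
  need <- c("subject_id", "network", "value")
  miss <- setdiff(need, names(values))
  if (length(miss) > 0) stop("values missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  covariates <- intersect(covariates, names(subjects))
  tbl <- dplyr::inner_join(values, subjects, by = "subject_id")
  if (anyNA(tbl$value)) {
    stop("per-subject network values must be complete", call. = FALSE)
  }
  groups <- sort(unique(tbl$group))
  nets <- intersect(yeo7_networks(), unique(tbl$network))
  rows <- purrr::map_dfr(nets, function(nw) {
    sub <- tbl[tbl$network == nw, ]
    cv <- if (length(covariates) > 0) sub[, covariates, drop = FALSE] else NULL
    qa <- quade_ancova(sub$value, sub$group, cv)
    dplyr::bind_cols(tibble::tibble(measure = measure, network = nw), qa)
  })
  rows$p_fdr <- bh_fdr(rows$p)
  rows <- dplyr::rename(rows, p_unc = "p")
  sizes <- table(subjects$group)
  rows$n_A <- as.integer(sizes[groups[1]])
  rows$n_B <- if (length(groups) > 1) as.integer(sizes[groups[2]]) else NA_integer_
  rows$covariates <- paste(covariates, collapse = ",")
  class(rows) <- c("fcg_comparison", class(rows))
  rows
}
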