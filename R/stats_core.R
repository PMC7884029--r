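# Shared statistical kernel: covariate-adjusted linear-model tests,
# multiple-testing adjustment, exact contingency tests and meta-analysis.

# Build a covariate design block (no intercept column) from a data.frame,
# matrix or NULL. Factors are expanded to treatment contrasts.
covariate_block <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.matrix(covariates)) {
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n) stop2("covariates have wrong number of rows")
    return(covariates)
  }
  if (is.data.frame(covariates)) {
    if (nrow(covariates) != n) stop2("covariates have wrong number of rows")
    mm <- stats::model.matrix(~ ., data = covariates)
    return(mm[, -1, drop = FALSE])
  }
  stop2("covariates must be NULL, a matrix, or a data.frame")
}

check_full_rank <- function(X, what = "design matrix") {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop2("rank-deficient ", what, "; collinear column(s): ",
          paste(dropped, collapse = ", "))
  }
  qx
}

#' Covariate-adjusted ANOVA F-test for a three-level group factor
#'
#' Compares a full ordinary-least-squares model (intercept + covariates +
#' group indicators) against the reduced model without the group indicators,
#' the standard nested-model F-test used for per-aptamer differential
#' abundance across centenarians, offspring and controls.
#'
#' @param y numeric response vector (typically log-RFU of one aptamer).
#' @param group factor; all observed levels enter the full model.
#' @param covariates optional data.frame or numeric matrix of adjustment
#'   covariates (e.g. sex and collection year); no intercept column.
#' @return list with `statistic` (F), `p_value`, `df` (numerator,
#'   denominator), `group_means` (covariate-adjusted group means at the mean
#'   covariate profile) and `effect` (max adjusted difference from the first
#'   level).
#' @details A constant response returns F = 0, p = 1 so that expressionless
#'   aptamers flow through a genome-scale screen rather than erroring.
#' @export
fit_anova_f <- function(y, group, covariates = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop2("y contains missing values")
  group <- droplevels(as.factor(group))
  n <- length(y)
  if (length(group) != n) stop2("y and group lengths differ")
  res <- anova_f_matrix(matrix(y, ncol = 1), group, covariates)
  gm <- drop(res$group_means)
  names(gm) <- levels(group)
  list(statistic = res$F[1], p_value = res$p[1],
       df = c(df1 = res$df1, df2 = res$df2),
       group_means = gm,
       effect = max(gm) - min(gm))
}

# Vectorized nested-OLS F-test over the columns of a response matrix.
# Returns per-column F, p and the covariate-adjusted group means
# (levels x m), computed at the mean covariate profile.
anova_f_matrix <- function(Y, group, covariates = NULL) {
  n <- nrow(Y)
  group <- droplevels(as.factor(group))
  if (length(group) != n) stop2("group length does not match rows of Y")
  if (nlevels(group) < 2) stop2("group must have at least two levels")
  C <- covariate_block(covariates, n)
  Xr <- cbind(`(Intercept)` = 1, C)
  G <- stats::model.matrix(~ group)[, -1, drop = FALSE]
  Xf <- cbind(Xr, G)
  qf <- check_full_rank(Xf, "full-model design")
  qr_ <- qr(Xr)

  rss_full <- colSums(qr.resid(qf, Y)^2)
  rss_red <- colSums(qr.resid(qr_, Y)^2)
  df1 <- ncol(G)
  df2 <- n - ncol(Xf)
  if (df2 <= 0) stop2("not enough residual degrees of freedom")
  Fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  # constant (or perfectly fitted by the reduced model) response: F = 0, p = 1
  degenerate <- rss_full <= .Machine$double.eps * n *
    pmax(colMeans(Y^2), 1) & (rss_red - rss_full) <= .Machine$double.eps * n
  Fstat[!is.finite(Fstat)] <- 0
  Fstat[degenerate] <- 0
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  B <- qr.coef(qf, Y)                      # k x m coefficients
  B[is.na(B)] <- 0
  cbar <- if (ncol(C) > 0) colMeans(C) else numeric(0)
  # adjusted mean of level l = intercept + level coef + cbar' beta_cov
  base <- c(1, cbar, rep(0, ncol(G)))
  L <- matrix(rep(base, nlevels(group)), nrow = nlevels(group), byrow = TRUE)
  if (ncol(G) > 0) {
    for (j in seq_len(ncol(G))) L[j + 1, 1 + length(cbar) + j] <- 1
  }
  group_means <- L %*% B
  rownames(group_means) <- levels(group)
  list(F = Fstat, p = p, df1 = df1, df2 = df2, group_means = group_means)
}

#' Covariate-adjusted two-group test via the OLS indicator coefficient
#'
#' Fits intercept + covariates + binary indicator by ordinary least squares
#' and reports the indicator coefficient with its two-sided t-test, the
#' per-aptamer model behind the survival signatures and the
#' offspring-versus-control contrast.
#'
#' @param y numeric response vector (log scale).
#' @param indicator two-level factor or 0/1 vector; the effect is the
#'   coefficient of the second level versus the first.
#' @param covariates optional data.frame or matrix of adjustment covariates.
#' @return list with `statistic` (t), `p_value`, `effect` (log-scale
#'   coefficient), `se` and `df`.
#' @export
fit_binary_adjusted <- function(y, indicator, covariates = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop2("y contains missing values")
  ind <- droplevels(as.factor(indicator))
  if (nlevels(ind) != 2) stop2("indicator must have exactly two observed levels")
  res <- binary_t_matrix(matrix(y, ncol = 1), ind, covariates)
  list(statistic = res$t[1], p_value = res$p[1], effect = res$effect[1],
       se = res$se[1], df = res$df)
}

# Vectorized OLS indicator t-test over the columns of a response matrix.
binary_t_matrix <- function(Y, indicator, covariates = NULL) {
  n <- nrow(Y)
  ind <- droplevels(as.factor(indicator))
  if (length(ind) != n) stop2("indicator length does not match rows of Y")
  if (nlevels(ind) != 2) stop2("indicator must have exactly two observed levels")
  C <- covariate_block(covariates, n)
  X <- cbind(`(Intercept)` = 1, C, indicator = as.numeric(ind) - 1)
  qx <- check_full_rank(X, "design")
  k <- ncol(X)
  df <- n - k
  if (df <= 0) stop2("not enough residual degrees of freedom")
  B <- qr.coef(qx, Y)
  resid <- qr.resid(qx, Y)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  v_ind <- XtXinv[k, k]
  effect <- B[k, ]
  se <- sqrt(sigma2 * v_ind)
  t <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, sign(effect) * Inf))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, p = p, effect = effect, se = se, df = df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; selection at q < f controls the
#' FDR at level f. Input order is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test with the minimum-likelihood two-sided definition:
#' the p-value sums hypergeometric probabilities of all tables with the same
#' margins whose point probability does not exceed that of the observed
#' table (up to a 1 + 1e-7 relative tolerance for ties). Also returns the
#' sample odds ratio ad/bc (infinite when bc = 0).
#'
#' @param tab 2x2 matrix of non-negative integer counts, rows = first
#'   classification, columns = second.
#' @return list with `p_value`, `odds_ratio` and the observed table.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop2("tab must be a 2x2 matrix")
  if (anyNA(tab) || any(tab < 0)) stop2("counts must be non-negative")
  if (any(abs(tab - round(tab)) > 1e-8)) stop2("counts must be integers")
  tab <- round(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (n == 0) return(list(p_value = 1, odds_ratio = NaN, table = tab))
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- stats::dhyper(support, r1, r2, c1, log = TRUE)
  obs <- logp[support == a]
  keep <- logp <= obs + log1p(1e-7)
  p <- exp(logsumexp(logp[keep]))
  p <- min(p, 1)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(p_value = p, odds_ratio = or, table = tab)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= x) for X ~ Hypergeometric(N, K, n): drawing n items without
#' replacement from a universe of N containing K marked items. Computed by
#' log-space summation over the support; the one-sided companion of
#' [fisher_exact_2x2()] used for over-representation sanity checks.
#'
#' @param N universe size; @param K marked count; @param n draw count;
#' @param x observed overlap.
#' @return probability in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(N, K, n, x) {
  if (any(c(N, K, n, x) < 0) || K > N || n > N || x > min(n, K)) {
    stop2("inconsistent hypergeometric counts")
  }
  if (x <= max(0, n + K - N)) return(1)
  support <- x:min(n, K)
  exp(logsumexp(stats::dhyper(support, K, N - K, n, log = TRUE)))
}

#' Stouffer weighted signed-z meta-analysis
#'
#' Combines signed per-study z-scores as
#' z_meta = sum(w_i z_i) / sqrt(sum(w_i^2)), with a two-sided normal p-value.
#' With w = sqrt(study sample size) this is the classic sample-size-weighted
#' combination requiring only the sign, p and n that aging studies exchange.
#'
#' @param z signed z-scores, one per study.
#' @param w positive weights; defaults to equal weights.
#' @return list with `statistic` (meta z) and `p_value`.
#' @export
stouffer_meta <- function(z, w = rep(1, length(z))) {
  if (length(z) == 0) stop2("empty z input")
  if (length(w) != length(z)) stop2("z and w lengths differ")
  if (any(!is.finite(z))) stop2("z must be finite")
  if (any(w <= 0)) stop2("weights must be positive")
  zm <- sum(w * z) / sqrt(sum(w^2))
  list(statistic = zm, p_value = 2 * stats::pnorm(-abs(zm)))
}

#' Total sample size for a two-group comparison (normal approximation)
#'
#' n_total = 4 ((z_{1-alpha/2} + z_{power}) / d)^2, rounded up: the textbook
#' closed form for a balanced two-arm comparison of a standardized mean
#' difference d.
#'
#' @param effect_d standardized difference (> 0).
#' @param alpha two-sided type-I level.
#' @param power target power.
#' @return integer total sample size.
#' @export
required_n_two_group <- function(effect_d, alpha = 0.05, power = 0.8) {
  if (effect_d <= 0) stop2("effect_d must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop2("alpha and power must lie in (0, 1)")
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(4 * (z / effect_d)^2))
}
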