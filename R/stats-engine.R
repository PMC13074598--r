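# From-scratch implementations of the statistical procedures used by the
# transplant analysis: sums-of-squares ANOVA, variance-ratio F-test, exact
# Wilcoxon rank-sum, Pearson/Spearman correlation, standardized OLS and the
# permutation Mantel test. Base-R distribution functions supply tail
# probabilities; everything else is computed here and cross-checked against
# independent oracles in the test suite.

# --- ANOVA -------------------------------------------------------------------

.anova_table <- function(term, df, ss) {
  ms <- ifelse(df > 0, ss / df, NA_real_)
  out <- data.frame(term = term, df = df, ss = ss, ms = ms,
                    f = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("anova_table", class(out))
  out
}

#' One-way analysis of variance
#'
#' Between/within sums-of-squares decomposition with `F = MSB / MSW` and the
#' p-value from the F distribution on (k - 1, N - k) degrees of freedom.
#'
#' @param values Numeric vector of observations, or a list of group vectors
#'   (in which case `groups` is ignored).
#' @param groups Group labels, same length as `values`.
#' @return An `anova_table` data frame with rows for the between-group term
#'   and the error. A zero within- and between-group variance yields `NA` F
#'   (flagged by warning); zero within with non-zero between yields `Inf` F
#'   and p = 0.
#' @export
one_way_anova <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  out <- .anova_table(c("between", "error"), c(dfb, dfw), c(ssb, ssw))
  if (ssw == 0 && ssb == 0) {
    warning("no variance at all: F undefined", call. = FALSE)
  } else {
    msw <- ssw / dfw
    f <- if (msw == 0) Inf else (ssb / dfb) / msw
    out$f[1] <- f
    out$p[1] <- if (is.infinite(f)) 0 else stats::pf(f, dfb, dfw,
                                                     lower.tail = FALSE)
  }
  out
}

#' Balanced two-way analysis of variance (2 x 2 crossed design)
#'
#' Marginal-means decomposition for a fully crossed two-factor design with
#' equal cell sizes (where Type I/II/III sums of squares coincide):
#' main-effect SS from factor marginal means, interaction SS from cell-mean
#' residuals, error SS within cells. Each term is tested against the error
#' mean square.
#'
#' @param y Response vector.
#' @param habitat,population Factors (any two crossed factors; named for the
#'   transplant design).
#' @return An `anova_table` with rows habitat, population,
#'   habitat:population, error. Unbalanced input is refused.
#' @export
two_way_anova_balanced <- function(y, habitat, population) {
  habitat <- factor(habitat)
  population <- factor(population)
  stopifnot(length(y) == length(habitat), length(y) == length(population))
  if (anyNA(y)) {
    stop("missing response values: the balanced decomposition requires ",
         "complete cells", call. = FALSE)
  }
  cells <- table(habitat, population)
  if (any(cells == 0)) stop("design is not fully crossed", call. = FALSE)
  if (length(unique(as.vector(cells))) != 1) {
    stop("unbalanced design: this decomposition requires equal cell sizes; ",
         "balance the data or analyze cells separately", call. = FALSE)
  }
  if (cells[1] < 2) stop("cell size must be >= 2", call. = FALSE)
  grand <- mean(y)
  mh <- tapply(y, habitat, mean)
  mp <- tapply(y, population, mean)
  mc <- tapply(y, list(habitat, population), mean)
  nh <- tapply(y, habitat, length)
  np <- tapply(y, population, length)
  ss_h <- sum(nh * (mh - grand)^2)
  ss_p <- sum(np * (mp - grand)^2)
  n_cell <- cells[1]
  inter <- outer(mh, rep(1, nlevels(population))) +
    outer(rep(1, nlevels(habitat)), mp) - grand
  ss_hp <- n_cell * sum((mc - inter)^2)
  ss_e <- sum((y - mc[cbind(habitat, population)])^2)
  df_h <- nlevels(habitat) - 1
  df_p <- nlevels(population) - 1
  df_hp <- df_h * df_p
  df_e <- length(y) - nlevels(habitat) * nlevels(population)
  out <- .anova_table(c("habitat", "population", "habitat:population", "error"),
                      c(df_h, df_p, df_hp, df_e),
                      c(ss_h, ss_p, ss_hp, ss_e))
  mse <- ss_e / df_e
  if (mse == 0 && all(c(ss_h, ss_p, ss_hp) == 0)) {
    warning("constant response: all F undefined", call. = FALSE)
    return(out)
  }
  for (i in 1:3) {
    f <- if (mse == 0) Inf else out$ms[i] / mse
    out$f[i] <- f
    out$p[i] <- if (is.infinite(f)) 0 else stats::pf(f, out$df[i], df_e,
                                                     lower.tail = FALSE)
  }
  out
}

# --- Variance-ratio F-test ---------------------------------------------------

#' Two-sided F-test of equality of variances
#'
#' `F = var(a) / var(b)` in the given group order (ratios below 1 are
#' reported as such, not inverted), with the two-sided p-value
#' `2 * min(P(F <= f), P(F >= f))` on (n_a - 1, n_b - 1) degrees of freedom.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @return A `test_result` list: statistic, df, p_value, method, sidedness.
#' @export
variance_ratio_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (vb == 0) {
    warning("zero variance in denominator group: F undefined", call. = FALSE)
    return(.test_result(NA_real_, NA_real_, "variance-ratio F",
                        df = c(length(a) - 1, length(b) - 1)))
  }
  f <- va / vb
  df1 <- length(a) - 1
  df2 <- length(b) - 1
  lower <- stats::pf(f, df1, df2)
  p <- min(1, 2 * min(lower, 1 - lower))
  .test_result(f, p, "variance-ratio F", df = c(df1, df2))
}

.test_result <- function(statistic, p, method, ...) {
  structure(c(list(statistic = statistic, p_value = p, method = method,
                   sidedness = "two.sided"), list(...)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

# --- Wilcoxon rank-sum -------------------------------------------------------

# Distribution of the rank-sum of n1 items drawn from integer ranks 1..N,
# by subset-sum dynamic programming (counts of size-k subsets by sum).
.rank_sum_distribution <- function(n1, n2) {
  n <- n1 + n2
  smax <- sum((n - n1 + 1):n)
  # counts[k + 1, s + 1] = number of k-subsets of 1..i with sum s
  counts <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  counts[1, 1] <- 1
  for (i in seq_len(n)) {
    for (k in min(i, n1):1) {
      upto <- smax - i
      if (upto >= 0) {
        src <- counts[k, 1:(upto + 1)]
        counts[k + 1, (i + 1):(smax + 1)] <-
          counts[k + 1, (i + 1):(smax + 1)] + src
      }
    }
  }
  probs <- counts[n1 + 1, ] / choose(n, n1)
  names(probs) <- 0:smax
  probs
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic `W` (sum of the ranks of `a` in the pooled sample,
#' midranks for ties). The exact two-sided p-value is computed by
#' enumeration of the rank-sum distribution when `mode = "exact"`, or when
#' `mode = "auto"` with `n_a + n_b <= 20` and no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' Two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b Numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return A `test_result` with `statistic` (rank sum of `a`), `p_value`,
#'   `n` per group and a `ties` flag.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(pooled) > 0
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal_approx = FALSE,
                      auto = n <= 20 && !ties)
  if (use_exact && ties) {
    warning("ties present: exact enumeration assumes distinct ranks; ",
            "falling back to the normal approximation", call. = FALSE)
    use_exact <- FALSE
  }
  if (use_exact) {
    dist <- .rank_sum_distribution(n1, n2)   # indexed by sum 0..smax
    idx <- as.integer(round(w)) + 1L
    lower <- sum(dist[seq_len(idx)])
    upper <- sum(dist[idx:length(dist)])
    p <- min(1, 2 * min(lower, upper))
    method <- "Wilcoxon rank-sum (exact)"
  } else {
    mu <- n1 * (n + 1) / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon rank-sum (normal approximation)"
  }
  .test_result(w, p, method, n = c(n1, n2), ties = ties)
}

# --- Correlation -------------------------------------------------------------

#' Pearson product-moment correlation with t-based p-value
#'
#' `r` by the product-moment formula; two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3), pairwise complete.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("pearson_corr needs n >= 3 complete pairs", call. = FALSE)
  sx <- x - mean(x); sy <- y - mean(y)
  denom <- sqrt(sum(sx^2) * sum(sy^2))
  if (denom == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- sum(sx * sy) / denom
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p_value = p, n = n)
}

# all permutations of 1..n (n! rows); recursive, fine for n <= 9
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. The two-sided p-value is exact by
#' enumeration of all n! rank permutations for n <= `exact_max` (default 9),
#' and uses the t approximation on the rank correlation otherwise.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @param exact_max Largest n for which full enumeration is used.
#' @return List with `rho`, `p_value`, `n`, `exact` flag.
#' @export
spearman_corr <- function(x, y, exact_max = 9) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman_corr needs n >= 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  base <- pearson_corr(rx, ry)
  rho <- base$r
  if (is.na(rho)) return(list(rho = NA_real_, p_value = NA_real_, n = n,
                              exact = FALSE))
  if (n <= exact_max) {
    perms <- .all_perms(n)
    # rho is affine in sum(rx * ry_perm) for fixed marginal rank sets
    sxx <- sum((rx - mean(rx))^2)
    syy <- sum((ry - mean(ry))^2)
    cross <- apply(perms, 1, function(p) sum(rx * ry[p]))
    rho_perm <- (cross - n * mean(rx) * mean(ry)) / sqrt(sxx * syy)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    return(list(rho = rho, p_value = p, n = n, exact = TRUE))
  }
  if (abs(rho) == 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p_value = p, n = n, exact = FALSE)
}

#' Pairwise correlation matrix with p-values
#'
#' @param df Data frame or matrix of numeric columns (traits).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `correlation_matrix` list: `r` (symmetric, unit diagonal), `p`,
#'   `n`, `method`, `labels`.
#' @export
corr_matrix <- function(df, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- as.data.frame(df)
  labs <- names(df)
  k <- length(labs)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); nmat <- matrix(NA_real_, k, k)
  diag(p) <- NA
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- if (method == "pearson") pearson_corr(df[[i]], df[[j]])
             else spearman_corr(df[[i]], df[[j]])
      coef <- if (method == "pearson") res$r else res$rho
      r[i, j] <- r[j, i] <- coef
      p[i, j] <- p[j, i] <- res$p_value
      nmat[i, j] <- nmat[j, i] <- res$n
    }
  }
  dimnames(r) <- dimnames(p) <- dimnames(nmat) <- list(labs, labs)
  structure(list(r = r, p = p, n = nmat, method = method, labels = labs),
            class = "correlation_matrix")
}

# --- Mantel test -------------------------------------------------------------

.lower_tri <- function(m) m[lower.tri(m)]

#' Permutation Mantel test between two square symmetric matrices
#'
#' The observed statistic is the Pearson correlation of the vectorized lower
#' triangles (diagonal excluded). The null distribution is generated by
#' simultaneously permuting the rows and columns of the second matrix. With
#' `exact = TRUE` (or n <= `exact_max`) all n! permutations are enumerated and
#' the p-value is the fraction of permutations (including the identity) with a
#' statistic at least as extreme; otherwise `n_perm` random permutations give
#' `p = (count + 1) / (n_perm + 1)`.
#'
#' @param m1,m2 Square symmetric numeric matrices of the same dimension >= 3.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param alternative `"greater"` (default, the usual matrix-association
#'   alternative) or `"two.sided"`.
#' @param exact Force full enumeration (n! permutations).
#' @param exact_max Enumerate whenever the matrix dimension is at most this.
#' @return A `mantel_result` list: `r_observed`, `p_value`, `n_perm` (or the
#'   enumeration count), `alternative`, `seed`, `exact`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = 1,
                        alternative = c("greater", "two.sided"),
                        exact = FALSE, exact_max = 0) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2)) || nrow(m1) != ncol(m1)) {
    stop("mantel_test needs two square matrices of equal dimension",
         call. = FALSE)
  }
  n <- nrow(m1)
  if (n < 3) stop("mantel_test needs dimension >= 3", call. = FALSE)
  if (max(abs(m1 - t(m1))) > 1e-8 || max(abs(m2 - t(m2))) > 1e-8) {
    stop("mantel_test needs symmetric matrices", call. = FALSE)
  }
  v1 <- .lower_tri(m1)
  if (stats::sd(v1) == 0 || stats::sd(.lower_tri(m2)) == 0) {
    warning("constant off-diagonal: Mantel r undefined", call. = FALSE)
    return(structure(list(r_observed = NA_real_, p_value = NA_real_,
                          n_perm = 0, alternative = alternative, seed = seed,
                          exact = FALSE), class = "mantel_result"))
  }
  stat <- function(perm) {
    stats::cor(v1, .lower_tri(m2[perm, perm]))
  }
  r_obs <- stat(seq_len(n))
  extreme <- function(r_perm) {
    if (alternative == "greater") r_perm >= r_obs - 1e-12
    else abs(r_perm) >= abs(r_obs) - 1e-12
  }
  if (exact || n <= exact_max) {
    perms <- .all_perms(n)
    r_perm <- apply(perms, 1, stat)
    p <- mean(extreme(r_perm))
    res <- list(r_observed = r_obs, p_value = p, n_perm = nrow(perms),
                alternative = alternative, seed = seed, exact = TRUE)
  } else {
    set.seed(as.integer(seed))
    r_perm <- vapply(seq_len(n_perm), function(i) stat(sample.int(n)),
                     numeric(1))
    p <- (sum(extreme(r_perm)) + 1) / (n_perm + 1)
    res <- list(r_observed = r_obs, p_value = p, n_perm = n_perm,
                alternative = alternative, seed = seed, exact = FALSE)
  }
  structure(res, class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %s permutations)\n",
              x$r_observed, x$p_value, x$alternative,
              if (x$exact) paste0("all ", x$n_perm) else x$n_perm))
  invisible(x)
}

# --- Standardized OLS --------------------------------------------------------

#' Standardized multiple regression
#'
#' Z-scores the response and every predictor (mean 0, sd 1) and fits ordinary
#' least squares with an intercept (which is 0 by construction). The
#' standardized coefficients are directly comparable effect sizes.
#'
#' @param y Response vector.
#' @param predictors Numeric matrix or data frame of predictors.
#' @return A `standardized_ols` list: `coefficients` data frame (estimate,
#'   se, t, p per predictor), `r_squared`, `f_statistic`, `f_p_value`,
#'   `df_residual`, `n`.
#' @export
standardized_ols <- function(y, predictors) {
  X <- as.matrix(as.data.frame(predictors))
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > number of predictors + 1", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0) || stats::sd(y) == 0) {
    stop("zero-variance variable cannot be standardized", call. = FALSE)
  }
  Z <- scale(X)
  zy <- as.vector(scale(y))
  D <- cbind(`(Intercept)` = 1, Z)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    dep <- colnames(D)[qrd$pivot[(qrd$rank + 1):ncol(D)]]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrd, zy)
  resid <- zy - D %*% beta
  df_res <- n - ncol(D)
  sigma2 <- sum(resid^2) / df_res
  xtx_inv <- chol2inv(qr.R(qrd))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  sst <- sum(zy^2)           # response is centered: TSS = sum of squares
  ssr <- sum(resid^2)
  r2 <- 1 - ssr / sst
  f <- (r2 / p) / ((1 - r2) / df_res)
  fp <- stats::pf(f, p, df_res, lower.tail = FALSE)
  coefs <- data.frame(predictor = colnames(D)[-1],
                      estimate = beta[-1], se = se[-1], t = tval[-1],
                      p = pval[-1], row.names = NULL)
  structure(list(coefficients = coefs, r_squared = r2, f_statistic = f,
                 f_p_value = fp, df_residual = df_res, n = n),
            class = "standardized_ols")
}

#' @export
print.standardized_ols <- function(x, ...) {
  cat(sprintf("Standardized OLS: R^2 = %.4f, F = %.4g (p = %.4g), n = %d\n",
              x$r_squared, x$f_statistic, x$f_p_value, x$n))
  print(x$coefficients)
  invisible(x)
}

#' Significance stars
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001 (strict inequalities at each boundary).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
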