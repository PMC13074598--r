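# Independent brute-force oracles, deliberately written without reusing any
# package internals: full enumeration references for the exact tests.

# all C(n1+n2, n1) labelings of the pooled sample
brute_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# recursive permutation generator shared by the enumeration oracles
perm_rec <- function(rest) {
  if (length(rest) == 1) return(list(rest))
  out <- list()
  for (k in seq_along(rest)) {
    for (tail in perm_rec(rest[-k])) out[[length(out) + 1]] <- c(rest[k], tail)
  }
  out
}

# all n! rank permutations
brute_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  rhos <- vapply(perm_rec(seq_len(n)),
                 function(p) stats::cor(rx, ry[p]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# all 4! simultaneous row/column permutations
brute_mantel_p <- function(m1, m2, alternative = "greater") {
  lt <- function(m) m[lower.tri(m)]
  r_obs <- stats::cor(lt(m1), lt(m2))
  rs <- vapply(perm_rec(seq_len(nrow(m1))),
               function(p) stats::cor(lt(m1), lt(m2[p, p])), numeric(1))
  if (alternative == "greater") mean(rs >= r_obs - 1e-12)
  else mean(abs(rs) >= abs(r_obs) - 1e-12)
}

rand_sym <- function(n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  m <- m + t(m)
  diag(m) <- 1
  m
}
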