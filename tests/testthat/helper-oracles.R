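# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately re-derive each quantity from first
# principles (enumeration, direct formulas) and never call the functions
# they check.

# --- Wilcoxon signed-rank: exhaustive sign-flip enumeration -------------
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 15, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# --- Fisher 2x2: hypergeometric point-probability enumeration -----------
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Benjamini-Hochberg step-up, written directly from the definition ---
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# --- average ranks computed by counting, for the Spearman tie check -----
oracle_avg_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

oracle_spearman_rho <- function(x, y) {
  rx <- oracle_avg_rank(x); ry <- oracle_avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- coating-category rule applied directly to presence bits ------------
# bits: named logical vector over (class, status) presence of one ASV
oracle_classify_bits <- function(coated_plus, coated_minus, in_noncoated) {
  if (coated_plus && coated_minus) "shared"
  else if (coated_plus) "iga_only"
  else if (coated_minus) "igm_only"
  else if (in_noncoated) "strictly_non_coated"
  else "unobserved"
}

# --- AND-of-OR rule satisfaction by direct set logic --------------------
oracle_rule_satisfied <- function(profile, groups) {
  for (g in groups) if (length(intersect(g, profile)) == 0) return(FALSE)
  TRUE
}
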