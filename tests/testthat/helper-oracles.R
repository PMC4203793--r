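# Independent oracles used to cross-check package results.  These are
# deliberate re-derivations from the definitions, not calls into the
# package's own code paths.

# Brute-force Benjamini-Hochberg step-up from the definition:
# adj_(i) = min_{j >= i} min(1, p_(j) * m / j), mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-part combined statistic recomputed from first principles on a
# label assignment: `pool` is the pooled abundance vector, `in_a` a
# logical selector for group A.  Returns c(stat, df).
oracle_two_part_stat <- function(pool, in_a) {
  x <- pool[in_a]; y <- pool[!in_a]
  n1 <- length(x); n2 <- length(y)
  nz <- pool > 0
  pbar <- mean(nz)
  if (pbar == 1) {
    r <- rank(pool)
    W <- sum(r[in_a])
    EW <- n1 * (n1 + n2 + 1) / 2
    t <- table(pool)
    V <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(t^3 - t) / ((n1 + n2) * (n1 + n2 - 1)))
    zw <- if (V > 0) (W - EW) / sqrt(V) else 0
    return(c(zw^2, 1))
  }
  zp <- if (pbar == 0) 0 else
    (mean(x > 0) - mean(y > 0)) /
      sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  m1 <- sum(x > 0); m2 <- sum(y > 0)
  if (m1 >= 1 && m2 >= 1) {
    v <- pool[nz]
    r <- rank(v)
    W <- sum(r[(in_a)[nz]])
    N <- m1 + m2
    EW <- m1 * (N + 1) / 2
    t <- table(v)
    V <- m1 * m2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    zw <- if (V > 0) (W - EW) / sqrt(V) else 0
    c(zp^2 + zw^2, 2)
  } else {
    c(zp^2, 1)
  }
}

# Monte-Carlo permutation p-value of the combined statistic under group
# relabeling, vectorized over B random relabelings.  Exploits that the
# pooled values (hence pooled presence fraction, nonzero ranks and tie
# structure) are permutation-invariant.
oracle_perm_p <- function(x, y, B = 1e5) {
  pool <- c(x, y)
  n <- length(pool); n1 <- length(x)
  obs <- oracle_two_part_stat(pool, seq_len(n) <= n1)[1]
  nzflag <- pool > 0
  nz <- sum(nzflag)
  pbar <- nz / n
  r_nz <- numeric(n)
  r_nz[nzflag] <- rank(pool[nzflag])
  t <- table(pool[nzflag])
  tie_term <- sum(t^3 - t)
  pick <- replicate(B, sample.int(n, n1))
  ind <- matrix(FALSE, n, B)
  ind[cbind(as.vector(pick), rep(seq_len(B), each = n1))] <- TRUE
  m1 <- colSums(ind & nzflag)
  n2 <- n - n1
  if (pbar == 1) {
    # no zeros anywhere: rank-sum on all values, df = 1 for every perm
    r_all <- rank(pool)
    W <- colSums(ind * r_all)
    EW <- n1 * (n + 1) / 2
    tt <- table(pool)
    V <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    zw <- if (V > 0) (W - EW) / sqrt(V) else rep(0, B)
    stat <- zw^2
  } else {
    p1 <- m1 / n1
    p2 <- (nz - m1) / n2
    zp <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    W <- colSums(ind * r_nz)
    m2 <- nz - m1
    EW <- m1 * (nz + 1) / 2
    V <- m1 * m2 / 12 * ((nz + 1) - tie_term / (nz * (nz - 1)))
    both <- m1 >= 1 & m2 >= 1 & V > 0
    zw <- numeric(B)
    zw[both] <- (W[both] - EW[both]) / sqrt(V[both])
    stat <- ifelse(m1 >= 1 & m2 >= 1, zp^2 + zw^2, zp^2)
  }
  mean(stat >= obs - 1e-12)
}

# small deterministic table used across tests
toy_table <- function() {
  m <- matrix(c(2, 1, 0,
                0, 3, 1,
                5, 0, 5,
                1, 1, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  taxon_table(m, groups = c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2"))
}
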