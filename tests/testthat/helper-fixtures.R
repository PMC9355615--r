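## Shared fixtures and independent brute-force oracles.  Oracle code here is
## deliberately written from scratch (no calls into the package's internal
## helpers) so that enumeration tests stay independent of the paths they
## check.

tiny_table <- function() {
  m <- matrix(c(5L, 0L, 2L,
                1L, 4L, 0L,
                0L, 3L, 3L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("o", 1:3)))
  m
}

rand_table <- function(n_samples, n_otus, depth, seed) {
  set.seed(seed)
  p <- rexp(n_otus)
  m <- t(sapply(seq_len(n_samples), function(i) rmultinom(1, depth, p)[, 1]))
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("o%03d", seq_len(n_otus)))
  m
}

## random symmetric "distance-like" matrix (signed ok) with zero diagonal
rand_sym <- function(n, seed, labels = sprintf("s%02d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- rnorm(n * (n - 1) / 2)
  m + t(m)
}

## symmetric matrix built from a given lower-triangle vector
sym_from_tri <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

## --- permutation enumeration (oracle-side; iterative, unlike the package's
## recursive generator)
oracle_perms <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    nxt <- matrix(0L, nrow(out) * k, k)
    r <- 0L
    for (pos in seq_len(k)) {
      for (i in seq_len(nrow(out))) {
        r <- r + 1L
        nxt[r, ] <- append(out[i, ], k, after = pos - 1L)
      }
    }
    out <- nxt
  }
  out
}

tri <- function(m) m[lower.tri(m)]

## exact Mantel p by full enumeration, two-sided on |r|
oracle_mantel_exact <- function(dx, dy) {
  P <- oracle_perms(nrow(dx))
  r_obs <- cor(tri(dx), tri(dy))
  rs <- apply(P, 1, function(p) cor(tri(dx[p, p]), tri(dy)))
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

## partial correlation via explicit residual regression
oracle_partial_r <- function(dx, dy, dz) {
  x <- tri(dx); y <- tri(dy); z <- tri(dz)
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  cor(rx, ry)
}

## exact partial-Mantel p: permute dx, recompute partial r with r_yz fixed
oracle_partial_mantel_exact <- function(dx, dy, dz) {
  P <- oracle_perms(nrow(dx))
  pr <- function(vx) {
    rxy <- cor(vx, tri(dy)); rxz <- cor(vx, tri(dz)); ryz <- cor(tri(dy), tri(dz))
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  r_obs <- pr(tri(dx))
  rs <- apply(P, 1, function(p) pr(tri(dx[p, p])))
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

## exact MRM p-values (coefficient |b| and model R2) via lm()
oracle_mrm_exact <- function(dy, predictors) {
  P <- oracle_perms(nrow(dy))
  X <- sapply(predictors, tri)
  X <- scale(X)
  y0 <- tri(dy)
  fit_one <- function(y) {
    y <- (y - mean(y0)) / sd(y0)
    f <- lm(y ~ X)
    list(coef = coef(f)[-1], r2 = summary(f)$r.squared)
  }
  obs <- fit_one(y0)
  stats <- lapply(seq_len(nrow(P)), function(b) fit_one(tri(dy[P[b, ], P[b, ]])))
  cnt <- colSums(do.call(rbind, lapply(stats, function(s)
    abs(s$coef) >= abs(obs$coef) - 1e-12)))
  list(coef = unname(obs$coef), r2 = obs$r2,
       p_coef = unname(cnt / nrow(P)),
       p_model = mean(sapply(stats, `[[`, "r2") >= obs$r2 - 1e-12))
}

## exact PERMANOVA p via direct pseudo-F formula over all label permutations
oracle_permanova_exact <- function(d, groups) {
  n <- nrow(d); a <- length(unique(groups)); d2 <- d^2
  f_of <- function(g) {
    sst <- sum(d2[lower.tri(d2)]) / n
    ssw <- sum(sapply(unique(g), function(lev) {
      idx <- g == lev
      sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / sum(idx)
    }))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  P <- oracle_perms(n)
  f_obs <- f_of(groups)
  fs <- apply(P, 1, function(p) f_of(groups[p]))
  list(F = f_obs, p = mean(fs >= f_obs - 1e-12))
}
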