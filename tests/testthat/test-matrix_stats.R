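test_that("mantel r is exact self-correlation and label-order invariant", {
  d <- rand_sym(7, seed = 1)
  m <- mantel(d, d, n_perm = 99, seed = 1)
  expect_equal(m$r, 1, tolerance = 1e-12)
  ## reordering sample labels leaves the statistic invariant
  dy <- rand_sym(7, seed = 2)
  ord <- c(3, 1, 7, 5, 2, 6, 4)
  m1 <- mantel(d, dy, exact = TRUE)
  m2 <- mantel(d[ord, ord], dy[ord, ord], exact = TRUE)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
  expect_equal(m1$p, m2$p)
  expect_error(mantel(d, rand_sym(7, seed = 3, labels = letters[1:7])), "labels")
})

test_that("exact Mantel and partial Mantel match brute-force enumeration", {
  for (seed in 1:3) {
    dx <- rand_sym(5, seed = seed)
    dy <- rand_sym(5, seed = seed + 10)
    dz <- rand_sym(5, seed = seed + 20)
    o <- oracle_mantel_exact(dx, dy)
    m <- mantel(dx, dy, exact = TRUE)
    expect_equal(m$r, o$r, tolerance = 1e-12)
    expect_identical(m$p, o$p)
    po <- oracle_partial_mantel_exact(dx, dy, dz)
    pm <- partial_mantel(dx, dy, dz, exact = TRUE)
    expect_equal(pm$r, po$r, tolerance = 1e-12)
    expect_identical(pm$p, po$p)
  }
})

test_that("partial Mantel r equals the residual-regression oracle", {
  for (seed in 4:8) {
    dx <- rand_sym(6, seed = seed)
    dy <- rand_sym(6, seed = seed + 30)
    dz <- rand_sym(6, seed = seed + 60)
    pm <- partial_mantel(dx, dy, dz, n_perm = 9, seed = 1)
    expect_equal(pm$r, oracle_partial_r(dx, dy, dz), tolerance = 1e-12)
  }
  ## control uncorrelated with both: partial r ~ plain r
  dx <- rand_sym(40, seed = 9); dy0 <- rand_sym(40, seed = 10)
  dy <- sym_from_tri(0.9 * tri(dx) + 0.4 * tri(dy0), rownames(dx))
  dz <- rand_sym(40, seed = 11)
  expect_equal(partial_mantel(dx, dy, dz, n_perm = 9)$r,
               mantel(dx, dy, n_perm = 9)$r, tolerance = 0.05)
  ## dy == dz: exact collinearity is rejected, not silently propagated
  expect_error(partial_mantel(dx, dy, dy, n_perm = 9), "collinear")
})

test_that("mantel p-values are uniform under the null", {
  ## calibration: independent random matrices, Kolmogorov-Smirnov against
  ## U(0,1); scaled down to 200 runs x 199 permutations
  ps <- vapply(1:200, function(s) {
    mantel(rand_sym(8, seed = 3000 + s), rand_sym(8, seed = 7000 + s),
           n_perm = 199, seed = s)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(all(ps >= 1 / 200))   # p floor at 1/(n_perm + 1)
})

test_that("MRM recovers exact fits and matches enumeration", {
  d <- rand_sym(6, seed = 12)
  fit <- mrm(d, list(self = d), n_perm = 49, seed = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), 1, tolerance = 1e-12)
  ## single-predictor MRM R2 equals the Mantel r squared
  dy <- rand_sym(6, seed = 13)
  expect_equal(mrm(dy, list(x = d), n_perm = 0)$r_squared,
               mantel(d, dy, n_perm = 9)$r ^ 2, tolerance = 1e-12)
  ## 5-sample enumeration oracle: identical coefficients, R2 and p-values
  for (seed in 1:2) {
    dy5 <- rand_sym(5, seed = 40 + seed)
    preds <- list(a = rand_sym(5, seed = 50 + seed),
                  b = rand_sym(5, seed = 60 + seed))
    o <- oracle_mrm_exact(dy5, preds)
    f <- mrm(dy5, preds, exact = TRUE)
    expect_equal(unname(f$coefficients), o$coef, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r2, tolerance = 1e-12)
    expect_equal(unname(f$p_per_predictor), o$p_coef)
    expect_equal(f$p_model, o$p_model)
  }
  expect_error(mrm(dy, list(a = d, b = d)), "collinear")
})

test_that("forward selection honours alpha and gain ordering", {
  set.seed(14)
  n <- 15
  labs <- sprintf("s%02d", 1:n)
  d1 <- rand_sym(n, seed = 15); d2 <- rand_sym(n, seed = 16)
  noise <- rand_sym(n, seed = 17)
  dy <- sym_from_tri(1.2 * tri(d1) + 0.8 * tri(d2) + 0.3 * tri(noise), labs)
  cands <- list(D1 = d1, D2 = d2, D3 = rand_sym(n, seed = 18),
                D4 = rand_sym(n, seed = 19))
  fit <- forward_select_mrm(dy, cands, alpha = 0.05, n_perm = 199, seed = 2)
  expect_setequal(fit$selected[1:2], c("D1", "D2"))
  ## alpha = 1 admits every candidate, in decreasing-gain order
  all_in <- forward_select_mrm(dy, cands, alpha = 1, n_perm = 49, seed = 2)
  expect_setequal(all_in$selected, names(cands))
  expect_identical(all_in$selected[1], "D1")
  ## no candidate significant -> empty model
  none <- forward_select_mrm(rand_sym(n, seed = 20),
                             list(Dx = rand_sym(n, seed = 21)),
                             alpha = 0.001, n_perm = 99, seed = 3)
  expect_length(none$selected, 0)
  expect_equal(none$r_squared, 0)
})

test_that("forward-selection R-squared is non-decreasing along the path", {
  dy <- rand_sym(12, seed = 22)
  cands <- lapply(1:4, function(i) rand_sym(12, seed = 22 + i))
  names(cands) <- paste0("C", 1:4)
  fit <- forward_select_mrm(dy, cands, alpha = 1, n_perm = 19, seed = 1)
  path_r2 <- vapply(attr(fit, "path"), `[[`, numeric(1), "r_squared")
  expect_true(all(diff(path_r2) >= -1e-12))
})

test_that("variation partitioning fractions sum to one and hit known shares", {
  labs <- sprintf("s%02d", 1:20)
  ## orthonormal construction: known variance shares a^2, b^2
  set.seed(23)
  ntri <- 190
  E <- qr.Q(qr(scale(cbind(rnorm(ntri), rnorm(ntri), rnorm(ntri)),
                     scale = FALSE)))
  a <- 0.6; b <- 0.5
  vE <- E[, 1]; vS <- E[, 2]; vN <- E[, 3]
  dy <- sym_from_tri(a * vE + b * vS + sqrt(1 - a^2 - b^2) * vN, labs)
  v <- variation_partitioning(dy, list(env = sym_from_tri(vE, labs)),
                              list(space = sym_from_tri(vS, labs)))
  expect_equal(v$pure_env + v$pure_space + v$shared + v$unexplained, 1,
               tolerance = 1e-9)
  expect_equal(v$pure_env, a^2, tolerance = 1e-9)
  expect_equal(v$pure_space, b^2, tolerance = 1e-9)
  ## identical env and space groups: everything shared
  same <- rand_sym(20, seed = 24)
  dy2 <- sym_from_tri(0.7 * tri(same) + 0.3 * rnorm(ntri), labs)
  v2 <- variation_partitioning(dy2, list(e = same), list(s = same + 0))
  expect_lt(abs(v2$pure_env), 1e-9)
  expect_lt(abs(v2$pure_space), 1e-9)
  expect_error(variation_partitioning(dy, list(), list(s = same)), "non-empty")
})

test_that("PERMANOVA separates blocks and matches enumeration", {
  ## fully separated blocks: minimal attainable p
  labs <- paste0("s", 1:8)
  d <- matrix(1, 8, 8, dimnames = list(labs, labs))
  d[1:4, 1:4] <- 0.05; d[5:8, 5:8] <- 0.05
  diag(d) <- 0
  g <- rep(c("A", "B"), each = 4)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  ## the attainable floor exceeds 1/(n_perm + 1): permutations preserving
  ## the block partition (prob 2 * 4!4!/8! = 1/35) tie with the observed F
  expect_lte(res$p, (1 + qbinom(0.999, 99, 1 / 35)) / 100)
  expect_gt(res$pseudo_F, 10)
  ## 6-sample enumeration oracle
  d6 <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(d6) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g6 <- rep(c("A", "B"), each = 3)
  o <- oracle_permanova_exact(d6, g6)
  r6 <- permanova(d6, g6, exact = TRUE)
  expect_equal(r6$pseudo_F, o$F, tolerance = 1e-12)
  expect_identical(r6$p, o$p)
  expect_error(permanova(d6, c("A", "A", "A", "A", "A", "B")), "singleton")
  expect_error(permanova(d6, rep("A", 6)), "2 groups")
})

test_that("NMDS embeds Euclidean configurations with near-zero stress", {
  ## three equidistant points embed exactly in two dimensions
  labs <- paste0("s", 1:3)
  d3 <- sym_from_tri(c(1, 1, 1), labs)
  expect_lt(nmds(d3, k = 2, n_starts = 5, seed = 1)$stress, 1e-4)
  ## planar coordinates are recovered with stress < 0.01
  set.seed(26)
  xy <- matrix(rnorm(20), 10, 2)
  d10 <- as.matrix(dist(xy))
  dimnames(d10) <- list(paste0("s", 1:10), paste0("s", 1:10))
  fit <- nmds(d10, k = 2, n_starts = 10, seed = 2)
  expect_lt(fit$stress, 0.01)
  ## determinism up to rigid motion: Procrustes distance ~ 0 under same seed
  fit2 <- nmds(d10, k = 2, n_starts = 10, seed = 2)
  pr <- vegan::procrustes(fit$coords, fit2$coords, symmetric = TRUE)
  expect_lt(sqrt(pr$ss), 1e-8)
  expect_error(nmds(d10, k = 10), "smaller")
})

test_that("category contrasts bin within-category pairs and letter the groups", {
  labs <- sprintf("s%02d", 1:12)
  attribute <- setNames(1:12, labs)
  ## bins shifted by a large constant: low and high must differ
  dev <- matrix(0, 12, 12, dimnames = list(labs, labs))
  dev[1:6, 1:6] <- 5 + rand_sym(6, seed = 27) * 0.1
  dev[7:12, 7:12] <- -5 + rand_sym(6, seed = 28) * 0.1
  dev[lower.tri(dev)] <- t(dev)[lower.tri(dev)]
  diag(dev) <- 0
  attr(dev, "signed") <- TRUE
  ct <- category_contrast(dev, attribute, n_categories = 2)
  expect_equal(ct$summary$n_pairs, c(15, 15))
  expect_false(ct$summary$letter[1] == ct$summary$letter[2])
  expect_lt(ct$p_matrix["low", "high"], 0.05)
  ## all-equal values: all bins share one letter
  flat <- sym_from_tri(rep(1, 66), labs)
  attr(flat, "signed") <- TRUE
  ct3 <- category_contrast(flat, attribute, n_categories = 3)
  expect_true(all(ct3$summary$letter == ct3$summary$letter[1]))
  ## within-bin pair rule: a medium bin of one sample has no pairs
  tiny_labs <- paste0("s", 1:5)
  tiny <- sym_from_tri(rnorm(10), tiny_labs)
  attr(tiny, "signed") <- TRUE
  ct2 <- category_contrast(tiny, setNames(c(1, 2, 3, 9, 10), tiny_labs),
                           n_categories = 3)
  expect_true("medium" %in% ct2$excluded)
})
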