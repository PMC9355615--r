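test_that("null communities preserve totals and the regional distribution", {
  ## one-OTU table: nulls forced identical to the observation
  one <- matrix(c(10L, 20L), 2, 1, dimnames = list(c("a", "b"), "x"))
  nulls <- null_communities(one, 5, seed = 1)
  for (nl in nulls) expect_equal(nl, one, ignore_attr = TRUE)
  ## row sums preserved in every replicate
  tab <- rand_table(5, 12, 800, seed = 6)
  for (nl in null_communities(tab, 10, seed = 2))
    expect_equal(rowSums(nl), rowSums(tab))
  ## binomial expectation: pool (0.7, 0.3), N = 1000 per sample
  two <- matrix(c(700L, 300L, 700L, 300L), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("x", "y")))
  nulls <- null_communities(two, 999, seed = 3)
  draws <- unlist(lapply(nulls, function(nl) nl[, "x"]))
  se <- sqrt(1000 * 0.7 * 0.3) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 700), 3 * se)
  expect_error(null_communities(two, 0), "n_null")
  expect_error(null_communities(two * 0L, 5), "empty")
})

test_that("beta_deviation is deterministic and flags degenerate cells", {
  tab <- rand_table(6, 40, 500, seed = 7)
  b1 <- suppressWarnings(beta_deviation(tab, n_null = 49, seed = 5))
  b2 <- suppressWarnings(beta_deviation(tab, n_null = 49, seed = 5))
  expect_identical(b1$deviation, b2$deviation)   # bit-identical under seed
  expect_warning(beta_deviation(tab, n_null = 9, seed = 1), "low")
  ## one-OTU table: null sd is 0 everywhere -> every pair flagged in ses mode
  one <- matrix(c(10L, 20L, 30L), 3, 1,
                dimnames = list(c("a", "b", "c"), "x"))
  bo <- suppressWarnings(beta_deviation(one, n_null = 19, seed = 1))
  expect_true(all(is.na(bo$deviation[lower.tri(bo$deviation)])))
  expect_length(bo$flagged, 3)
  ## raw mode is bounded by construction
  br <- suppressWarnings(beta_deviation(tab, n_null = 49, mode = "raw", seed = 2))
  expect_true(all(abs(br$deviation) <= 1, na.rm = TRUE))
})

test_that("divergent site groups give strictly positive between-group deviations", {
  ## two blocks on disjoint OTU sets: observed BC = 1 between groups while
  ## null BC < 1 almost surely
  m <- matrix(0L, 4, 10, dimnames = list(paste0("s", 1:4), paste0("o", 1:10)))
  m[1:2, 1:5] <- 200L
  m[3:4, 6:10] <- 200L
  bd <- beta_deviation(m, n_null = 199, seed = 4)
  between <- bd$deviation[3:4, 1:2]
  expect_true(all(between > 0))
})

test_that("Monte-Carlo null mean matches exhaustive multinomial enumeration", {
  ## brute-force oracle: all 66 compositions of N = 10 reads over 3 OTUs,
  ## expected Bray-Curtis between two independent null samples
  tab <- matrix(c(5L, 3L, 2L, 2L, 6L, 2L, 1L, 2L, 7L), 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), paste0("o", 1:3)))
  p <- colSums(tab) / sum(tab)
  comps <- as.matrix(expand.grid(0:10, 0:10))
  comps <- cbind(comps, 10 - rowSums(comps))
  comps <- comps[comps[, 3] >= 0, , drop = FALSE]
  pr <- apply(comps, 1, function(c3) dmultinom(c3, prob = p))
  e_bc <- 0
  for (i in seq_len(nrow(comps))) {
    bc_i <- rowSums(abs(sweep(comps, 2, comps[i, ]))) / 20
    e_bc <- e_bc + pr[i] * sum(pr * bc_i)
  }
  bd <- beta_deviation(tab, n_null = 50000, seed = 12)
  expect_lt(max(abs(bd$null_mean[lower.tri(bd$null_mean)] - e_bc)), 1e-2)
})

test_that("null self-consistency: neutral tables give calibrated ses values", {
  ## tables generated by the null process itself: ses cells should exceed
  ## |1.96| about 5% of the time (within 3 points, pooled over 20 runs)
  set.seed(20)
  p <- rexp(150)
  p <- p / sum(p)
  cells <- unlist(lapply(1:20, function(rep) {
    tab <- t(sapply(1:10, function(i) rmultinom(1, 1000, p)[, 1]))
    dimnames(tab) <- list(paste0("s", 1:10), paste0("o", 1:150))
    bd <- beta_deviation(tab, n_null = 499, seed = 1000 + rep)
    tri(bd$deviation)
  }))
  frac <- mean(abs(cells) > 1.96)
  expect_lt(abs(frac - 0.05), 0.03)
  ## and the pooled mean is near zero on the ses scale
  expect_lt(abs(mean(cells)), 0.5)
})

test_that("shrinking niche breadth never decreases the mean deviation", {
  pool <- simulate_pool(150, seed = 30)
  mean_dev <- function(breadth) {
    mean(vapply(1:5, function(s) {
      sc <- assembly_scenario("heterogeneous_selection", n_sites = 6,
                              quadrats_per_site = 1, depths = "surface",
                              reads_per_sample = 1000, niche_breadth = breadth,
                              seed = s)
      ds <- assemble_communities(pool, sc)
      mean(tri(beta_deviation(ds$otu_table, n_null = 99, seed = s)$deviation))
    }, numeric(1)))
  }
  devs <- vapply(c(0.5, 0.12, 0.05), mean_dev, numeric(1))
  expect_true(all(diff(devs) >= 0))
})

test_that("mean_deviation_test matches the closed-form t-test", {
  labs <- paste0("s", 1:3)
  res <- mean_deviation_test(sym_from_tri(c(2, 3, 4), labs))
  expect_equal(res$mean, 3)
  expect_equal(res$t, 3 * sqrt(3), tolerance = 1e-9)   # 5.196 with 2 df
  expect_equal(res$p, 2 * pt(3 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p, 0.0351, tolerance = 2e-3)
  z <- mean_deviation_test(sym_from_tri(c(0, 0, 0), labs))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_error(mean_deviation_test(sym_from_tri(c(1, 1, 1), labs)), "constant")
})
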