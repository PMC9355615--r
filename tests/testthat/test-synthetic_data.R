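test_that("simulate_pool produces a normalized, reproducible abundance distribution", {
  p1 <- simulate_pool(500, 1.5, seed = 1)
  expect_equal(sum(p1$regional_abundance), 1, tolerance = 1e-9)
  expect_true(all(p1$regional_abundance > 0))
  expect_gt(max(p1$regional_abundance) / min(p1$regional_abundance), 10)
  expect_length(p1$niche_optimum, 500)
  expect_true(all(p1$niche_optimum >= 0 & p1$niche_optimum <= 1))
  expect_identical(p1, simulate_pool(500, 1.5, seed = 1))
  expect_false(identical(p1$regional_abundance,
                         simulate_pool(500, 1.5, seed = 2)$regional_abundance))
  ## degenerate lognormal: sigma -> 0 gives an even distribution
  p2 <- simulate_pool(2, 1e-9, seed = 3)
  expect_equal(p2$regional_abundance, c(0.5, 0.5), tolerance = 1e-6)
  expect_error(simulate_pool(1), "n_otus")
  expect_error(simulate_pool(10, lognormal_sigma = 0), "lognormal_sigma")
})

test_that("assembled samples conserve reads and are seed-deterministic", {
  pool <- simulate_pool(120, seed = 2)
  for (regime in c("neutral", "heterogeneous_selection",
                   "homogeneous_selection", "dispersal_limitation")) {
    sc <- assembly_scenario(regime, n_sites = 5, quadrats_per_site = 2,
                            depths = c("surface", "subsurface"),
                            reads_per_sample = 5000, seed = 7)
    ds <- assemble_communities(pool, sc)
    expect_equal(nrow(ds$otu_table), 5 * 2 * 2)
    expect_true(all(rowSums(ds$otu_table) == 5000), info = regime)
    ds2 <- assemble_communities(pool, sc)
    expect_identical(ds$otu_table, ds2$otu_table, info = regime)
    ## components aligned on the same ordered sample labels
    expect_identical(rownames(ds$otu_table), ds$metadata$sample_id)
  }
  expect_error(assembly_scenario("drift"), "arg")
  expect_error(assembly_scenario("neutral", reads_per_sample = 50), "reads_per_sample")
})

test_that("selection regimes reorder mean Bray-Curtis as expected", {
  ## oracle: simulate both regimes repeatedly under a common pool/seed
  ## budget, compare mean pairwise dissimilarity across sites
  pool <- simulate_pool(150, seed = 4)
  mean_bc <- function(regime, seed, strength = NULL) {
    sc <- assembly_scenario(regime, n_sites = 6, quadrats_per_site = 1,
                            depths = "surface", reads_per_sample = 1000,
                            niche_breadth = 0.08, seed = seed,
                            selection_strength = strength)
    mean(tri(bray_curtis(assemble_communities(pool, sc)$otu_table)))
  }
  reps <- 20
  het <- vapply(seq_len(reps), function(s) mean_bc("heterogeneous_selection", s), 1)
  neu <- vapply(seq_len(reps), function(s) mean_bc("neutral", s), 1)
  hom <- vapply(seq_len(reps), function(s) mean_bc("homogeneous_selection", s), 1)
  expect_gt(mean(het), mean(neu))
  expect_lt(mean(hom), mean(neu))
})

test_that("guild annotation fractions are binomially calibrated and deterministic", {
  pool <- simulate_pool(1000, seed = 5)
  fr <- c(saprotrophic = 0.3, mycorrhizal = 0.15, pathotrophic = 0.08)
  ann <- simulate_guild_annotation(pool, fr, seed = 9)
  truth <- attr(ann, "truth")
  for (g in names(fr)) {
    n <- sum(truth == g)
    lo <- qbinom(0.005, 1000, fr[[g]]); hi <- qbinom(0.995, 1000, fr[[g]])
    expect_true(n >= lo && n <= hi,
                info = sprintf("%s: %d outside [%d, %d]", g, n, lo, hi))
  }
  expect_identical(ann, simulate_guild_annotation(pool, fr, seed = 9))
  ## all-zero fractions: everything unassigned
  ann0 <- simulate_guild_annotation(pool, c(saprotrophic = 0), seed = 1)
  expect_true(all(attr(ann0, "truth") == "unassigned"))
  expect_error(simulate_guild_annotation(pool, c(saprotrophic = 0.9,
                                                 mycorrhizal = 0.2)), "sum")
})

test_that("community-weighted SRL tracks the environmental gradient", {
  pool <- simulate_pool(100, seed = 6)
  sc <- assembly_scenario("heterogeneous_selection", n_sites = 12,
                          quadrats_per_site = 1, depths = "surface",
                          reads_per_sample = 1000, trait_env_r = 0.9, seed = 11)
  ds <- assemble_communities(pool, sc)
  tr <- apply_transforms(ds$trait_table)
  cwm <- community_weighted_mean(ds$plant_community, tr, "SRL")
  env_q <- ds$site_env[substr(names(cwm), 1, 3)]
  expect_gt(abs(cor(cwm, env_q)), 0.6)
})
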