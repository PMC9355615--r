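## Synthetic communities with known assembly regimes.
##
## The generator emulates an arid inland-river-basin survey: sites spanning a
## latent environmental gradient (standing in for river distance /
## groundwater depth), quadrats nested in sites, two depth layers, a regional
## OTU pool with a lognormal abundance distribution, FUNGuild-style
## annotations, a plant community whose community-weighted specific root
## length (SRL) tracks the gradient, and edaphic covariates.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a regional OTU pool
#'
#' Regional relative abundances are normalized lognormal draws (the standard
#' species-abundance distribution); each OTU gets a niche optimum uniform on
#' the environmental axis.
#'
#' @param n_otus number of OTUs (>= 2).
#' @param lognormal_sigma lognormal sd on the log scale (default 1.5).
#' @param env_range numeric length-2, the environmental axis (default 0..1).
#' @param seed integer RNG seed.
#' @return object of class `regional_pool`: list with `otu_ids`,
#'   `regional_abundance` (sums to 1), `niche_optimum`, `env_range`.
#' @export
simulate_pool <- function(n_otus, lognormal_sigma = 1.5, env_range = c(0, 1),
                          seed = 1L) {
  n_otus <- check_count(n_otus, "n_otus", min = 2L)
  lognormal_sigma <- check_number(lognormal_sigma, "lognormal_sigma", 0, strict = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  if (length(env_range) != 2L || env_range[2L] <= env_range[1L])
    stop_ga("`env_range` must be an increasing length-2 interval")
  with_seed(seed, {
    ab <- stats::rlnorm(n_otus, meanlog = 0, sdlog = lognormal_sigma)
    opt <- stats::runif(n_otus, env_range[1L], env_range[2L])
  })
  structure(list(otu_ids = sprintf("OTU%04d", seq_len(n_otus)),
                 regional_abundance = ab / sum(ab),
                 niche_optimum = opt,
                 env_range = as.numeric(env_range)),
            class = "regional_pool")
}

#' Describe an assembly scenario
#'
#' Bundles the generative regime and its parameters.  Defaults mirror the
#' emulated survey: 27 sites x 3 quadrats x 2 depth layers = 162 samples,
#' 23883 reads per sample.
#'
#' `selection_strength` is the fraction of each sample's reads allocated
#' deterministically to the environmentally filtered expectation (remainder
#' multinomial).  It is what lets homogeneous selection produce communities
#' *more* similar than the abundance-weighted null expects; it defaults to
#' 0.8 for the two selection regimes and is forced to 0 otherwise.
#'
#' @param regime one of `neutral`, `heterogeneous_selection`,
#'   `homogeneous_selection`, `dispersal_limitation`.
#' @param n_sites,quadrats_per_site,depths,reads_per_sample survey design.
#' @param niche_breadth sd of the Gaussian environmental filter (axis units).
#' @param dispersal_decay per-km immigration decay rate (dispersal regime).
#' @param env_gradient_range environmental axis spanned by the sites.
#' @param selection_strength deterministic read fraction under selection.
#' @param trait_env_r correlation between species' (log) SRL and their niche
#'   optimum; dials how tightly community-weighted SRL tracks the filter.
#' @param guild_fractions named proportions for `saprotrophic`,
#'   `mycorrhizal`, `pathotrophic` OTU labels.
#' @param region_lon,region_lat site rectangle, decimal degrees (km scale).
#' @param seed integer RNG seed.
#' @return validated list of class `assembly_scenario`.
#' @export
assembly_scenario <- function(regime = c("neutral", "heterogeneous_selection",
                                         "homogeneous_selection",
                                         "dispersal_limitation"),
                              n_sites = 27L, quadrats_per_site = 3L,
                              depths = c("surface", "subsurface"),
                              reads_per_sample = 23883L,
                              niche_breadth = 0.15,
                              dispersal_decay = 0.05,
                              env_gradient_range = c(0, 1),
                              selection_strength = NULL,
                              trait_env_r = 0.8,
                              guild_fractions = c(saprotrophic = 0.19,
                                                  mycorrhizal = 0.10,
                                                  pathotrophic = 0.05),
                              region_lon = c(100.0, 101.0),
                              region_lat = c(41.3, 42.3),
                              seed = 1L) {
  regime <- match.arg(regime)
  n_sites <- check_count(n_sites, "n_sites")
  quadrats_per_site <- check_count(quadrats_per_site, "quadrats_per_site")
  reads_per_sample <- check_count(reads_per_sample, "reads_per_sample", min = 100L)
  niche_breadth <- check_number(niche_breadth, "niche_breadth", 0, strict = TRUE)
  dispersal_decay <- check_number(dispersal_decay, "dispersal_decay", 0)
  trait_env_r <- check_number(trait_env_r, "trait_env_r", -1)
  if (abs(trait_env_r) > 1) stop_ga("`trait_env_r` must lie in [-1, 1]")
  if (length(env_gradient_range) != 2L ||
      env_gradient_range[2L] <= env_gradient_range[1L])
    stop_ga("`env_gradient_range` must be an increasing length-2 interval")
  if (is.null(selection_strength))
    selection_strength <- if (regime %in% c("heterogeneous_selection",
                                            "homogeneous_selection")) 0.8 else 0
  selection_strength <- check_number(selection_strength, "selection_strength", 0)
  if (selection_strength > 1) stop_ga("`selection_strength` must lie in [0, 1]")
  if (any(guild_fractions < 0) || sum(guild_fractions) > 1)
    stop_ga("`guild_fractions` must be non-negative and sum to <= 1")
  structure(list(regime = regime, n_sites = n_sites,
                 quadrats_per_site = quadrats_per_site,
                 depths = as.character(depths),
                 reads_per_sample = reads_per_sample,
                 niche_breadth = niche_breadth,
                 dispersal_decay = dispersal_decay,
                 env_gradient_range = as.numeric(env_gradient_range),
                 selection_strength = selection_strength,
                 trait_env_r = trait_env_r,
                 guild_fractions = guild_fractions,
                 region_lon = as.numeric(region_lon),
                 region_lat = as.numeric(region_lat),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "assembly_scenario")
}

## deterministic largest-remainder allocation of n reads to probabilities p
allocate_reads <- function(n, p) {
  e <- n * p
  base <- floor(e)
  short <- n - sum(base)
  if (short > 0) {
    idx <- order(e - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1L
  }
  base
}

draw_sample <- function(n_reads, p, determinism) {
  n_det <- round(n_reads * determinism)
  det <- if (n_det > 0) allocate_reads(n_det, p) else numeric(length(p))
  sto <- if (n_reads - n_det > 0)
    as.numeric(stats::rmultinom(1L, n_reads - n_det, p)) else numeric(length(p))
  det + sto
}

#' Simulate FUNGuild-style annotations for a pool
#'
#' Each OTU is labelled saprotrophic, mycorrhizal, pathotrophic or left
#' unassigned, with the stated proportions (defaults make saprotrophs the
#' most numerous guild, then mycorrhizal, then pathotrophic).  Labelled OTUs
#' receive includable annotations (single trophic mode, confidence Highly
#' Probable or Probable); a small share of the remainder gets realistic
#' *excludable* records (multi-mode, endophyte, Possible) so that
#' downstream filtering is exercised.
#'
#' @param pool a `regional_pool`.
#' @param fractions named guild proportions, sum <= 1.
#' @param seed integer RNG seed.
#' @return annotation data.frame with a `truth` attribute (the generated
#'   guild label per OTU).
#' @export
simulate_guild_annotation <- function(pool,
                                      fractions = c(saprotrophic = 0.19,
                                                    mycorrhizal = 0.10,
                                                    pathotrophic = 0.05),
                                      seed = 1L) {
  stopifnot(inherits(pool, "regional_pool"))
  if (any(fractions < 0) || sum(fractions) > 1)
    stop_ga("`fractions` must be non-negative and sum to <= 1")
  f <- c(saprotrophic = 0, mycorrhizal = 0, pathotrophic = 0)
  f[names(fractions)] <- fractions
  n <- length(pool$otu_ids)
  with_seed(seed, {
    lab <- sample(c("saprotrophic", "mycorrhizal", "pathotrophic", "unassigned"),
                  n, replace = TRUE, prob = c(f, 1 - sum(f)))
    conf <- sample(c("Highly Probable", "Probable"), n, replace = TRUE,
                   prob = c(0.6, 0.4))
    myc_guild <- sample(c("Arbuscular Mycorrhizal", "Ectomycorrhizal"),
                        n, replace = TRUE, prob = c(0.7, 0.3))
    sap_guild <- sample(c("Undefined Saprotroph", "Wood Saprotroph",
                          "Soil Saprotroph", "Dung Saprotroph"), n, replace = TRUE)
    path_guild <- sample(c("Plant Pathogen", "Animal Pathogen"),
                         n, replace = TRUE, prob = c(0.8, 0.2))
    decoy <- stats::runif(n) < 0.3  # among unassigned: annotated-but-excluded
    decoy_kind <- sample(3L, n, replace = TRUE)
  })
  mode <- guild <- character(n)
  mode[lab == "saprotrophic"] <- "Saprotroph"
  guild[lab == "saprotrophic"] <- sap_guild[lab == "saprotrophic"]
  mode[lab == "mycorrhizal"] <- "Symbiotroph"
  guild[lab == "mycorrhizal"] <- myc_guild[lab == "mycorrhizal"]
  mode[lab == "pathotrophic"] <- "Pathotroph"
  guild[lab == "pathotrophic"] <- path_guild[lab == "pathotrophic"]
  un <- lab == "unassigned"
  mode[un] <- "-"; guild[un] <- "-"; conf[un] <- "Unassigned"
  dk <- un & decoy & decoy_kind == 1L
  mode[dk] <- "Pathotroph-Saprotroph"; guild[dk] <- "Undefined Saprotroph"
  conf[dk] <- "Probable"
  dk <- un & decoy & decoy_kind == 2L
  mode[dk] <- "Symbiotroph"; guild[dk] <- "Endophyte"; conf[dk] <- "Highly Probable"
  dk <- un & decoy & decoy_kind == 3L
  mode[dk] <- "Saprotroph"; guild[dk] <- "Undefined Saprotroph"; conf[dk] <- "Possible"
  ann <- data.frame(otu_id = pool$otu_ids, trophic_mode = mode, guild = guild,
                    confidence = conf, stringsAsFactors = FALSE)
  attr(ann, "truth") <- stats::setNames(lab, pool$otu_ids)
  ann
}

plausible_metadata <- function(env, noise) {
  ## edaphic covariates on field-plausible scales, driven by the gradient
  ## (high env = riparian end: moist, organic, shallow groundwater)
  e <- pmin(pmax(env + noise * stats::rnorm(length(env)), 0), 1)
  data.frame(
    SM = 0.1 + 16.9 * e,                       # soil moisture, %
    SEC = 0.2 + 4.5 * e + 0.2 * stats::rnorm(length(e))^2,  # ms/cm
    pH = 8.9 - 1.0 * e + 0.1 * stats::rnorm(length(e)),
    SOC = exp(0.5 + 1.5 * e + 0.2 * stats::rnorm(length(e))),  # g/kg
    STN = exp(-1.5 + 1.2 * e + 0.2 * stats::rnorm(length(e))), # g/kg
    NH4N = 1 + 8 * e + 0.5 * stats::rnorm(length(e))^2,        # mg/kg
    NO3N = 1 + 12 * e + 0.5 * stats::rnorm(length(e))^2,       # mg/kg
    STP = 0.3 + 0.4 * e + 0.05 * abs(stats::rnorm(length(e))), # g/kg
    SAP = 2 + 6 * e + 0.5 * stats::rnorm(length(e))^2,         # mg/kg
    MGWD = 1 + 29 * (1 - e),                   # mean groundwater depth, m
    SDGWD = 0.2 + 1.5 * e + 0.1 * abs(stats::rnorm(length(e))))
}

#' Assemble synthetic communities under a known regime
#'
#' Realizes the scenario's regime as sampling probabilities over the regional
#' pool:
#' * `neutral` — regional relative abundances unchanged;
#' * `heterogeneous_selection` — per-site environments spread over the
#'   gradient, probabilities proportional to abundance x Gaussian(environment
#'   - optimum; niche_breadth);
#' * `homogeneous_selection` — one shared environment, same filter;
#' * `dispersal_limitation` — probabilities proportional to abundance x
#'   exp(-dispersal_decay x km to each OTU's origin site).
#'
#' Every sample holds exactly `reads_per_sample` individuals.  Under the two
#' selection regimes a `selection_strength` fraction of reads follows the
#' filtered expectation deterministically (see [assembly_scenario()]).
#'
#' @param pool a `regional_pool`.
#' @param scenario an `assembly_scenario`.
#' @return object of class `synthetic_dataset`: list with `otu_table`,
#'   `annotation`, `metadata`, `plant_community`, `trait_table`, `truth`
#'   (the scenario), and `site_env` (latent site environments).
#' @export
assemble_communities <- function(pool, scenario) {
  stopifnot(inherits(pool, "regional_pool"))
  if (!inherits(scenario, "assembly_scenario"))
    stop_ga("`scenario` must come from assembly_scenario()")
  sc <- scenario
  n_otu <- length(pool$otu_ids)
  sites <- sprintf("S%02d", seq_len(sc$n_sites))
  quadrats <- as.vector(t(outer(sites, seq_len(sc$quadrats_per_site),
                                function(s, q) paste0(s, "Q", q))))
  grid <- expand.grid(depth = sc$depths, quadrat = quadrats,
                      stringsAsFactors = FALSE)[, 2:1]
  grid$site <- substr(grid$quadrat, 1L, 3L)
  sample_ids <- paste0(grid$quadrat, "_", grid$depth)
  gr <- sc$env_gradient_range

  with_seed(sc$seed, {
    ## -- spatial layout: sites uniform on the region rectangle, quadrats
    ##    jittered within ~500 m
    site_lon <- stats::runif(sc$n_sites, sc$region_lon[1L], sc$region_lon[2L])
    site_lat <- stats::runif(sc$n_sites, sc$region_lat[1L], sc$region_lat[2L])
    names(site_lon) <- names(site_lat) <- sites
    q_site <- substr(quadrats, 1L, 3L)
    q_lon <- site_lon[q_site] + stats::runif(length(quadrats), -0.003, 0.003)
    q_lat <- site_lat[q_site] + stats::runif(length(quadrats), -0.003, 0.003)
    names(q_lon) <- names(q_lat) <- quadrats

    ## -- site environments
    site_env <- switch(sc$regime,
      homogeneous_selection = rep(mean(gr), sc$n_sites),
      stats::runif(sc$n_sites, gr[1L], gr[2L]))
    names(site_env) <- sites

    ## -- per-site sampling probabilities
    probs <- matrix(0, n_otu, sc$n_sites, dimnames = list(pool$otu_ids, sites))
    if (sc$regime %in% c("heterogeneous_selection", "homogeneous_selection")) {
      for (s in seq_len(sc$n_sites)) {
        w <- pool$regional_abundance *
          exp(-(site_env[s] - pool$niche_optimum)^2 / (2 * sc$niche_breadth^2))
        if (sum(w) == 0) w <- pool$regional_abundance
        probs[, s] <- w / sum(w)
      }
    } else if (sc$regime == "dispersal_limitation") {
      origin <- sample.int(sc$n_sites, n_otu, replace = TRUE)
      dkm <- haversine_km(site_lat, site_lon, site_lat, site_lon, cross = TRUE)
      for (s in seq_len(sc$n_sites)) {
        w <- pool$regional_abundance * exp(-sc$dispersal_decay * dkm[s, origin])
        probs[, s] <- w / sum(w)
      }
    } else {
      probs[] <- pool$regional_abundance
    }

    ## -- community draws (quadrat x depth samples within each site)
    counts <- matrix(0, length(sample_ids), n_otu,
                     dimnames = list(sample_ids, pool$otu_ids))
    for (i in seq_along(sample_ids))
      counts[i, ] <- draw_sample(sc$reads_per_sample, probs[, grid$site[i]],
                                 sc$selection_strength)

    ## -- plant community + traits: species optima on the axis; quadrat
    ##    abundances Gaussian around the site environment, so CWM-SRL tracks
    ##    the same filter the fungi feel
    n_sp <- 15L
    species <- sprintf("plant_%02d", seq_len(n_sp))
    sp_opt <- seq(gr[1L], gr[2L], length.out = n_sp)
    pw <- exp(-outer(site_env[q_site], sp_opt, "-")^2 / (2 * 0.2^2)) + 1e-6
    pw <- pw / rowSums(pw)
    dimnames(pw) <- list(quadrats, species)
    z_opt <- as.numeric(scale(sp_opt))
    r <- sc$trait_env_r
    z_srl <- r * z_opt + sqrt(max(0, 1 - r^2)) * stats::rnorm(n_sp)
    traits <- data.frame(
      species = species,
      LA = round(exp(1.0 + 0.8 * stats::rnorm(n_sp)), 3),     # cm^2
      SLA = round(exp(4.5 + 0.4 * stats::rnorm(n_sp)), 2),    # cm^2/g
      LCC = round(420 + 30 * stats::rnorm(n_sp), 1),          # mg/g
      LNC = round(18 + 4 * abs(stats::rnorm(n_sp)), 2),       # mg/g
      LPC = round(1.4 + 0.3 * abs(stats::rnorm(n_sp)), 2),    # mg/g
      RL = round(exp(1.2 + 0.5 * stats::rnorm(n_sp)), 3),     # m
      RD = round(0.3 + 0.25 * abs(stats::rnorm(n_sp)), 3),    # mm
      SRL = round(10^(1.6 - 0.45 * z_srl), 2),                # m/g
      RCC = round(430 + 25 * stats::rnorm(n_sp), 1),          # mg/g
      RNC = round(exp(2.2 + 0.25 * stats::rnorm(n_sp)), 2),   # mg/g
      RPC = round(1.0 + 0.25 * abs(stats::rnorm(n_sp)), 2),   # mg/g
      stringsAsFactors = FALSE)

    ## -- metadata: edaphic covariates + quadrat-level fine-root biomass
    env_s <- site_env[grid$site]
    brk <- stats::quantile(site_env, c(0, 1/3, 2/3, 1), names = FALSE) +
      c(-1e-9, 0, 0, 1e-9)
    veg <- if (any(diff(brk) <= 0)) {  # flat gradient: one vegetation type
      rep("deciduous_scrub", length(env_s))
    } else {
      as.character(cut(env_s, breaks = brk,
                       labels = c("desert_vegetation", "deciduous_scrub",
                                  "riparian_forest")))
    }
    md <- data.frame(sample_id = sample_ids, site_id = grid$site,
                     quadrat_id = grid$quadrat, depth_layer = grid$depth,
                     latitude = round(as.numeric(q_lat[grid$quadrat]), 6),
                     longitude = round(as.numeric(q_lon[grid$quadrat]), 6),
                     vegetation_type = veg,
                     stringsAsFactors = FALSE)
    md <- cbind(md, plausible_metadata(env_s, noise = 0.05))
    frb_q <- exp(-1 + 2.2 * site_env[q_site] + 0.3 * stats::rnorm(length(quadrats)))
    names(frb_q) <- quadrats
    md$FRB <- round(frb_q[md$quadrat_id], 4)  # kg, quadrat-level
    for (v in c("SM", "SEC", "pH", "SOC", "STN", "NH4N", "NO3N", "STP", "SAP",
                "MGWD", "SDGWD"))
      md[[v]] <- round(md[[v]], 4)
  })

  annotation <- simulate_guild_annotation(pool, sc$guild_fractions,
                                          seed = sc$seed + 1L)
  structure(list(otu_table = counts, annotation = annotation, metadata = md,
                 plant_community = round(pw, 8) / rowSums(round(pw, 8)),
                 trait_table = traits, truth = sc,
                 site_env = stats::setNames(as.numeric(site_env), sites)),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' Emits the five TSV components plus the scenario as `scenario.json`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(otu_table = file.path(dir, "otu_table.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             plant_community = file.path(dir, "plant_community.tsv"),
             trait_table = file.path(dir, "trait_table.tsv"),
             scenario = file.path(dir, "scenario.json"))
  write_otu_table(dataset$otu_table, paths["otu_table"])
  write_guild_annotation(dataset$annotation, paths["annotation"])
  write_sample_metadata(dataset$metadata, paths["metadata"])
  write_plant_community(dataset$plant_community, paths["plant_community"])
  write_trait_table(dataset$trait_table, paths["trait_table"])
  jsonlite::write_json(unclass(dataset$truth), paths["scenario"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
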