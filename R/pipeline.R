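## End-to-end orchestration: (simulate | ingest) -> guild partition ->
## rarefaction + transforms -> distance matrices -> beta-null deviation ->
## attribution (Mantel, forward-selected MRM, VPA, PERMANOVA/NMDS, category
## contrasts), per depth-layer x guild stratum, with a reproducibility
## manifest.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_ga("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

sample_attribute_distances <- function(md, cwm_srl, cwm_sla, plant_bc) {
  ids <- md$sample_id
  named <- function(v) stats::setNames(v, ids)
  preds <- list()
  preds$PCD <- plant_bc[md$quadrat_id, md$quadrat_id]
  dimnames(preds$PCD) <- list(ids, ids)
  for (v in c("SOC", "SEC", "STN", "MGWD"))
    if (stats::sd(md[[v]]) > 0)
      preds[[v]] <- standardized_euclidean_1d(named(md[[v]]))
  if (stats::sd(cwm_sla[md$quadrat_id]) > 0)
    preds$SLA <- standardized_euclidean_1d(named(cwm_sla[md$quadrat_id]))
  if (stats::sd(cwm_srl[md$quadrat_id]) > 0)
    preds$SRL <- standardized_euclidean_1d(named(cwm_srl[md$quadrat_id]))
  if (stats::sd(md$FRB) > 0)
    preds$FRB <- standardized_euclidean_1d(named(md$FRB))
  preds$space <- geographic_distance(md)
  preds
}

analyze_stratum <- function(otu, md, preds, attrs, cfg, seed) {
  out <- list(n_samples = nrow(otu), n_otus = ncol(otu))
  bd <- stage("beta_deviation",
              beta_deviation(otu, n_null = cfg$n_null, mode = cfg$mode,
                             seed = seed))
  out$beta_deviation <- bd
  out$mean_test <- stage("mean_deviation_test", mean_deviation_test(bd))
  dev <- bd$deviation

  out$mantel <- stage("mantel", {
    tab <- lapply(names(preds), function(nm) {
      m <- mantel(preds[[nm]], dev, n_perm = cfg$n_perm, seed = seed + 1L)
      data.frame(predictor = nm, r = m$r, p = m$p, stringsAsFactors = FALSE)
    })
    do.call(rbind, tab)
  })

  out$mrm <- stage("forward_select_mrm",
                   forward_select_mrm(dev, preds, alpha = cfg$alpha,
                                      n_perm = cfg$n_perm, seed = seed + 2L))

  env_preds <- preds[setdiff(names(preds), "space")]
  sel_env <- intersect(out$mrm$selected, names(env_preds))
  if (!length(sel_env)) {
    ## nothing survived forward selection: fall back to the strongest
    ## Mantel env predictors, capped so the OLS keeps residual df
    n_pairs <- sum(lower.tri(dev) & !is.na(dev))
    k <- max(1L, min(3L, length(env_preds), n_pairs - 3L))
    ranked <- out$mantel[out$mantel$predictor != "space", ]
    sel_env <- ranked$predictor[order(-abs(ranked$r))][seq_len(k)]
  }
  out$vpa <- stage("variation_partitioning",
                   variation_partitioning(dev, env_preds[sel_env],
                                          preds["space"]))

  ## partial Mantel: root attributes against deviations, controlling plant
  ## community dissimilarity
  out$partial_mantel <- stage("partial_mantel", {
    tab <- lapply(intersect(c("SRL", "FRB"), names(preds)), function(nm) {
      m <- partial_mantel(preds[[nm]], dev, preds$PCD, n_perm = cfg$n_perm,
                          seed = seed + 3L, controlled = "PCD")
      data.frame(predictor = nm, r = m$r, p = m$p, controlled = "PCD",
                 stringsAsFactors = FALSE)
    })
    if (length(tab)) do.call(rbind, tab) else NULL
  })

  if (length(unique(md$vegetation_type)) >= 2L &&
      all(table(md$vegetation_type) >= 2L)) {
    out$permanova <- stage("permanova",
                           permanova(bd$observed_beta, md$vegetation_type,
                                     n_perm = cfg$n_perm, seed = seed + 4L))
    out$nmds <- stage("nmds", nmds(bd$observed_beta, k = 2L, n_starts = 20L,
                                   seed = seed + 5L))
  } else {
    out$permanova <- out$nmds <- NULL
    out$notes <- c(out$notes %||% character(0),
                   "vegetation groups degenerate; PERMANOVA/NMDS skipped")
  }

  out$contrasts <- list()
  if ("SRL" %in% names(attrs))
    out$contrasts$SRL <- stage("category_contrast",
                               category_contrast(dev, attrs$SRL,
                                                 n_categories = 3L,
                                                 alpha = cfg$alpha))
  if ("FRB" %in% names(attrs))
    out$contrasts$FRB <- stage("category_contrast",
                               category_contrast(dev, attrs$FRB,
                                                 n_categories = 2L,
                                                 alpha = cfg$alpha))
  out
}

#' Run the full assembly-analysis pipeline
#'
#' Per depth-layer x guild stratum: rarefaction, beta-null deviation and its
#' mean test, a Mantel table over the predictor set, forward-selected MRM,
#' variation partitioning (environment vs space), PERMANOVA and NMDS over
#' vegetation types, and SRL/FRB category contrasts.  With an `out_dir`, all
#' matrices/summaries plus a manifest and Markdown report are written.
#'
#' @param config a config list from [load_config()] or a path to a JSON
#'   config.
#' @param out_dir optional output directory (overrides `config$out_dir`).
#' @return run report: nested list by stratum, plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) load_config(config) else config
  out_dir <- out_dir %||% cfg$out_dir
  input_hashes <- NULL

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    n_otus <- sim$n_otus %||% 500L
    sigma <- sim$lognormal_sigma %||% 1.5
    sim$n_otus <- NULL; sim$lognormal_sigma <- NULL
    if (is.null(sim$seed)) sim$seed <- cfg$seed
    scenario <- stage("scenario", do.call(assembly_scenario, sim))
    pool <- stage("simulate_pool",
                  simulate_pool(n_otus, sigma, scenario$env_gradient_range,
                                seed = scenario$seed))
    ds <- stage("assemble_communities", assemble_communities(pool, scenario))
  } else {
    ds <- stage("ingest", list(
      otu_table = read_otu_table(cfg$inputs$otu_table),
      annotation = read_guild_annotation(cfg$inputs$annotation),
      metadata = read_sample_metadata(cfg$inputs$metadata),
      plant_community = read_plant_community(cfg$inputs$plant_community),
      trait_table = read_trait_table(cfg$inputs$trait_table)))
    input_hashes <- vapply(unlist(cfg$inputs), function(p)
      unname(tools::md5sum(p)), character(1))
  }

  scheme <- transform_scheme(cfg$sqrt_vars, cfg$log10_vars)
  md_t <- stage("transforms", apply_transforms(ds$metadata, scheme))
  tr_t <- stage("transforms", apply_transforms(ds$trait_table, scheme))
  cwm_srl <- stage("cwm", community_weighted_mean(ds$plant_community, tr_t, "SRL"))
  cwm_sla <- stage("cwm", community_weighted_mean(ds$plant_community, tr_t, "SLA"))
  plant_bc <- stage("plant_bray_curtis", bray_curtis(ds$plant_community))

  report <- list(strata = list())
  for (depth in intersect(cfg$depth_layers, unique(ds$metadata$depth_layer))) {
    md <- md_t[md_t$depth_layer == depth, , drop = FALSE]
    tab <- ds$otu_table[md$sample_id, , drop = FALSE]
    rdepth <- if (identical(cfg$rarefy_depth, "auto")) min(rowSums(tab))
              else check_count(cfg$rarefy_depth, "rarefy_depth")
    tab <- stage("rarefy", rarefy(tab, rdepth, seed = cfg$seed))
    parts <- stage("partition", partition_table(tab, ds$annotation))
    preds <- stage("distances",
                   sample_attribute_distances(md, cwm_srl, cwm_sla, plant_bc))
    attrs <- list(SRL = stats::setNames(cwm_srl[md$quadrat_id], md$sample_id),
                  FRB = stats::setNames(md$FRB, md$sample_id))
    for (g in intersect(cfg$guilds, names(parts))) {
      sub <- parts[[g]]
      key <- paste(depth, g, sep = ".")
      if (ncol(sub) < 2L || any(rowSums(sub) == 0)) {
        report$strata[[key]] <- list(skipped = "guild table empty or has empty samples")
        next
      }
      seed_g <- cfg$seed + 10L * match(depth, cfg$depth_layers) +
        100L * match(g, cfg$guilds)
      report$strata[[key]] <- analyze_stratum(sub, md, preds, attrs, cfg, seed_g)
      report$strata[[key]]$guild <- g
      report$strata[[key]]$depth_layer <- depth
      report$strata[[key]]$rarefy_depth <- rdepth
    }
  }

  report$manifest <- list(
    package = "guildassembly",
    version = as.character(utils::packageVersion("guildassembly")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    settings = cfg[c("n_null", "n_perm", "alpha", "seed", "mode",
                     "rarefy_depth", "depth_layers", "guilds")],
    mode_note = "deviation mode 'ses' divides (obs - null mean) by null sd",
    input_hashes = input_hashes)
  if (!is.null(out_dir)) write_run_outputs(report, out_dir)
  invisible(report)
}

write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c("# guildassembly run report", "")
  for (key in names(report$strata)) {
    st <- report$strata[[key]]
    sdir <- file.path(out_dir, key)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(st$skipped)) {
      lines <- c(lines, sprintf("## %s", key), "", sprintf("skipped: %s", st$skipped), "")
      next
    }
    write_distance_matrix(st$beta_deviation$deviation,
                          file.path(sdir, "beta_deviation.tsv"))
    jsonlite::write_json(
      list(mean_test = st$mean_test[c("mean", "t", "df", "p", "n")],
           n_null = st$beta_deviation$n_null, mode = st$beta_deviation$mode,
           seed = st$beta_deviation$seed,
           flagged_cells = st$beta_deviation$flagged,
           mrm = list(selected = st$mrm$selected,
                      coefficients = as.list(st$mrm$coefficients),
                      r_squared = st$mrm$r_squared,
                      p_per_predictor = as.list(st$mrm$p_per_predictor),
                      p_model = st$mrm$p_model),
           vpa = st$vpa[c("pure_env", "pure_space", "shared", "unexplained")],
           permanova = st$permanova,
           nmds_stress = st$nmds$stress %||% NA,
           notes = st$notes %||% character(0)),
      file.path(sdir, "summary.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    utils::write.table(st$mantel, file.path(sdir, "mantel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(st$partial_mantel))
      utils::write.table(st$partial_mantel, file.path(sdir, "partial_mantel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(st$nmds))
      utils::write.table(data.frame(sample_id = rownames(st$nmds$coords),
                                    st$nmds$coords),
                         file.path(sdir, "nmds.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    for (a in names(st$contrasts))
      utils::write.table(st$contrasts[[a]]$summary,
                         file.path(sdir, sprintf("contrast_%s.tsv", a)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    lines <- c(lines, sprintf("## %s", key), "",
               sprintf("- samples: %d, OTUs: %d, rarefied to %d",
                       st$n_samples, st$n_otus, st$rarefy_depth),
               sprintf("- mean beta deviation (%s): %.3f (t = %.2f, p = %.3g)",
                       st$beta_deviation$mode, st$mean_test$mean,
                       st$mean_test$t, st$mean_test$p),
               sprintf("- MRM selected: %s (R2 = %.3f)",
                       if (length(st$mrm$selected))
                         paste(st$mrm$selected, collapse = ", ") else "(none)",
                       st$mrm$r_squared),
               sprintf("- VPA: pure env %.3f, pure space %.3f, shared %.3f, unexplained %.3f",
                       st$vpa$pure_env, st$vpa$pure_space, st$vpa$shared,
                       st$vpa$unexplained),
               if (!is.null(st$permanova))
                 sprintf("- PERMANOVA by vegetation: F = %.2f, p = %.3g",
                         st$permanova$pseudo_F, st$permanova$p) else NULL,
               "")
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
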