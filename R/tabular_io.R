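## TSV dialects for every tabular artifact the pipeline consumes or emits.
## All files are plain tab-separated text with a header line; OTU tables
## default to OTUs-as-rows (the common amplicon convention), flipped by the
## `orientation` flag.

parse_error <- function(path, line, col, fmt, ...) {
  stop_ga("parse error in '%s' (line %s, column %s): %s", path,
          as.character(line), as.character(col), sprintf(fmt, ...),
          class = "guildassembly_parse_error")
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop_ga("file not found: '%s'", path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    row.names = NULL, colClasses = "character",
                    quote = "", comment.char = "")
}

#' Read / write an OTU count table
#'
#' The canonical on-disk form is a TSV whose first column holds OTU IDs and
#' whose header holds sample IDs (`orientation = "otus_as_rows"`, default).
#' With `orientation = "samples_as_rows"` the roles are swapped.  In memory
#' the table is always samples x OTUs.
#'
#' @param path file path.
#' @param orientation `"otus_as_rows"` (default) or `"samples_as_rows"`.
#' @return a samples x OTUs integer matrix.
#' @export
read_otu_table <- function(path, orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- read_tsv_raw(path)
  if (ncol(df) < 2L) stop_ga("'%s': an OTU table needs id column + data", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    parse_error(path, "-", 1, "duplicated %s ID '%s'",
                if (orientation == "otus_as_rows") "OTU" else "sample",
                ids[duplicated(ids)][1L])
  hdr <- colnames(df)[-1L]
  if (anyDuplicated(hdr))
    parse_error(path, 1, "-", "duplicated %s ID '%s'",
                if (orientation == "otus_as_rows") "sample" else "OTU",
                hdr[duplicated(hdr)][1L])
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L, dimnames = list(ids, hdr))
  for (j in seq_along(hdr)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      parse_error(path, bad[1L] + 1L, j + 1L,
                  "count '%s' (row '%s', column '%s') is not a non-negative integer",
                  df[[j + 1L]][bad[1L]], ids[bad[1L]], hdr[j])
    m[, j] <- v
  }
  if (orientation == "otus_as_rows") m <- t(m)
  validate_otu_table(m, what = sprintf("OTU table '%s'", path))
}

#' @rdname read_otu_table
#' @param table samples x OTUs count matrix.
#' @export
write_otu_table <- function(table, path, orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  table <- validate_otu_table(table)
  m <- if (orientation == "otus_as_rows") t(table) else table
  idname <- if (orientation == "otus_as_rows") "otu_id" else "sample_id"
  df <- data.frame(id = rownames(m), format(m, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- idname
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labelled square distance matrix
#'
#' TSV with sample labels in the header and in the first column.  Symmetry is
#' validated on read (tolerance 1e-6); signed matrices (beta-deviations) are
#' accepted when `signed = TRUE` and round-trip the flag via a `# signed`
#' comment line.
#'
#' @param path file path.
#' @param signed accept negative off-diagonal entries.
#' @return labelled square matrix, `signed` attribute set when flagged.
#' @export
read_distance_matrix <- function(path, signed = NA) {
  if (!file.exists(path)) stop_ga("file not found: '%s'", path)
  first <- readLines(path, n = 1L)
  flagged <- identical(first, "# signed")
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1L, quote = "", comment.char = "#")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop_ga("'%s': distance matrix is not square (%d x %d)", path, nrow(m), ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop_ga("'%s': row labels do not match column labels", path)
  signed <- if (is.na(signed)) flagged else check_flag(signed, "signed")
  if (signed) attr(m, "signed") <- TRUE
  validate_dist_matrix(m, signed = signed, what = sprintf("distance matrix '%s'", path))
}

#' @rdname read_distance_matrix
#' @param m labelled square matrix.
#' @export
write_distance_matrix <- function(m, path) {
  signed <- isTRUE(attr(m, "signed"))
  m <- validate_dist_matrix(m, signed = signed)
  con <- file(path, "w")
  on.exit(close(con))
  if (signed) writeLines("# signed", con)
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write guild annotation tables
#'
#' Columns: `otu_id`, `trophic_mode`, `guild`, `confidence`.  Multiple
#' trophic modes are joined with `-` (FUNGuild convention); unannotated OTUs
#' may simply be absent.
#'
#' @param path file path.
#' @return data.frame with the four annotation columns.
#' @export
read_guild_annotation <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("otu_id", "trophic_mode", "guild", "confidence")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop_ga("'%s': annotation is missing column(s): %s", path,
            paste(miss, collapse = ", "))
  if (anyDuplicated(df$otu_id))
    parse_error(path, "-", 1, "duplicated otu_id '%s'",
                df$otu_id[duplicated(df$otu_id)][1L])
  ok <- c("Highly Probable", "Probable", "Possible", "Unassigned")
  bad <- which(!(df$confidence %in% ok))
  if (length(bad))
    parse_error(path, bad[1L] + 1L, which(colnames(df) == "confidence"),
                "confidence '%s' not one of: %s", df$confidence[bad[1L]],
                paste(ok, collapse = ", "))
  df[need]
}

#' @rdname read_guild_annotation
#' @param annotation annotation data.frame.
#' @export
write_guild_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Required columns: `sample_id`, `site_id`, `quadrat_id`, `depth_layer`
#' (one of `surface`, `subsurface`), `latitude`, `longitude`,
#' `vegetation_type`; any further columns are treated as numeric
#' environmental variables.
#'
#' @param path file path.
#' @return data.frame; environmental columns numeric.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("sample_id", "site_id", "quadrat_id", "depth_layer",
            "latitude", "longitude", "vegetation_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop_ga("'%s': metadata missing column(s): %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    parse_error(path, "-", 1, "duplicated sample_id '%s'",
                df$sample_id[duplicated(df$sample_id)][1L])
  bad <- which(!(df$depth_layer %in% c("surface", "subsurface")))
  if (length(bad))
    parse_error(path, bad[1L] + 1L, which(colnames(df) == "depth_layer"),
                "depth_layer '%s' not 'surface'/'subsurface'", df$depth_layer[bad[1L]])
  num_cols <- setdiff(colnames(df), c("sample_id", "site_id", "quadrat_id",
                                      "depth_layer", "vegetation_type"))
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE))
    stop_ga("'%s': latitude outside [-90, 90]", path)
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE))
    stop_ga("'%s': longitude outside [-180, 180]", path)
  df
}

#' @rdname read_sample_metadata
#' @param metadata metadata data.frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write plant community and trait tables
#'
#' The plant community TSV has a `quadrat_id` first column and species
#' relative abundances (each row sums to 1 within 1e-6).  The trait TSV has a
#' `species` first column and numeric trait columns (NA allowed; consumers
#' that cannot tolerate NA must error, not impute).
#'
#' @param path file path.
#' @return community: quadrats x species numeric matrix; traits: data.frame.
#' @export
read_plant_community <- function(path) {
  df <- read_tsv_raw(path)
  if (colnames(df)[1L] != "quadrat_id")
    stop_ga("'%s': first column must be 'quadrat_id'", path)
  m <- as.matrix(as.data.frame(lapply(df[-1L], as.numeric),
                               check.names = FALSE, optional = TRUE))
  rownames(m) <- df[[1L]]
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > 1e-6)
  if (length(bad))
    stop_ga("'%s': quadrat '%s' abundances sum to %g, not 1", path,
            rownames(m)[bad[1L]], rs[bad[1L]])
  m
}

#' @rdname read_plant_community
#' @param community quadrats x species relative-abundance matrix.
#' @export
write_plant_community <- function(community, path) {
  df <- data.frame(quadrat_id = rownames(community), community,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_plant_community
#' @export
read_trait_table <- function(path) {
  df <- read_tsv_raw(path)
  if (colnames(df)[1L] != "species")
    stop_ga("'%s': first column must be 'species'", path)
  if (anyDuplicated(df$species))
    parse_error(path, "-", 1, "duplicated species '%s'",
                df$species[duplicated(df$species)][1L])
  for (cl in colnames(df)[-1L]) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' @rdname read_plant_community
#' @param traits trait data.frame (`species` column + numeric traits).
#' @export
write_trait_table <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

config_defaults <- function() {
  list(n_null = 999L, n_perm = 999L, alpha = 0.05, seed = 1L,
       mode = "ses", rarefy_depth = "auto",
       depth_layers = c("surface", "subsurface"),
       guilds = c("total", "mycorrhizal", "saprotrophic", "pathotrophic"),
       sqrt_vars = c("SM", "SEC", "SAP", "NH4N", "NO3N"),
       log10_vars = c("LA", "SLA", "RL", "SRL", "RNC"))
}

#' Load and validate a run configuration
#'
#' JSON file with either a `simulate` block (an [assembly_scenario()]
#' argument list) or an `inputs` block naming the five input TSV paths
#' (`otu_table`, `annotation`, `metadata`, `plant_community`, `trait_table`).
#' Missing analysis settings get defaults: `n_null = 999`, `n_perm = 999`,
#' `alpha = 0.05`.  Unknown keys are rejected with a nearest-match
#' suggestion.
#'
#' @param path path to a JSON config.
#' @return validated config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_ga("config file not found: '%s'", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(names(config_defaults()), "simulate", "inputs", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    key <- unknown[1L]
    d <- utils::adist(key, known)
    hint <- if (min(d) <= 3) sprintf("; did you mean \"%s\"?", known[which.min(d)]) else ""
    stop_ga("config '%s': unknown key \"%s\"%s", path, key, hint)
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop_ga("config '%s': needs either a \"simulate\" block or an \"inputs\" block", path)
  if (!is.null(cfg$inputs)) {
    need <- c("otu_table", "annotation", "metadata", "plant_community", "trait_table")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss))
      stop_ga("config '%s': \"inputs\" missing required path(s): %s", path,
              paste(miss, collapse = ", "))
  }
  out <- utils::modifyList(config_defaults(), cfg)
  out$n_null <- check_count(out$n_null, "n_null")
  out$n_perm <- check_count(out$n_perm, "n_perm")
  out$alpha <- check_number(out$alpha, "alpha", min = 0, strict = TRUE)
  if (out$alpha >= 1) stop_ga("config '%s': alpha must be in (0, 1)", path)
  out$seed <- check_count(out$seed, "seed", min = 0L)
  out
}
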