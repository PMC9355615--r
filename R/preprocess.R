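## Rarefaction, analysis-scale variable transforms, and community-weighted
## trait means.

#' Rarefy an OTU table to a common depth
#'
#' Single draw per sample, without replacement from the sample's individuals
#' (multivariate hypergeometric).  OTU columns are retained even when they
#' end up all-zero, so tables stay aligned across strata.
#'
#' @param table samples x OTUs count matrix.
#' @param depth target reads per sample; `"auto"` uses the minimum row sum.
#' @param seed integer RNG seed (logged in the `rarefy_seed` attribute).
#' @return rarefied table; every row sums exactly to `depth`.
#' @export
rarefy <- function(table, depth = "auto", seed = 1L) {
  table <- validate_otu_table(table)
  rs <- rowSums(table)
  if (identical(depth, "auto")) depth <- min(rs)
  depth <- check_count(depth, "depth")
  short <- rownames(table)[rs < depth]
  if (length(short))
    stop_ga("rarefaction depth %d exceeds the total of %d sample(s): %s",
            depth, length(short), paste(short, collapse = ", "))
  seed <- check_count(seed, "seed", min = 0L)
  out <- table
  with_seed(seed, {
    for (i in seq_len(nrow(table))) {
      if (rs[i] == depth) next
      x <- table[i, ]
      keep <- sample.int(rs[i], depth)  # which individuals survive
      cum <- cumsum(x)
      out[i, ] <- tabulate(findInterval(keep, cum + 0.5) + 1L, nbins = ncol(table))
    }
  })
  attr(out, "rarefy_depth") <- depth
  attr(out, "rarefy_seed") <- seed
  out
}

#' Transform scheme for analysis-scale variables
#'
#' Defaults follow the usual normalization of skewed field variables:
#' square-root for SM, SEC, SAP, NH4N, NO3N; log10 for LA, SLA, RL, SRL,
#' RNC.
#'
#' @param sqrt_vars,log10_vars disjoint character vectors of variable names.
#' @return list of class `transform_scheme`.
#' @export
transform_scheme <- function(sqrt_vars = c("SM", "SEC", "SAP", "NH4N", "NO3N"),
                             log10_vars = c("LA", "SLA", "RL", "SRL", "RNC")) {
  if (length(intersect(sqrt_vars, log10_vars)))
    stop_ga("sqrt and log10 variable sets overlap: %s",
            paste(intersect(sqrt_vars, log10_vars), collapse = ", "))
  structure(list(sqrt_vars = sqrt_vars, log10_vars = log10_vars),
            class = "transform_scheme")
}

#' Apply a transform scheme to a data.frame
#'
#' Named variables are replaced in place (other columns untouched); applied
#' transforms are recorded in the `transforms` attribute.  Negative values
#' under sqrt or non-positive under log10 raise an error naming the variable
#' and the offending row.
#'
#' @param data data.frame (metadata or traits).
#' @param scheme a [transform_scheme()].
#' @param id_col column used to name offending rows in errors.
#' @return transformed data.frame.
#' @export
apply_transforms <- function(data, scheme = transform_scheme(),
                             id_col = intersect(c("sample_id", "species"),
                                                colnames(data))[1]) {
  stopifnot(inherits(scheme, "transform_scheme"), is.data.frame(data))
  ids <- if (!is.na(id_col) && !is.null(id_col)) as.character(data[[id_col]])
         else as.character(seq_len(nrow(data)))
  applied <- character(0)
  for (v in intersect(scheme$sqrt_vars, colnames(data))) {
    bad <- which(data[[v]] < 0)
    if (length(bad))
      stop_ga("sqrt transform of '%s': negative value %g at '%s'", v,
              data[[v]][bad[1L]], ids[bad[1L]])
    data[[v]] <- sqrt(data[[v]])
    applied <- c(applied, paste0("sqrt(", v, ")"))
  }
  for (v in intersect(scheme$log10_vars, colnames(data))) {
    bad <- which(data[[v]] <= 0)
    if (length(bad))
      stop_ga("log10 transform of '%s': non-positive value %g at '%s'", v,
              data[[v]][bad[1L]], ids[bad[1L]])
    data[[v]] <- log10(data[[v]])
    applied <- c(applied, paste0("log10(", v, ")"))
  }
  attr(data, "transforms") <- applied
  data
}

#' Community-weighted mean of a trait
#'
#' CWM per quadrat: the sum over species of relative abundance times trait
#' value.  Species with positive abundance but a missing trait raise an
#' error (no silent dropping).
#'
#' @param community quadrats x species relative-abundance matrix (rows sum
#'   to 1).
#' @param traits trait data.frame with a `species` column.
#' @param trait trait column name.
#' @return named numeric vector, one CWM per quadrat.
#' @export
community_weighted_mean <- function(community, traits, trait) {
  if (!trait %in% colnames(traits))
    stop_ga("trait '%s' not found in the trait table", trait)
  rs <- rowSums(community)
  if (any(abs(rs - 1) > 1e-6))
    stop_ga("community rows must sum to 1 (quadrat '%s' sums to %g)",
            rownames(community)[which.max(abs(rs - 1))], rs[which.max(abs(rs - 1))])
  tv <- stats::setNames(traits[[trait]], traits$species)
  out <- stats::setNames(numeric(nrow(community)), rownames(community))
  for (q in seq_len(nrow(community))) {
    present <- colnames(community)[community[q, ] > 0]
    missing <- present[!(present %in% names(tv)) | is.na(tv[present])]
    if (length(missing))
      stop_ga("quadrat '%s': species with abundance > 0 lack trait '%s': %s",
              rownames(community)[q], trait, paste(missing, collapse = ", "))
    out[q] <- sum(community[q, present] * tv[present])
  }
  out
}
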