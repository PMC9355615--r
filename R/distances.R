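## The three distance families the inference consumes: Bray-Curtis community
## dissimilarity, standardized Euclidean distance on single attributes, and
## great-circle spatial distance.

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i,j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)`, abundance-weighted,
#' in `[0, 1]`.  A pair of all-zero samples makes the statistic undefined
#' and is an error.
#'
#' @param table samples x OTUs non-negative matrix (counts or relative
#'   abundances).
#' @return labelled symmetric matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop_ga("`table` must be a numeric matrix")
  if (nrow(table) < 2L) stop_ga("Bray-Curtis needs >= 2 samples")
  if (any(table < 0)) stop_ga("negative abundances are not allowed")
  rs <- rowSums(table)
  if (sum(rs == 0) >= 2L)
    stop_ga("Bray-Curtis undefined for all-zero sample pair: %s",
            paste(rownames(table)[rs == 0][1:2], collapse = ", "))
  num <- as.matrix(stats::dist(table, method = "manhattan"))
  den <- outer(rs, rs, "+")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' Standardized Euclidean distance for a single attribute
#'
#' Values are z-scored (sample SD, n-1 denominator); the distance is the
#' absolute z difference.
#'
#' @param values named numeric vector, one value per sample.
#' @return labelled symmetric matrix.
#' @export
standardized_euclidean_1d <- function(values) {
  if (length(values) < 2L) stop_ga("need >= 2 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop_ga("values must be finite and non-missing")
  if (is.null(names(values))) stop_ga("values must carry sample names")
  s <- stats::sd(values)
  if (s == 0) stop_ga("attribute has zero variance; standardized distance undefined")
  z <- (values - mean(values)) / s
  d <- abs(outer(z, z, "-"))
  dimnames(d) <- list(names(values), names(values))
  d
}

## great-circle distance in km on a 6371-km sphere
haversine_km <- function(lat1, lon1, lat2, lon2, cross = FALSE) {
  rad <- pi / 180
  if (cross) {
    ## full matrix between point set 1 and point set 2
    phi1 <- lat1 * rad; phi2 <- lat2 * rad
    dphi <- outer(phi1, phi2, "-")
    dlam <- outer(lon1 * rad, lon2 * rad, "-")
    a <- sin(dphi / 2)^2 + outer(cos(phi1), cos(phi2)) * sin(dlam / 2)^2
    return(2 * 6371 * asin(pmin(sqrt(a), 1)))
  }
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * 6371 * asin(pmin(sqrt(a), 1))
}

#' Geographic (great-circle) distance matrix
#'
#' Haversine distance in kilometres on a 6371-km sphere, from decimal-degree
#' WGS84 coordinates.
#'
#' @param metadata data.frame with `sample_id`, `latitude`, `longitude`
#'   columns, or a matrix/data.frame with `latitude`/`longitude` and row
#'   names.
#' @return labelled symmetric matrix (km).
#' @export
geographic_distance <- function(metadata) {
  lat <- metadata$latitude
  lon <- metadata$longitude
  ids <- metadata$sample_id %||% rownames(metadata)
  if (is.null(lat) || is.null(lon) || is.null(ids))
    stop_ga("metadata must provide sample_id, latitude and longitude")
  if (any(lat < -90 | lat > 90)) stop_ga("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop_ga("longitude outside [-180, 180]")
  d <- haversine_km(lat, lon, lat, lon, cross = TRUE)
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}
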