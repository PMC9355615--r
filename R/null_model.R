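## Abundance-weighted beta-null deviation.  The regional species-abundance
## distribution is fixed at the observed table's column totals; null
## communities re-draw each sample's individuals multinomially from it, so
## each null sample keeps its observed total.  The deviation compares
## observed Bray-Curtis dissimilarity with its null distribution, by default
## as a standardized effect size (ses): (obs - null mean) / null sd.

#' Generate null community tables
#'
#' Regional probabilities are the observed column sums normalized; each null
#' replicate redraws every sample multinomially at its observed total.
#'
#' @param table samples x OTUs count matrix.
#' @param n_null number of null replicates.
#' @param seed integer RNG seed.
#' @return list of `n_null` count matrices with the observed dimnames and
#'   row totals.
#' @export
null_communities <- function(table, n_null, seed = 1L) {
  table <- validate_otu_table(table)
  n_null <- check_count(n_null, "n_null")
  if (sum(table) == 0) stop_ga("empty table: no individuals to resample")
  p <- colSums(table) / sum(table)
  rs <- rowSums(table)
  with_seed(seed, {
    lapply(seq_len(n_null), function(b) {
      m <- vapply(rs, function(n) as.numeric(stats::rmultinom(1L, n, p)),
                  numeric(ncol(table)))
      m <- t(matrix(m, nrow = ncol(table)))
      dimnames(m) <- dimnames(table)
      m
    })
  })
}

## chunked accumulation of null Bray-Curtis moments; returns lower-triangle
## running sums (s1, s2) without materializing all nulls
null_bc_moments <- function(table, n_null, seed, chunk = 100L) {
  p <- colSums(table) / sum(table)
  rs <- rowSums(table)
  n_s <- nrow(table)
  n_o <- ncol(table)
  pairs <- which(lower.tri(matrix(0, n_s, n_s)), arr.ind = TRUE)  # (row > col)
  den <- rs[pairs[, 1L]] + rs[pairs[, 2L]]
  s1 <- s2 <- numeric(nrow(pairs))
  with_seed(seed, {
    done <- 0L
    while (done < n_null) {
      B <- min(chunk, n_null - done)
      ## A: n_otus x (n_samples * B), sample-major within each replicate
      A <- matrix(0, n_o, n_s * B)
      equal <- length(unique(rs)) == 1L
      if (equal) {
        A[] <- stats::rmultinom(n_s * B, rs[1L], p)
      } else {
        for (s in seq_len(n_s))
          A[, s + n_s * (seq_len(B) - 1L)] <- stats::rmultinom(B, rs[s], p)
      }
      base <- n_s * (seq_len(B) - 1L)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1L]; j <- pairs[k, 2L]
        num <- colSums(abs(A[, base + i, drop = FALSE] -
                             A[, base + j, drop = FALSE]))
        bc <- num / den[k]
        s1[k] <- s1[k] + sum(bc)
        s2[k] <- s2[k] + sum(bc * bc)
      }
      done <- done + B
    }
  })
  list(pairs = pairs, s1 = s1, s2 = s2)
}

#' Beta-null deviation of a community table
#'
#' @param table samples x OTUs count matrix (rarefied tables recommended;
#'   unequal totals are allowed).
#' @param n_null number of null communities (default 999; a warning is
#'   issued below 99).
#' @param mode `"ses"` (default): deviation = (observed - null mean) / null
#'   sd; `"raw"`: observed - null mean.
#' @param seed integer RNG seed.
#' @return object of class `beta_deviation`: list with `observed_beta`,
#'   `null_mean`, `null_sd`, `deviation` (signed matrix; cells with zero
#'   null sd in ses mode are NA and listed in `flagged`), `n_null`, `mode`,
#'   `seed`.
#' @export
beta_deviation <- function(table, n_null = 999L, mode = c("ses", "raw"),
                           seed = 1L) {
  table <- validate_otu_table(table)
  mode <- match.arg(mode)
  n_null <- check_count(n_null, "n_null")
  seed <- check_count(seed, "seed", min = 0L)
  if (nrow(table) < 2L) stop_ga("need >= 2 samples")
  if (n_null < 99L)
    warning(sprintf("n_null = %d is low for inference; 999 is conventional", n_null))
  obs <- bray_curtis(table)
  mom <- null_bc_moments(table, n_null, seed)
  n_s <- nrow(table)
  mmat <- smat <- matrix(0, n_s, n_s, dimnames = dimnames(obs))
  mu <- mom$s1 / n_null
  va <- if (n_null > 1L) pmax(0, (mom$s2 - n_null * mu^2) / (n_null - 1L)) else
    rep(NA_real_, length(mu))
  mmat[mom$pairs] <- mu; mmat[mom$pairs[, 2:1, drop = FALSE]] <- mu
  smat[mom$pairs] <- sqrt(va); smat[mom$pairs[, 2:1, drop = FALSE]] <- sqrt(va)
  dev <- obs - mmat
  flagged <- character(0)
  if (mode == "ses") {
    dev <- dev / smat
    diag(dev) <- 0
    zero_sd <- which(smat == 0 & upper.tri(smat) | smat == 0 & lower.tri(smat))
    if (length(zero_sd)) {
      dev[zero_sd] <- NA_real_
      idx <- which(is.na(dev) & lower.tri(dev), arr.ind = TRUE)
      flagged <- apply(idx, 1L, function(r)
        paste(rownames(dev)[r[1L]], colnames(dev)[r[2L]], sep = " ~ "))
    }
  }
  diag(dev) <- 0
  attr(dev, "signed") <- TRUE
  structure(list(observed_beta = obs, null_mean = mmat, null_sd = smat,
                 deviation = dev, n_null = n_null, mode = mode, seed = seed,
                 flagged = flagged),
            class = "beta_deviation")
}

#' @export
print.beta_deviation <- function(x, ...) {
  cat(sprintf("beta-null deviation: %d samples, %d nulls, mode = %s\n",
              nrow(x$deviation), x$n_null, x$mode))
  v <- lower_tri(x$deviation)
  cat(sprintf("  mean deviation: %.4f (range %.4f .. %.4f, %d flagged cells)\n",
              mean(v, na.rm = TRUE), min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              length(x$flagged)))
  invisible(x)
}

#' One-sample t-test of the mean beta deviation against zero
#'
#' Two-sided classical t-test over the lower-triangle deviations, treating
#' pairwise values as observations (`by = "pairs"`, the field's reporting
#' convention).  Pairwise deviations sharing samples are positively
#' correlated, so this p-value is anti-conservative (noted in the returned
#' `caveat`); `by = "samples"` instead tests the per-sample mean deviations,
#' which is less inflated though still approximate.
#'
#' @param result a `beta_deviation` object (or a signed deviation matrix).
#' @param by `"pairs"` (default) or `"samples"`.
#' @return list: `mean`, `t`, `df`, `p`, `n`, `by`, `caveat`.
#' @export
mean_deviation_test <- function(result, by = c("pairs", "samples")) {
  by <- match.arg(by)
  dev <- if (inherits(result, "beta_deviation")) result$deviation else result
  v <- if (by == "pairs") {
    lower_tri(dev)
  } else {
    dd <- dev
    diag(dd) <- NA
    rowMeans(dd, na.rm = TRUE)
  }
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop_ga("need >= 2 defined pairwise deviations")
  caveat <- "pairwise deviations are not independent; p is approximate"
  if (stats::sd(v) == 0) {
    if (mean(v) == 0)
      return(list(mean = 0, t = 0, df = length(v) - 1L, p = 1, n = length(v),
                  by = by, caveat = caveat))
    stop_ga("deviations are constant and nonzero; t statistic undefined")
  }
  tt <- stats::t.test(v, mu = 0, alternative = "two.sided")
  list(mean = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, n = length(v),
       by = by, caveat = caveat)
}
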