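## Permutation inference on distance matrices.  All statistics operate on
## the same canonical lower-triangle vectorization in a fixed label order,
## and all permutation schemes permute rows and columns of the *response*
## matrix simultaneously (predictors fixed), with (count + 1)/(n_perm + 1)
## smoothing for Monte-Carlo p-values.  `exact = TRUE` enumerates all n!
## sample permutations (small n), in which case p = count / n! with the
## identity included.

PERM_EPS <- 1e-12  # tie tolerance when comparing permuted statistics

perm_set <- function(n, n_perm, seed, exact) {
  if (exact) {
    if (n > 8L) stop_ga("exact enumeration limited to n <= 8 samples (n! permutations)")
    return(all_perms(n))
  }
  with_seed(seed, t(vapply(seq_len(n_perm), function(i) sample.int(n),
                           integer(n))))
}

perm_pvalue <- function(obs, perm_stats, exact, n_perm) {
  count <- sum(perm_stats >= obs - PERM_EPS)
  if (exact) count / length(perm_stats) else (count + 1) / (n_perm + 1)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles; significance by simultaneous
#' row/column permutation of `dx`.
#'
#' @param dx,dy labelled square matrices with identical labels.
#' @param n_perm number of permutations (ignored when `exact = TRUE`).
#' @param seed integer RNG seed.
#' @param alternative `"two.sided"` (default; compares |r|) or `"greater"`.
#' @param exact enumerate all n! permutations (n <= 8).
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`,
#'   `alternative`, `controlled` (NULL here).
#' @export
mantel <- function(dx, dy, n_perm = 999L, seed = 1L,
                   alternative = c("two.sided", "greater"), exact = FALSE) {
  alternative <- match.arg(alternative)
  check_aligned(list(dx, dy))
  vy <- lower_tri(dy)
  vx <- lower_tri(dx)
  keep <- !is.na(vy)   # response cells flagged NA (e.g. undefined ses) drop out
  if (sum(keep) < 3L) stop_ga("fewer than 3 defined response cells")
  if (stats::sd(vx[keep]) == 0 || stats::sd(vy[keep]) == 0)
    stop_ga("a matrix has zero lower-triangle variance; Mantel r undefined")
  r <- stats::cor(vx[keep], vy[keep])
  P <- perm_set(nrow(dx), n_perm, seed, exact)
  stat <- function(v) if (alternative == "two.sided") abs(v) else v
  perm_r <- vapply(seq_len(nrow(P)), function(b) {
    p <- P[b, ]
    stats::cor(lower_tri(dx[p, p])[keep], vy[keep])
  }, numeric(1))
  structure(list(r = r, p = perm_pvalue(stat(r), stat(perm_r), exact, n_perm),
                 n_perm = if (exact) nrow(P) else n_perm,
                 alternative = alternative, controlled = NULL, exact = exact),
            class = "mantel_result")
}

partial_r <- function(rxy, rxz, ryz) {
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den == 0) stop_ga("control matrix is perfectly collinear with x or y; partial r undefined")
  (rxy - rxz * ryz) / den
}

#' Partial Mantel test
#'
#' Correlation between `dx` and `dy` controlling for `dz` via the
#' first-order partial correlation of lower triangles; permutation of `dx`
#' recomputes the partial statistic (`r_yz` is fixed).
#'
#' @inheritParams mantel
#' @param dz control distance matrix.
#' @param controlled label stored in the result (defaults to "dz").
#' @return `mantel_result` with `controlled` set.
#' @export
partial_mantel <- function(dx, dy, dz, n_perm = 999L, seed = 1L,
                           alternative = c("two.sided", "greater"),
                           exact = FALSE, controlled = "dz") {
  alternative <- match.arg(alternative)
  check_aligned(list(dx, dy, dz))
  vx <- lower_tri(dx); vy <- lower_tri(dy); vz <- lower_tri(dz)
  keep <- !is.na(vy) & !is.na(vz)
  if (sum(keep) < 4L) stop_ga("fewer than 4 defined response cells")
  vx0 <- vx[keep]; vy0 <- vy[keep]; vz0 <- vz[keep]
  if (any(vapply(list(vx0, vy0, vz0), stats::sd, numeric(1)) == 0))
    stop_ga("a matrix has zero lower-triangle variance")
  ryz <- stats::cor(vy0, vz0)
  r <- partial_r(stats::cor(vx0, vy0), stats::cor(vx0, vz0), ryz)
  P <- perm_set(nrow(dx), n_perm, seed, exact)
  stat <- function(v) if (alternative == "two.sided") abs(v) else v
  perm_r <- vapply(seq_len(nrow(P)), function(b) {
    p <- P[b, ]
    vxp <- lower_tri(dx[p, p])[keep]
    partial_r(stats::cor(vxp, vy0), stats::cor(vxp, vz0), ryz)
  }, numeric(1))
  structure(list(r = r, p = perm_pvalue(stat(r), stat(perm_r), exact, n_perm),
                 n_perm = if (exact) nrow(P) else n_perm,
                 alternative = alternative, controlled = controlled, exact = exact),
            class = "mantel_result")
}

mrm_design <- function(dy, predictors, standardize) {
  if (!length(predictors)) stop_ga("MRM needs >= 1 predictor matrix")
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    stop_ga("predictor matrices must be named")
  check_aligned(c(list(dy), unname(predictors)))
  X <- vapply(predictors, lower_tri, numeric(sum(lower.tri(dy))))
  X <- as.matrix(X)
  if (anyNA(X)) stop_ga("predictor matrices must not contain missing cells")
  vy <- lower_tri(dy)   # NA response cells (flagged ses) are masked at fit time
  if (sum(!is.na(vy)) < ncol(X) + 2L)
    stop_ga("too few defined response cells for %d predictor(s)", ncol(X))
  mu_y <- mean(vy, na.rm = TRUE)
  sd_y <- stats::sd(vy, na.rm = TRUE)
  if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0))
      stop_ga("predictor '%s' has zero variance", names(predictors)[sds == 0][1L])
    X <- scale(X)
    if (sd_y == 0) stop_ga("response has zero lower-triangle variance")
    vy <- (vy - mu_y) / sd_y
  }
  if (ncol(X) > 1L) {
    cc <- stats::cor(X)
    cc[upper.tri(cc, diag = TRUE)] <- 0
    w <- which(abs(cc) > 0.999, arr.ind = TRUE)
    if (nrow(w))
      stop_ga("collinear predictors: '%s' and '%s' (|r| > 0.999)",
              names(predictors)[w[1L, 2L]], names(predictors)[w[1L, 1L]])
  }
  list(X = X, vy = vy, mu_y = mu_y, sd_y = sd_y)
}

ols_fit <- function(X, y) {
  keep <- !is.na(y)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[keep, , drop = FALSE]),
                       y[keep])
  rss <- sum(fit$residuals^2)
  tss <- sum((y[keep] - mean(y[keep]))^2)
  list(coef = fit$coefficients[-1L], r2 = 1 - rss / tss)
}

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the response matrix's lower triangle on predictor triangles
#' (z-scored by default, so coefficients are standardized).  Per-coefficient
#' and whole-model p-values come from simultaneous row/column permutation of
#' the response only: the per-coefficient statistic is |b|, the model
#' statistic is R-squared.
#'
#' @param dy response distance matrix (signed matrices allowed).
#' @param predictors named list of predictor distance matrices.
#' @param n_perm permutations (0 skips inference; p's are NA).
#' @param seed integer RNG seed.
#' @param standardize z-score response and predictor triangles.
#' @param exact enumerate all n! permutations (n <= 8).
#' @return list of class `mrm_result`: `selected` (predictor names),
#'   `coefficients`, `r_squared`, `p_per_predictor`, `p_model`, `n_perm`.
#' @export
mrm <- function(dy, predictors, n_perm = 999L, seed = 1L, standardize = TRUE,
                exact = FALSE) {
  d <- mrm_design(dy, predictors, standardize)
  obs <- ols_fit(d$X, d$vy)
  p_coef <- rep(NA_real_, length(obs$coef))
  p_model <- NA_real_
  if (exact || n_perm > 0L) {
    P <- perm_set(nrow(dy), n_perm, seed, exact)
    nB <- nrow(P)
    cnt_coef <- numeric(length(obs$coef))
    cnt_model <- 0
    for (b in seq_len(nB)) {
      p <- P[b, ]
      vyp <- lower_tri(dy[p, p])
      if (standardize) vyp <- (vyp - d$mu_y) / d$sd_y
      f <- ols_fit(d$X, vyp)
      cnt_coef <- cnt_coef + (abs(f$coef) >= abs(obs$coef) - PERM_EPS)
      cnt_model <- cnt_model + (f$r2 >= obs$r2 - PERM_EPS)
    }
    if (exact) {
      p_coef <- cnt_coef / nB
      p_model <- cnt_model / nB
    } else {
      p_coef <- (cnt_coef + 1) / (n_perm + 1)
      p_model <- (cnt_model + 1) / (n_perm + 1)
    }
  }
  structure(list(selected = names(predictors),
                 coefficients = stats::setNames(obs$coef, names(predictors)),
                 r_squared = obs$r2,
                 p_per_predictor = stats::setNames(p_coef, names(predictors)),
                 p_model = p_model,
                 n_perm = if (exact) NA_integer_ else n_perm, exact = exact),
            class = "mrm_result")
}

#' Forward selection of MRM predictors
#'
#' Iteratively adds the candidate with the largest R-squared increase whose
#' marginal permutation p (in the model containing already-selected terms)
#' is below `alpha`; stops when no candidate qualifies.  Ties on the
#' R-squared gain are broken by candidate name order.
#'
#' @inheritParams mrm
#' @param candidates named list of candidate predictor matrices.
#' @param alpha entry threshold (default 0.05).
#' @return `mrm_result` for the final model (empty selection gives
#'   `r_squared = 0`), with a `path` attribute recording entry order and
#'   marginal p-values.
#' @export
forward_select_mrm <- function(dy, candidates, alpha = 0.05, n_perm = 999L,
                               seed = 1L, exact = FALSE) {
  alpha <- check_number(alpha, "alpha", 0, strict = TRUE)
  if (alpha > 1) stop_ga("`alpha` must lie in (0, 1]")
  selected <- character(0)
  path <- list()
  remaining <- names(candidates)
  step_seed <- seed
  repeat {
    if (!length(remaining)) break
    gains <- vapply(remaining, function(nm) {
      mrm(dy, candidates[c(selected, nm)], n_perm = 0L, seed = step_seed)$r_squared
    }, numeric(1))
    base_r2 <- if (length(selected))
      mrm(dy, candidates[selected], n_perm = 0L, seed = step_seed)$r_squared else 0
    ord <- remaining[order(-(gains - base_r2), remaining)]
    entered <- FALSE
    for (nm in ord) {
      fit <- mrm(dy, candidates[c(selected, nm)], n_perm = n_perm,
                 seed = step_seed, exact = exact)
      p_marg <- fit$p_per_predictor[[nm]]
      ## alpha = 1 is the documented degenerate threshold: everything enters
      if (alpha >= 1 || (!is.na(p_marg) && p_marg < alpha)) {
        selected <- c(selected, nm)
        remaining <- setdiff(remaining, nm)
        path[[nm]] <- list(r_squared = fit$r_squared, p = p_marg)
        entered <- TRUE
        break
      }
    }
    if (!entered) break
    step_seed <- step_seed + 1L
  }
  if (!length(selected)) {
    out <- structure(list(selected = character(0), coefficients = numeric(0),
                          r_squared = 0, p_per_predictor = numeric(0),
                          p_model = NA_real_, n_perm = n_perm, exact = exact),
                     class = "mrm_result")
  } else {
    out <- mrm(dy, candidates[selected], n_perm = n_perm, seed = seed,
               exact = exact)
  }
  attr(out, "path") <- path
  out
}

#' Variation partitioning between environmental and spatial predictors
#'
#' R-squared decomposition from three MRM fits (full, environment-only,
#' space-only).  Pure environmental fraction = R2(full) - R2(space); pure
#' spatial = R2(full) - R2(env); shared = R2(env) + R2(space) - R2(full);
#' unexplained = 1 - R2(full).  The four fractions sum to 1 exactly.  Pure
#' environmental effects are read as environmental selection; pure spatial
#' effects as dispersal limitation.
#'
#' @param dy response distance matrix.
#' @param env,space named lists of predictor distance matrices.
#' @param adjusted use adjusted R-squared (may yield small negative pure
#'   fractions; flagged in the result).
#' @return list of class `vpa_result`: `pure_env`, `pure_space`, `shared`,
#'   `unexplained`, `r2` (the three fits), `adjusted`.
#' @export
variation_partitioning <- function(dy, env, space, adjusted = FALSE) {
  if (!length(env) || !length(space))
    stop_ga("both predictor groups must be non-empty")
  r2_of <- function(preds) {
    ## drop predictors exactly collinear with an earlier one (R2 unchanged;
    ## lets env == space degenerate cases resolve to pure shared variance)
    keep <- 1L
    for (i in seq_along(preds)[-1L]) {
      cc <- vapply(keep, function(j)
        abs(stats::cor(lower_tri(preds[[i]]), lower_tri(preds[[j]]))), numeric(1))
      if (all(cc <= 0.999)) keep <- c(keep, i)
    }
    f <- mrm(dy, preds[keep], n_perm = 0L)
    if (!adjusted) return(f$r_squared)
    n <- sum(lower.tri(dy)); k <- length(keep)
    1 - (1 - f$r_squared) * (n - 1) / (n - k - 1)
  }
  r2_full <- r2_of(c(env, space))
  r2_env <- r2_of(env)
  r2_space <- r2_of(space)
  structure(list(pure_env = r2_full - r2_space,
                 pure_space = r2_full - r2_env,
                 shared = r2_env + r2_space - r2_full,
                 unexplained = 1 - r2_full,
                 r2 = c(full = r2_full, env = r2_env, space = r2_space),
                 adjusted = adjusted),
            class = "vpa_result")
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational analysis of variance: pseudo-F from total and
#' within-group sums of squared distances, significance by permuting sample
#' group labels.
#'
#' @param d labelled distance matrix.
#' @param groups group label per sample (same order as `d`).
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @param exact enumerate all n! permutations (n <= 8).
#' @return list: `pseudo_F`, `p`, `df_between`, `df_within`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L, exact = FALSE) {
  d <- validate_dist_matrix(d, signed = TRUE)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop_ga("`groups` must give one label per sample")
  tab <- table(groups)
  if (length(tab) < 2L) stop_ga("PERMANOVA needs >= 2 groups")
  if (any(tab < 2L))
    stop_ga("group '%s' is a singleton", names(tab)[tab < 2L][1L])
  d2 <- d^2
  a <- length(tab)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  pseudo_f <- function(g) {
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
    }
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- pseudo_f(groups)
  P <- perm_set(n, n_perm, seed, exact)
  f_perm <- vapply(seq_len(nrow(P)), function(b) pseudo_f(groups[P[b, ]]),
                   numeric(1))
  list(pseudo_F = f_obs, p = perm_pvalue(f_obs, f_perm, exact, n_perm),
       df_between = a - 1L, df_within = n - a,
       n_perm = if (exact) nrow(P) else n_perm)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via vegan's engine, best of `n_starts` random
#' initializations.
#'
#' @param d labelled distance matrix (non-negative).
#' @param k embedding dimension (default 2; must be < number of samples).
#' @param n_starts random starts (default 20).
#' @param seed integer RNG seed.
#' @return list: `coords` (samples x k), `stress` (fraction in `[0, 1]`),
#'   `converged`.
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, seed = 1L) {
  d <- validate_dist_matrix(d)
  k <- check_count(k, "k")
  if (k >= nrow(d)) stop_ga("k must be smaller than the number of samples")
  fit <- with_seed(seed, suppressWarnings(suppressMessages(
    vegan::metaMDS(stats::as.dist(d), k = k, try = n_starts, trymax = n_starts,
                   trace = 0, autotransform = FALSE, wascores = FALSE,
                   sratmax = 1 - 1e-6))))
  coords <- fit$points
  colnames(coords) <- paste0("NMDS", seq_len(k))
  list(coords = coords, stress = fit$stress, converged = fit$converged > 0)
}

## compact letter display by insert-and-absorb over the significance graph
letter_display <- function(labels, sig_pairs) {
  cols <- list(labels)
  for (k in seq_len(nrow(sig_pairs))) {
    i <- sig_pairs[k, 1L]; j <- sig_pairs[k, 2L]
    nxt <- list()
    for (cl in cols) {
      if (i %in% cl && j %in% cl) {
        nxt <- c(nxt, list(setdiff(cl, i)), list(setdiff(cl, j)))
      } else nxt <- c(nxt, list(cl))
    }
    keep <- rep(TRUE, length(nxt))  # absorb subsets
    for (aa in seq_along(nxt)) for (bb in seq_along(nxt))
      if (aa != bb && keep[aa] && all(nxt[[aa]] %in% nxt[[bb]]) &&
          (length(nxt[[aa]]) < length(nxt[[bb]]) || aa > bb)) keep[aa] <- FALSE
    cols <- nxt[keep]
  }
  lets <- letters[seq_along(cols)]
  vapply(labels, function(l)
    paste(lets[vapply(cols, function(cl) l %in% cl, logical(1))], collapse = ""),
    character(1))
}

#' Category contrasts of pairwise deviations along an attribute gradient
#'
#' Samples are binned by quantiles of a (transformed) attribute (terciles
#' for 3 categories, median split for 2).  A pairwise deviation belongs to a
#' bin only when *both* samples fall in that bin; within-bin distributions
#' are compared with pairwise Wilcoxon rank-sum tests and summarized with a
#' compact letter display (bins sharing a letter are not significantly
#' different at `alpha`).
#'
#' @param deviation signed pairwise deviation matrix.
#' @param attribute named numeric vector, one value per sample (same
#'   labels).
#' @param n_categories 2 or 3.
#' @param alpha significance level for the letter display.
#' @return list of class `category_contrast`: `summary` (per-bin n_pairs,
#'   mean, median, letter), `p_matrix`, `bins` (per-sample bin), `excluded`
#'   (bins with < 2 within-bin pairs).
#' @export
category_contrast <- function(deviation, attribute, n_categories = 3L,
                              alpha = 0.05) {
  deviation <- validate_dist_matrix(deviation, signed = TRUE)
  n_categories <- check_count(n_categories, "n_categories", min = 2L)
  if (n_categories > 3L) stop_ga("n_categories must be 2 or 3")
  if (is.null(names(attribute)) ||
      !setequal(names(attribute), rownames(deviation)))
    stop_ga("attribute must be named with the deviation matrix's sample labels")
  attribute <- attribute[rownames(deviation)]
  qs <- stats::quantile(attribute, probs = seq(0, 1, length.out = n_categories + 1L),
                        names = FALSE)
  qs[1L] <- -Inf; qs[length(qs)] <- Inf
  labs <- if (n_categories == 2L) c("low", "high") else c("low", "medium", "high")
  bins <- stats::setNames(as.character(cut(attribute, breaks = qs, labels = labs,
                                           include.lowest = TRUE)),
                          names(attribute))
  vals <- lapply(labs, function(b) {
    idx <- which(bins == b)
    if (length(idx) < 2L) return(numeric(0))
    v <- lower_tri(deviation[idx, idx, drop = FALSE])
    v[!is.na(v)]
  })
  names(vals) <- labs
  excluded <- labs[vapply(vals, length, integer(1)) < 2L]
  use <- setdiff(labs, excluded)
  pm <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(use)) for (j in seq_along(use)) if (i < j) {
    p <- suppressWarnings(stats::wilcox.test(vals[[use[i]]], vals[[use[j]]],
                                             exact = FALSE)$p.value)
    pm[use[i], use[j]] <- pm[use[j], use[i]] <- p
  }
  sig <- which(pm < alpha & upper.tri(pm), arr.ind = TRUE)
  sig_pairs <- cbind(rownames(pm)[sig[, 1L]], colnames(pm)[sig[, 2L]])
  letter <- stats::setNames(rep(NA_character_, length(labs)), labs)
  if (length(use))
    letter[use] <- letter_display(use,
                                  sig_pairs[sig_pairs[, 1L] %in% use &
                                              sig_pairs[, 2L] %in% use, ,
                                            drop = FALSE])
  structure(list(
    summary = data.frame(
      category = labs,
      n_samples = vapply(labs, function(b) sum(bins == b), integer(1)),
      n_pairs = vapply(vals, length, integer(1)),
      mean = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, numeric(1)),
      median = vapply(vals, function(v) if (length(v)) stats::median(v) else NA_real_,
                      numeric(1)),
      letter = letter, row.names = NULL, stringsAsFactors = FALSE),
    p_matrix = pm, bins = bins, excluded = excluded, alpha = alpha),
    class = "category_contrast")
}
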