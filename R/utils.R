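#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ga <- function(fmt, ..., class = "guildassembly_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

check_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_ga("`%s` must be TRUE or FALSE", nm)
  x
}

check_count <- function(x, nm, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_ga("`%s` must be a single integer >= %d", nm, min)
  as.integer(x)
}

check_number <- function(x, nm, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min))
    stop_ga("`%s` must be a single finite number %s %s", nm,
            if (strict) ">" else ">=", format(min))
  as.numeric(x)
}

#' Validate an OTU table
#'
#' An OTU table is a numeric matrix of non-negative integer counts with
#' samples as rows and OTUs as columns, both uniquely named.
#'
#' @param x matrix to validate.
#' @param what label used in error messages.
#' @return the validated matrix (storage mode integer-valued numeric).
#' @export
validate_otu_table <- function(x, what = "otu table") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_ga("%s must be a numeric matrix (samples x OTUs)", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_ga("%s must have sample rownames and OTU colnames", what)
  if (anyDuplicated(rownames(x))) stop_ga("%s has duplicated sample IDs", what)
  if (anyDuplicated(colnames(x))) stop_ga("%s has duplicated OTU IDs", what)
  if (anyNA(x)) stop_ga("%s contains missing counts", what)
  if (any(x < 0)) stop_ga("%s contains negative counts", what)
  if (any(x != floor(x))) stop_ga("%s contains non-integer counts", what)
  x
}

#' Validate a labelled distance matrix
#'
#' Square, symmetric (within `tol`), zero diagonal, matching row/column
#' labels.  Signed matrices (beta-deviation) are permitted negative values
#' when `signed = TRUE` or when the matrix carries a `signed` attribute.
#'
#' @param d matrix to validate.
#' @param signed allow negative off-diagonal values.
#' @param tol symmetry tolerance.
#' @param what label used in error messages.
#' @return the validated matrix.
#' @export
validate_dist_matrix <- function(d, signed = isTRUE(attr(d, "signed")),
                                 tol = 1e-6, what = "distance matrix") {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop_ga("%s must be a square numeric matrix", what)
  if (is.null(rownames(d)) || is.null(colnames(d)))
    stop_ga("%s must carry sample labels", what)
  if (!identical(rownames(d), colnames(d)))
    stop_ga("%s row labels differ from column labels", what)
  if (anyDuplicated(rownames(d))) stop_ga("%s has duplicated labels", what)
  asym <- max(abs(d - t(d)), na.rm = TRUE)
  if (is.finite(asym) && asym > tol)
    stop_ga("%s is asymmetric (max |d - t(d)| = %g > %g)", what, asym, tol)
  if (any(abs(diag(d)) > tol, na.rm = TRUE))
    stop_ga("%s has a nonzero diagonal", what)
  if (!signed && any(d < -tol, na.rm = TRUE))
    stop_ga("%s has negative entries but is not flagged as signed", what)
  d
}

## lower-triangle vectorization in a fixed (label) order: the canonical
## form every matrix statistic operates on
lower_tri <- function(d) d[lower.tri(d)]

check_aligned <- function(mats, what = "distance matrices") {
  labs <- rownames(mats[[1L]])
  for (m in mats[-1L])
    if (!identical(rownames(m), labs))
      stop_ga("%s do not share identical sample labels/order", what)
  invisible(labs)
}

## all permutations of 1..n, as a n! x n integer matrix (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    idx <- seq_len(nrow(sub)) + r
    out[idx, 1L] <- k
    rest <- seq_len(n)[-k]
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}
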