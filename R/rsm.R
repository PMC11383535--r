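#' Construct a model RSM container
#'
#' @param values n x n numeric similarity matrix.
#' @param item_ids ordered item labels (defaults to rownames).
#' @param category one of `"visual"`, `"semantic"`, `"residual-visual"`,
#'   `"residual-semantic"`.
#' @export
model_rsm <- function(values, item_ids = rownames(values), category) {
  values <- as.matrix(values)
  if (is.null(item_ids)) item_ids <- sprintf("item_%d", seq_len(nrow(values)))
  category <- match.arg(category, c("visual", "semantic",
                                    "residual-visual", "residual-semantic"))
  resid <- startsWith(category, "residual")
  off <- values[lower.tri(values)]
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("RSM must be symmetric")
  if (!resid) {
    if (any(abs(diag(values) - 1) > 1e-12)) stop("RSM diagonal must be 1")
    if (any(off < -1 - 1e-12 | off > 1 + 1e-12))
      stop("RSM entries must lie in [-1, 1]")
  }
  dimnames(values) <- list(item_ids, item_ids)
  structure(list(item_ids = item_ids, values = values, category = category),
            class = "model_rsm")
}

#' @export
print.model_rsm <- function(x, ...) {
  cat(sprintf("<model_rsm> %s, %d items\n", x$category, length(x$item_ids)))
  invisible(x)
}

#' Build a model RSM from feature norms
#'
#' Cell (i, j) is the Pearson correlation between the feature vectors of
#' concepts i and j restricted to the requested category's features, the
#' standard construction of a stimulus-model similarity matrix from
#' property norms.
#'
#' @param norms a `feature_norms` object.
#' @param category `"visual"` or `"semantic"`.
#' @return A [model_rsm()] of that category.
#' @export
build_model_rsm <- function(norms, category = c("visual", "semantic")) {
  category <- match.arg(category)
  stopifnot(inherits(norms, "feature_norms"))
  sub <- norms$values[, norms$category == category, drop = FALSE]
  if (ncol(sub) < 2) stop("need >= 2 features in category '", category, "'")
  if (nrow(sub) < 3) stop("need >= 3 concepts")
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0))
    stop("zero feature variance over '", category, "' features for concept(s): ",
         paste(rownames(sub)[sds == 0], collapse = ", "))
  model_rsm(stats::cor(t(sub)), item_ids = rownames(sub), category = category)
}

# strict lower triangle, excluding the diagonal
.lower_vec <- function(m) m[lower.tri(m)]

# refold a lower-triangle vector into a symmetric matrix with diagonal `diag`
.refold <- function(v, n, diag_val = NA_real_) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_val
  m
}

.rho_or_na <- function(x, y, method = "spearman") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Compare two RSMs globally and item by item
#'
#' The global comparison is the Spearman rank correlation over the
#' vectorized strict lower triangles; the item-wise comparison correlates
#' each row of the two matrices after removing the self-similarity element.
#' An item whose row is constant in either matrix yields `NA` (reported, not
#' silently zero).
#'
#' @param a,b [model_rsm()] objects over the same items, in the same order.
#' @return list with `global_rho` and `itemwise_rho` (named per item).
#' @export
compare_rsms <- function(a, b) {
  stopifnot(inherits(a, "model_rsm"), inherits(b, "model_rsm"))
  if (!identical(a$item_ids, b$item_ids))
    stop("RSMs must share the same item ordering")
  global_rho <- .rho_or_na(.lower_vec(a$values), .lower_vec(b$values))
  n <- length(a$item_ids)
  itemwise <- vapply(seq_len(n), function(i) {
    .rho_or_na(a$values[i, -i], b$values[i, -i])
  }, numeric(1))
  if (anyNA(itemwise))
    warning(sum(is.na(itemwise)), " item(s) had a constant row; rho reported as NA")
  names(itemwise) <- a$item_ids
  list(global_rho = global_rho, itemwise_rho = itemwise)
}

.ols_resid <- function(y, x) {
  X <- cbind(1, x)
  qr.resid(qr(X), y)
}

#' Mutually residualize two RSMs
#'
#' Removes the shared variance between two model RSMs: the off-diagonal
#' lower triangle of each matrix is regressed (OLS with intercept) on the
#' other's and replaced by the residuals, re-folded to symmetric form with
#' the diagonal marked unused (`NA`). For standardized vectors with
#' correlation r, the two residual vectors have correlation exactly -r, so
#' residual models of partially overlapping feature spaces are expected to
#' be anticorrelated.
#'
#' @param a,b [model_rsm()] objects over the same items.
#' @param per_row if `TRUE`, residualize each item's row (excluding the self
#'   element) on the matching row of the other matrix instead of the whole
#'   vectorized triangle; the asymmetric row-wise result is re-symmetrized
#'   by averaging cell (i, j) with (j, i).
#' @return list with `a_resid` and `b_resid` (categories prefixed
#'   `"residual-"`).
#' @export
residualize_rsms <- function(a, b, per_row = FALSE) {
  stopifnot(inherits(a, "model_rsm"), inherits(b, "model_rsm"))
  if (!identical(a$item_ids, b$item_ids))
    stop("RSMs must share the same item ordering")
  n <- length(a$item_ids)
  res_cat <- function(m) {
    if (startsWith(m$category, "residual")) m$category
    else paste0("residual-", m$category)
  }
  if (!per_row) {
    va <- .lower_vec(a$values); vb <- .lower_vec(b$values)
    if (stats::sd(va) == 0 || stats::sd(vb) == 0)
      stop("zero-variance predictor: cannot residualize degenerate RSM")
    ra <- .refold(.ols_resid(va, vb), n)
    rb <- .refold(.ols_resid(vb, va), n)
  } else {
    ra <- rb <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      xa <- a$values[i, -i]; xb <- b$values[i, -i]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
        stop("zero-variance row for item ", a$item_ids[i])
      ra[i, -i] <- .ols_resid(xa, xb)
      rb[i, -i] <- .ols_resid(xb, xa)
    }
    ra <- (ra + t(ra)) / 2
    rb <- (rb + t(rb)) / 2
    diag(ra) <- diag(rb) <- NA_real_
  }
  list(a_resid = model_rsm(ra, a$item_ids, res_cat(a)),
       b_resid = model_rsm(rb, b$item_ids, res_cat(b)))
}
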