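#' Aitchison-geometry primitives for compositional data
#'
#' A composition is a vector of strictly positive parts carrying only
#' relative information: rescaling it changes nothing.  All multivariate
#' work in this package therefore happens after a log-ratio transform.
#' These primitives operate on plain numeric vectors (one composition) or
#' matrices (one composition per row) and keep dimnames, so they compose
#' with the tibble-based survey functions via [contribution_matrix()].
#'
#' @name coda
NULL

# coerce vector / matrix / data frame to a rows-are-compositions matrix
as_comp_matrix <- function(x) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    ids <- NULL
    if ("site_id" %in% names(x)) ids <- as.character(x$site_id)
    x <- as.matrix(x[num])
    if (!is.null(ids)) rownames(x) <- ids
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  storage.mode(x) <- "double"
  x
}

check_positive <- function(x, what = "composition") {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("all parts of a %s must be finite and strictly positive", what),
         call. = FALSE)
  }
  invisible(x)
}

#' Close a vector of positive parts to a constant sum
#'
#' @param x numeric vector, or matrix with one composition per row.
#' @param kappa closure constant (default 1, i.e. proportions).
#' @return object of the same shape with each composition summing to `kappa`.
#' @examples
#' closure(c(1, 1, 2))
#' @export
closure <- function(x, kappa = 1) {
  m <- as_comp_matrix(x)
  check_positive(m)
  out <- kappa * m / rowSums(m)
  if (is.null(dim(x))) out <- stats::setNames(drop(out), colnames(m))
  out
}

#' Perturbation and powering on the simplex
#'
#' Perturbation (closed element-wise product) and powering (closed
#' element-wise power) are the group operations of Aitchison geometry;
#' centering a data set is perturbation by the inverse of its closed
#' geometric mean.
#'
#' @param x,y compositions with matching parts (`y` may be a single
#'   composition recycled over the rows of `x`).
#' @param a scalar power.
#' @return composition(s) closed to 1.
#' @export
perturb <- function(x, y) {
  mx <- as_comp_matrix(x); my <- as_comp_matrix(y)
  if (!is.null(colnames(mx)) && !is.null(colnames(my))) {
    if (!identical(colnames(mx), colnames(my))) {
      stop("part labels of `x` and `y` do not match", call. = FALSE)
    }
  } else if (ncol(mx) != ncol(my)) {
    stop("`x` and `y` have different numbers of parts", call. = FALSE)
  }
  check_positive(mx); check_positive(my)
  if (nrow(my) == 1L && nrow(mx) > 1L) my <- my[rep(1L, nrow(mx)), , drop = FALSE]
  out <- closure(mx * my)
  if (is.null(dim(x))) out <- stats::setNames(drop(out), colnames(mx))
  out
}

#' @rdname perturb
#' @export
comp_power <- function(x, a) {
  m <- as_comp_matrix(x)
  check_positive(m)
  out <- closure(m^a)
  if (is.null(dim(x))) out <- stats::setNames(drop(out), colnames(m))
  out
}

#' Centred log-ratio transform and its inverse
#'
#' `clr()` maps each composition to log-parts centred on their mean,
#' `clr_inv()` maps back (up to closure).  clr images sum to zero across
#' parts, so their covariance matrix is singular; use [ilr()] when a
#' full-rank representation is needed.
#'
#' @param x composition vector or matrix (rows).
#' @param z clr-image vector or matrix.
#' @return transformed object of the same shape.
#' @export
clr <- function(x) {
  m <- as_comp_matrix(x)
  check_positive(m)
  lg <- log(m)
  out <- lg - rowMeans(lg)
  if (is.null(dim(x))) out <- stats::setNames(drop(out), colnames(m))
  out
}

#' @rdname clr
#' @export
clr_inv <- function(z) {
  m <- as_comp_matrix(z)
  out <- closure(exp(m))
  if (is.null(dim(z))) out <- stats::setNames(drop(out), colnames(m))
  out
}

#' Orthonormal isometric log-ratio basis
#'
#' Returns the (D-1) x D contrast matrix of the standard sequential-binary
#' ilr basis, in which coordinate j contrasts the geometric mean of the
#' first j parts against part j+1:
#' z_j = sqrt(j/(j+1)) * ln( g(x_1..x_j) / x_{j+1} ).
#' Rows are orthonormal and sum to zero.  All distance-based results are
#' invariant to this choice of basis.
#'
#' @param d number of parts (>= 2).
#' @param parts optional part labels for the columns.
#' @return a (d-1) x d matrix `psi` with `psi %*% t(psi) = I`.
#' @export
ilr_basis <- function(d, parts = NULL) {
  if (d < 2) stop("an ilr basis needs at least 2 parts", call. = FALSE)
  psi <- matrix(0, d - 1L, d)
  for (j in seq_len(d - 1L)) {
    psi[j, seq_len(j)] <- sqrt(1 / (j * (j + 1)))
    psi[j, j + 1L] <- -sqrt(j / (j + 1))
  }
  if (!is.null(parts)) colnames(psi) <- parts
  rownames(psi) <- paste0("z", seq_len(d - 1L))
  psi
}

#' Isometric log-ratio transform and inverse
#'
#' `ilr()` is an isometry between the D-part simplex (Aitchison metric) and
#' R^(D-1) (Euclidean metric): Euclidean distances between ilr images equal
#' [aitchison_dist()] between the compositions.
#'
#' @param x composition vector or matrix (rows).
#' @param z ilr-coordinate vector or matrix.
#' @param basis contrast matrix from [ilr_basis()]; defaults to the
#'   sequential-binary basis for the number of parts found.
#' @return coordinate matrix/vector, or composition on inversion.
#' @export
ilr <- function(x, basis = NULL) {
  m <- as_comp_matrix(x)
  if (is.null(basis)) basis <- ilr_basis(ncol(m), colnames(m))
  out <- clr(m) %*% t(basis)
  colnames(out) <- rownames(basis)
  if (is.null(dim(x))) out <- stats::setNames(drop(out), colnames(out))
  out
}

#' @rdname ilr
#' @export
ilr_inv <- function(z, basis = NULL) {
  m <- as_comp_matrix(z)
  if (is.null(basis)) basis <- ilr_basis(ncol(m) + 1L)
  out <- closure(exp(m %*% basis))
  colnames(out) <- colnames(basis)
  if (is.null(dim(z))) out <- stats::setNames(drop(out), colnames(out))
  out
}

#' Aitchison distance
#'
#' The Euclidean distance between clr (equivalently ilr) images.  It is
#' scale invariant, permutation invariant and perturbation invariant, and
#' never increases when passing to a subcomposition.
#'
#' @param x composition vector or matrix (rows).
#' @param y optional second composition; if omitted and `x` is a matrix,
#'   the full pairwise [stats::dist] object is returned.
#' @return a scalar, or a `dist` object for matrix input.
#' @export
aitchison_dist <- function(x, y = NULL) {
  if (is.null(y)) {
    return(stats::dist(clr(as_comp_matrix(x))))
  }
  sqrt(sum((clr(x) - clr(y))^2))
}

#' Log-ratio variation matrix
#'
#' Entry (i, j) is the variance of `log(x_i / x_j)` over the rows; small
#' entries flag near-proportional parts (short biplot links).  The
#' unbiased n-1 estimator is used.
#'
#' @param x matrix or data frame of compositions (rows).
#' @return symmetric D x D matrix with zero diagonal.
#' @export
variation_matrix <- function(x) {
  m <- as_comp_matrix(x)
  if (nrow(m) < 2) stop("variation matrix needs at least 2 compositions", call. = FALSE)
  check_positive(m)
  lg <- log(m)
  d <- ncol(m)
  tv <- matrix(0, d, d, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(d - 1L)) {
    for (j in (i + 1L):d) {
      tv[i, j] <- tv[j, i] <- stats::var(lg[, i] - lg[, j])
    }
  }
  tv
}

#' Centre a compositional data set at the barycentre
#'
#' The centre is the closure of the column-wise geometric means; each row
#' is perturbed by its inverse so the geometric centre of the output is the
#' neutral composition (1/D, ..., 1/D).  Centering is an isometry: it moves
#' the data cloud without distorting Aitchison distances.
#'
#' @param x matrix or data frame of compositions (rows).
#' @return list with `centered` (matrix) and `center` (named vector).
#' @export
center_composition <- function(x) {
  m <- closure(as_comp_matrix(x))
  ctr <- closure(exp(colMeans(log(m))))
  centered <- perturb(m, matrix(1 / ctr, 1, dimnames = list(NULL, colnames(m))))
  list(centered = centered, center = stats::setNames(drop(ctr), colnames(m)))
}

#' Extract and re-close a subcomposition
#'
#' @param x composition vector or matrix (rows).
#' @param parts character labels or integer indices of the parts to keep
#'   (at least 2).
#' @return re-closed composition(s) over the selected parts.
#' @export
subcomposition <- function(x, parts) {
  m <- as_comp_matrix(x)
  if (is.character(parts)) {
    missing <- setdiff(parts, colnames(m))
    if (length(missing)) {
      stop("unknown parts: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  sub <- m[, parts, drop = FALSE]
  if (ncol(sub) < 2) stop("a subcomposition needs at least 2 parts", call. = FALSE)
  out <- closure(sub)
  if (is.null(dim(x))) out <- stats::setNames(drop(out), colnames(sub))
  out
}

#' Planar coordinates for a ternary diagram
#'
#' Maps closed 3-part compositions onto the reference triangle with
#' vertices (0,0), (1,0) and (1/2, sqrt(3)/2) corresponding to parts
#' 1, 2 and 3 (counter-clockwise); the barycentre maps to
#' (1/2, sqrt(3)/6).
#'
#' @param x 3-part composition vector, matrix (rows) or data frame.
#' @return tibble with columns `u`, `v` (and `site_id` when rownames exist).
#' @export
ternary_coords <- function(x) {
  m <- closure(as_comp_matrix(x))
  if (ncol(m) != 3) stop("ternary coordinates require exactly 3 parts", call. = FALSE)
  out <- tibble::tibble(
    u = m[, 2] + m[, 3] / 2,
    v = sqrt(3) / 2 * m[, 3]
  )
  if (!is.null(rownames(m))) out <- tibble::add_column(out, site_id = rownames(m), .before = 1)
  out
}
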