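#' Principal component analysis of compositions in log-ratio coordinates
#'
#' Transforms the compositions to ilr coordinates, estimates location and
#' scatter — by the minimum covariance determinant (MCD, subset fraction
#' 0.75) when `robust = TRUE`, so that a minority of aberrant pollution
#' profiles cannot steer the components, or by the classical mean and
#' covariance otherwise — and eigendecomposes the scatter.  Scores are the
#' centred ilr coordinates projected on the eigenvectors; loadings are
#' back-transformed to clr space (`t(psi) %*% V`), where one ray per part
#' makes the compositional biplot readable.  Results in clr space do not
#' depend on the ilr basis.
#'
#' @param x wide tibble (`site_id` + one column per part) or matrix of
#'   compositions (rows); e.g. from [contribution_matrix()].
#' @param robust use the MCD scatter? (default TRUE)
#' @param h MCD subset fraction (default 0.75).
#' @param seed integer fixing the MCD subsampling, making the robust fit
#'   deterministic.
#' @return object of class `coda_pca`: `loadings_clr` (D x k),
#'   `loadings_ilr`, `scores` (n x k), `eig`, `explained_variance`,
#'   `center_ilr`, `basis`, `parts`, `robust`.
#' @examples
#' svy <- generate_survey(n_sites = 40, seed = 1)
#' haz <- evaluate_sites(substitute_half_dl(svy$samples))
#' fit <- coda_pca(contribution_matrix(haz), seed = 1)
#' glance(fit)
#' @export
coda_pca <- function(x, robust = TRUE, h = 0.75, seed = 1) {
  m <- comp_input(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("part", seq_len(ncol(m)))
  n <- nrow(m); d <- ncol(m)
  if (n <= d) {
    stop("need more compositions (", n, ") than parts (", d, ")", call. = FALSE)
  }
  psi <- ilr_basis(d, colnames(m))
  z <- ilr(m, psi)
  if (robust) {
    # MCD needs at least p + 1 points in the subset; the 0.75 fraction
    # applies whenever the sample allows it
    q <- min(n, max(ceiling(h * n), ncol(z) + 1L))
    est <- with_local_seed(seed, MASS::cov.rob(z, method = "mcd", quantile.used = q))
    ctr <- est$center
    scatter <- est$cov
  } else {
    ctr <- colMeans(z)
    scatter <- stats::cov(z)
  }
  if (!all(is.finite(scatter))) {
    stop("scatter matrix is not finite", call. = FALSE)
  }
  eg <- eigen(scatter, symmetric = TRUE)
  if (max(eg$values) <= 0) {
    stop("no variation in ilr space; data are degenerate", call. = FALSE)
  }
  eig <- pmax(eg$values, 0)
  v <- eg$vectors
  loadings_clr <- t(psi) %*% v
  # reproducible orientation: largest-magnitude clr entry positive
  for (j in seq_len(ncol(v))) {
    s <- sign(loadings_clr[which.max(abs(loadings_clr[, j])), j])
    if (s < 0) {
      v[, j] <- -v[, j]
      loadings_clr[, j] <- -loadings_clr[, j]
    }
  }
  scores <- sweep(z, 2, ctr) %*% v
  k <- ncol(v)
  pcs <- paste0("PC", seq_len(k))
  dimnames(loadings_clr) <- list(colnames(m), pcs)
  dimnames(scores) <- list(rownames(m), pcs)
  structure(list(
    loadings_clr = loadings_clr,
    loadings_ilr = `dimnames<-`(v, list(rownames(psi), pcs)),
    scores = scores,
    eig = stats::setNames(eig, pcs),
    explained_variance = stats::setNames(eig / sum(eig), pcs),
    center_ilr = ctr,
    basis = psi,
    parts = colnames(m),
    robust = robust
  ), class = "coda_pca")
}

#' @export
print.coda_pca <- function(x, ...) {
  cat(sprintf("Compositional PCA (%s), %d parts, %d scores\n",
              if (x$robust) "robust MCD scatter" else "classical covariance",
              length(x$parts), nrow(x$scores)))
  ev <- round(100 * x$explained_variance[1:min(3, length(x$eig))], 1)
  cat("explained variance:", paste0(names(ev), " ", ev, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Biplot geometry of a compositional PCA
#'
#' In the covariance biplot the rays are the first two clr loading columns
#' scaled by the square roots of their eigenvalues; the squared length of
#' the *link* between the vertices of two rays approximates the variance
#' of the log-ratio of those two parts, so short links flag proportional
#' (redundant) parts.  The form biplot leaves loadings unscaled and
#' scales the scores instead.
#'
#' @param p a [coda_pca()] fit with at least 2 components.
#' @param kind `"covariance"` (default) or `"form"`.
#' @return list with `rays` (tibble: part, pc1, pc2, length), `links`
#'   (tibble: part_i, part_j, link_variance) and standardized `scores`.
#' @export
biplot_elements <- function(p, kind = c("covariance", "form")) {
  kind <- match.arg(kind)
  stopifnot(inherits(p, "coda_pca"))
  if (length(p$eig) < 2) stop("need at least 2 components", call. = FALSE)
  sc <- sqrt(p$eig[1:2])
  if (kind == "covariance") {
    rays2 <- sweep(p$loadings_clr[, 1:2, drop = FALSE], 2, sc, `*`)
    scores2 <- sweep(p$scores[, 1:2, drop = FALSE], 2, sc, `/`)
  } else {
    rays2 <- p$loadings_clr[, 1:2, drop = FALSE]
    scores2 <- p$scores[, 1:2, drop = FALSE]
  }
  rays <- tibble::tibble(part = rownames(rays2),
                         pc1 = rays2[, 1], pc2 = rays2[, 2],
                         length = sqrt(rowSums(rays2^2)))
  cov_rays <- sweep(p$loadings_clr[, 1:2, drop = FALSE], 2, sc, `*`)
  pairs <- utils::combn(rownames(cov_rays), 2)
  links <- tibble::tibble(
    part_i = pairs[1, ], part_j = pairs[2, ],
    link_variance = apply(pairs, 2, function(ij) {
      sum((cov_rays[ij[1], ] - cov_rays[ij[2], ])^2)
    })
  )
  list(rays = rays, links = links, scores = scores2)
}

#' Pick one representative part per compound family
#'
#' For a ternary summary of a high-dimensional composition, picks from
#' each family (e.g. PAH / DDT-and-metabolites / other organochlorines)
#' the part whose 2-D covariance-biplot ray is longest — the most
#' variance-bearing, hence most distinctive, member of the family.
#'
#' @param p a [coda_pca()] fit.
#' @param groups data frame with columns `part` (or `id`) and `group`
#'   covering every part, or a named character vector `part -> group`.
#' @return tibble with one row per group: `group`, `part`, `ray_length`.
#' @export
select_representative <- function(p, groups) {
  stopifnot(inherits(p, "coda_pca"))
  if (!is.data.frame(groups)) {
    groups <- tibble::tibble(part = names(groups), group = unname(groups))
  }
  if ("id" %in% names(groups) && !"part" %in% names(groups)) {
    groups <- dplyr::rename(groups, part = "id")
  }
  missing <- setdiff(p$parts, groups$part)
  if (length(missing)) {
    stop("parts without a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  be <- biplot_elements(p, "covariance")
  be$rays |>
    dplyr::inner_join(groups, by = "part") |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$length, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("group", "part", ray_length = "length")
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical (metric) scaling: double-centres -d^2/2, eigendecomposes,
#' and scales each eigenvector by the square root of its eigenvalue so
#' that Euclidean distances among the full set of coordinates reproduce
#' the input distances (Gower scaling).  Aitchison distance matrices are
#' Euclidean-embeddable, so negative eigenvalues are numerical noise;
#' they are dropped, with a warning when they are not negligible.
#'
#' @param d a `dist` object or symmetric matrix with zero diagonal, e.g.
#'   from [aitchison_dist()].
#' @return object of class `coda_pcoa` with `coordinates` (n x m),
#'   `eigenvalues` (positive, decreasing) and `negative_eigenvalues`.
#' @export
coda_pcoa <- function(d) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8) || any(abs(diag(dm)) > 1e-12)) {
    stop("input must be a symmetric distance matrix with zero diagonal",
         call. = FALSE)
  }
  n <- nrow(dm)
  a <- -dm^2 / 2
  b <- a - rowMeans(a)
  b <- sweep(b, 2, colMeans(b))  # double-centred Gower matrix
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  neg <- eg$values[eg$values < -tol]
  if (length(neg)) {
    warning(sprintf("%d negative eigenvalue(s) dropped (most negative %.3g)",
                    length(neg), min(neg)), call. = FALSE)
  }
  keep <- which(eg$values > tol)
  coords <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep]),
                                                     length(keep))
  dimnames(coords) <- list(rownames(dm), paste0("PCo", seq_along(keep)))
  structure(list(coordinates = coords,
                 eigenvalues = eg$values[keep],
                 negative_eigenvalues = neg),
            class = "coda_pcoa")
}

#' @export
print.coda_pcoa <- function(x, ...) {
  rel <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("PCoA: %d points, %d positive axes; first two axes %.1f%% + %.1f%%\n",
              nrow(x$coordinates), length(x$eigenvalues),
              100 * rel[1], 100 * ifelse(length(rel) > 1, rel[2], 0)))
  invisible(x)
}
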