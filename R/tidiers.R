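#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a compositional PCA
#'
#' One row per part and component with the clr loading; `glance()` gives
#' the one-row fit summary.
#'
#' @param x a [coda_pca()] fit.
#' @param ... unused.
#' @return tibble `part`, `component`, `loading_clr`.
#' @export
tidy.coda_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings_clr, rownames = "part") |>
    tidyr::pivot_longer(-"part", names_to = "component", values_to = "loading_clr")
}

#' @rdname tidy.coda_pca
#' @export
glance.coda_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores), n_parts = length(x$parts), robust = x$robust,
    total_variance = sum(x$eig),
    explained_pc1 = x$explained_variance[[1]],
    explained_pc2 = if (length(x$eig) > 1) x$explained_variance[[2]] else NA_real_
  )
}

#' Tidy a principal coordinate analysis
#'
#' @param x a [coda_pcoa()] fit.
#' @param ... unused.
#' @return tibble with `site_id` (when available) and one row per point
#'   and axis.
#' @export
tidy.coda_pcoa <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "site_id") |>
    tidyr::pivot_longer(-"site_id", names_to = "axis", values_to = "coordinate")
}

#' @rdname tidy.coda_pcoa
#' @export
glance.coda_pcoa <- function(x, ...) {
  rel <- x$eigenvalues / sum(x$eigenvalues)
  tibble::tibble(n = nrow(x$coordinates), n_axes = length(x$eigenvalues),
                 n_negative_dropped = length(x$negative_eigenvalues),
                 relative_eig1 = rel[1],
                 relative_eig2 = if (length(rel) > 1) rel[2] else NA_real_)
}

#' Tidy a fuzzy c-means fit
#'
#' @param x a [coda_fcm()] fit.
#' @param ... unused.
#' @return long tibble `site_id`, `cluster`, `membership`, `hard_label`.
#' @export
tidy.coda_fcm <- function(x, ...) {
  u <- x$membership
  if (is.null(rownames(u))) rownames(u) <- as.character(seq_len(nrow(u)))
  tibble::as_tibble(u, rownames = "site_id") |>
    dplyr::mutate(hard_label = unname(x$hard_labels)) |>
    tidyr::pivot_longer(dplyr::starts_with("cluster"), names_to = "cluster",
                        values_to = "membership")
}

#' @rdname tidy.coda_fcm
#' @export
glance.coda_fcm <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$membership), n_clusters = ncol(x$membership), m = x$m,
    iterations = x$iterations, converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)],
    partition_coefficient = sum(x$membership^2) / nrow(x$membership)
  )
}
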