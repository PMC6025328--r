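#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means on a coordinate matrix — for compositional
#' profiles, on their ilr coordinates, where Euclidean distance equals
#' Aitchison distance and the clr-singularity problem does not arise.
#' Prototypes are seeded k-means++-style from `seed`, then membership and
#' prototype updates alternate:
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`,
#' `prototype_k = sum_i u_ik^m z_i / sum_i u_ik^m`,
#' until the largest prototype shift falls below `tol`.  A point landing
#' exactly on a prototype gets an indicator membership (the usual
#' singularity rule).  Clusters are relabelled by decreasing membership
#' mass for reproducible reporting.
#'
#' @param z numeric matrix (rows = observations) or wide tibble with a
#'   `site_id` column; typically `ilr()` of a contribution matrix.
#' @param centers number of clusters c (2 <= c < n).
#' @param m fuzzifier (> 1; 2 is the usual default — larger values give
#'   flatter memberships).
#' @param tol convergence tolerance on prototype movement.
#' @param max_iter iteration cap.
#' @param seed integer; the run is deterministic given the seed.
#' @return object of class `coda_fcm`: `membership` (n x c, rows sum to
#'   1), `prototypes` (c x p), `objective_trace` (non-increasing),
#'   `hard_labels`, `m`, `iterations`, `converged`.
#' @examples
#' z <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 6), 20))
#' coda_fcm(z, centers = 2, seed = 1)
#' @export
coda_fcm <- function(z, centers, m = 2, tol = 1e-6, max_iter = 300, seed = 1) {
  z <- as_comp_matrix(z)
  n <- nrow(z)
  c <- as.integer(centers)
  if (c < 2 || c >= n) stop("need 2 <= centers < n", call. = FALSE)
  if (m <= 1) stop("fuzzifier `m` must exceed 1", call. = FALSE)
  proto <- with_local_seed(seed, kmeanspp_init(z, c))
  trace <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to(z, proto)
    u <- fcm_membership(d2, m)
    trace <- c(trace, sum(u^m * d2))
    um <- u^m
    new_proto <- (t(um) %*% z) / colSums(um)
    shift <- sqrt(max(rowSums((new_proto - proto)^2)))
    proto <- new_proto
    if (shift < tol) { converged <- TRUE; break }
  }
  # final memberships for the final prototypes
  d2 <- dist2_to(z, proto)
  u <- fcm_membership(d2, m)
  ord <- order(colSums(u), decreasing = TRUE)
  u <- u[, ord, drop = FALSE]
  proto <- proto[ord, , drop = FALSE]
  dimnames(u) <- list(rownames(z), paste0("cluster", seq_len(c)))
  dimnames(proto) <- list(paste0("cluster", seq_len(c)), colnames(z))
  structure(list(
    membership = u,
    prototypes = proto,
    objective_trace = trace,
    hard_labels = stats::setNames(max.col(u, ties.method = "first"), rownames(z)),
    m = m, iterations = length(trace), converged = converged
  ), class = "coda_fcm")
}

# squared Euclidean distances of each row of z to each prototype row
dist2_to <- function(z, proto) {
  d2 <- outer(rowSums(z^2), rep(1, nrow(proto))) - 2 * z %*% t(proto) +
    outer(rep(1, nrow(z)), rowSums(proto^2))
  pmax(d2, 0)
}

fcm_membership <- function(d2, m) {
  w <- d2^(-1 / (m - 1))
  u <- w / rowSums(w)
  zero <- which(d2 < .Machine$double.eps^2, arr.ind = TRUE)
  if (nrow(zero)) {
    for (i in unique(zero[, 1])) {
      hit <- d2[i, ] < .Machine$double.eps^2
      u[i, ] <- hit / sum(hit)
    }
  }
  u
}

kmeanspp_init <- function(z, c) {
  n <- nrow(z)
  idx <- sample.int(n, 1)
  for (j in seq_len(c - 1)) {
    d2 <- apply(dist2_to(z, z[idx, , drop = FALSE]), 1, min)
    d2[idx] <- 0
    idx <- c(idx, if (sum(d2) > 0) sample.int(n, 1, prob = d2) else
      sample(setdiff(seq_len(n), idx), 1))
  }
  z[idx, , drop = FALSE]
}

#' @export
print.coda_fcm <- function(x, ...) {
  cat(sprintf("Fuzzy c-means: %d clusters, m = %g, %d iterations (%sconverged)\n",
              ncol(x$membership), x$m, x$iterations,
              if (x$converged) "" else "not "))
  print(table(cluster = x$hard_labels))
  invisible(x)
}

#' Score candidate cluster counts
#'
#' Fits fuzzy c-means for each candidate c and reports two internal
#' criteria: the fuzzy partition coefficient `sum(U^2)/n` (larger =
#' crisper partition) and the average silhouette width of the hard
#' labels.  Both are returned with per-criterion best flags; when the
#' criteria disagree the choice is left to the analyst.
#'
#' @inheritParams coda_fcm
#' @param c_range integer vector of candidate cluster counts.
#' @return tibble: `c`, `partition_coefficient`, `avg_silhouette`,
#'   `best_pc`, `best_silhouette`.
#' @export
choose_cluster_count <- function(z, c_range = 2:5, m = 2, tol = 1e-6,
                                 max_iter = 300, seed = 1) {
  z <- as_comp_matrix(z)
  if (any(c_range < 2 | c_range >= nrow(z))) {
    stop("candidate cluster counts must lie in [2, n)", call. = FALSE)
  }
  dz <- stats::dist(z)
  rows <- purrr::map(c_range, function(cc) {
    fit <- coda_fcm(z, cc, m = m, tol = tol, max_iter = max_iter, seed = seed)
    sil <- if (length(unique(fit$hard_labels)) > 1) {
      mean(cluster::silhouette(fit$hard_labels, dz)[, "sil_width"])
    } else NA_real_
    tibble::tibble(c = cc,
                   partition_coefficient = sum(fit$membership^2) / nrow(z),
                   avg_silhouette = sil)
  })
  out <- dplyr::bind_rows(rows)
  out$best_pc <- out$partition_coefficient == max(out$partition_coefficient)
  out$best_silhouette <- !is.na(out$avg_silhouette) &
    out$avg_silhouette == max(out$avg_silhouette, na.rm = TRUE)
  out
}

#' Compositional cluster profiles
#'
#' Characterizes each cluster by the closed (membership-weighted)
#' geometric mean of its members' *centered* compositions.  On centered
#' data the overall mean profile is neutral (1/D per part), so parts with
#' weight above 1/D are enriched in that cluster relative to the survey
#' as a whole.
#'
#' @param x_centered centered compositions (matrix or wide tibble), e.g.
#'   `center_composition(...)$centered`.
#' @param membership n x c membership matrix, a [coda_fcm()] fit, or a
#'   vector of hard labels.
#' @param hard use hard (argmax) labels instead of membership weights?
#' @return tibble: `cluster`, `part`, `weight`, `enriched`.
#' @export
cluster_profiles <- function(x_centered, membership, hard = FALSE) {
  m <- comp_input(x_centered)
  if (inherits(membership, "coda_fcm")) {
    u <- membership$membership
  } else if (is.matrix(membership)) {
    u <- membership
  } else {
    labs <- as.integer(factor(membership))
    u <- diag(max(labs))[labs, , drop = FALSE]
    colnames(u) <- paste0("cluster", seq_len(ncol(u)))
  }
  if (nrow(u) != nrow(m)) stop("membership rows must match compositions", call. = FALSE)
  if (hard) {
    lab <- max.col(u, ties.method = "first")
    u <- diag(ncol(u))[lab, , drop = FALSE]
    colnames(u) <- paste0("cluster", seq_len(ncol(u)))
  }
  d <- ncol(m)
  profs <- purrr::map(seq_len(ncol(u)), function(k) {
    w <- u[, k]
    if (sum(w) <= 0) stop("cluster ", k, " is empty", call. = FALSE)
    prof <- closure(exp(colSums(w * log(m)) / sum(w)))
    tibble::tibble(cluster = k, part = colnames(m),
                   weight = unname(prof),
                   enriched = unname(prof) > 1 / d + 1e-9)
  })
  dplyr::bind_rows(profs)
}
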