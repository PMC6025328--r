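test_that("rank-1 compositional data put all variance on the first PC", {
  t_vals <- seq(-2, 2, length.out = 12)
  dir <- c(1, -0.5, 0.25, -0.75)  # line in ilr space
  Z <- outer(t_vals, dir)
  X <- ilr_inv(Z)
  fit <- coda_pca(X, robust = FALSE)
  expect_equal(fit$explained_variance[[1]], 1, tolerance = 1e-8)
})

test_that("classical path reproduces the direct eigendecomposition oracle", {
  X <- random_compositions(30, 5, seed = 21)
  fit <- coda_pca(X, robust = FALSE)
  z <- ilr(X)
  oracle <- eigen(stats::cov(z), symmetric = TRUE)
  expect_equal(unname(fit$eig), oracle$values, tolerance = 1e-10)
  # scores reproduce centred data in the eigenbasis
  recon <- fit$scores %*% t(fit$loadings_ilr)
  expect_equal(recon, sweep(z, 2, colMeans(z)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(fit$eig), sum(apply(z, 2, stats::var)), tolerance = 1e-10)
  # clr loadings live in the zero-sum plane
  expect_lt(max(abs(colSums(fit$loadings_clr))), 1e-10)
})

test_that("clr-space results do not depend on the ilr basis", {
  X <- random_compositions(40, 6, seed = 22)
  d <- ncol(X)
  fit <- coda_pca(X, robust = FALSE)
  # manual fit in a rotated orthonormal basis
  rot <- qr.Q(qr(matrix(withr::with_seed(99, stats::rnorm((d - 1)^2)), d - 1)))
  psi2 <- rot %*% ilr_basis(d)
  z2 <- clr(X) %*% t(psi2)
  eg <- eigen(stats::cov(z2), symmetric = TRUE)
  loadings2 <- t(psi2) %*% eg$vectors
  expect_equal(unname(fit$eig), eg$values, tolerance = 1e-8)
  for (j in 1:2) {
    a <- fit$loadings_clr[, j]; b <- loadings2[, j]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)  # same axis up to sign
  }
})

test_that("scores are invariant under a common perturbation", {
  X <- random_compositions(25, 5, seed = 23)
  p <- drop(random_compositions(1, 5, seed = 24))
  f1 <- coda_pca(X, robust = FALSE)
  f2 <- coda_pca(perturb(X, p), robust = FALSE)
  expect_equal(abs(f1$scores), abs(f2$scores), tolerance = 1e-8)
})

test_that("robust PCA shrugs off 20% extreme outliers; classical does not", {
  svy <- generate_survey(n_sites = 100, seed = 25, censor = FALSE)
  haz <- evaluate_sites(svy$samples, basis = "noncarcinogenic")
  pm <- contribution_matrix(haz)
  X <- closure(as.matrix(pm[, -1]))
  Xc <- X
  n_out <- 20
  d <- ncol(X)
  out_rows <- withr::with_seed(26, sample(nrow(X), n_out))
  # scattered extreme profiles: each outlier spikes its own random part
  Xc[out_rows, ] <- withr::with_seed(27, {
    t(vapply(seq_len(n_out), function(i) {
      lg <- stats::rnorm(d, sd = 2)
      lg[sample.int(d, 1)] <- lg[sample.int(d, 1)] + 15
      closure(exp(lg))
    }, numeric(d)))
  })

  rob1 <- coda_pca(X, robust = TRUE, seed = 1)$explained_variance[1:2]
  rob2 <- coda_pca(Xc, robust = TRUE, seed = 1)$explained_variance[1:2]
  cls1 <- coda_pca(X, robust = FALSE)$explained_variance[1:2]
  cls2 <- coda_pca(Xc, robust = FALSE)$explained_variance[1:2]
  rob_change <- max(abs(rob1 - rob2) / rob1)
  cls_change <- max(abs(cls1 - cls2) / cls1)
  expect_lt(rob_change, 0.10)
  expect_gt(cls_change, rob_change)
})

test_that("biplot links estimate log-ratio variances", {
  # rank-2 data: 2D projection is exact, links equal variation entries
  Z <- cbind(withr::with_seed(27, stats::rnorm(40)),
             withr::with_seed(28, stats::rnorm(40, sd = 0.5)),
             0, 0)
  X <- ilr_inv(Z)
  colnames(X) <- paste0("p", seq_len(ncol(X)))
  fit <- coda_pca(X, robust = FALSE)
  be <- biplot_elements(fit, "covariance")
  tv <- variation_matrix(closure(X))
  # links are scaled by sqrt(eig) of a cov estimated with n-1: same estimator
  for (k in seq_len(nrow(be$links))) {
    i <- be$links$part_i[k]; j <- be$links$part_j[k]
    expect_equal(be$links$link_variance[k], tv[i, j], tolerance = 1e-8)
  }
  # rays of clr loadings sum to zero
  expect_equal(colSums(be$rays[, c("pc1", "pc2")]), c(pc1 = 0, pc2 = 0),
               tolerance = 1e-10)
  # proportional parts give a near-zero link
  Xp <- cbind(X[, 1], X[, 1] * 2, X[, 2], X[, 3])
  colnames(Xp) <- paste0("q", 1:4)
  bp <- biplot_elements(coda_pca(closure(Xp), robust = FALSE), "covariance")
  expect_lt(bp$links$link_variance[bp$links$part_i == "q1" &
                                     bp$links$part_j == "q2"], 1e-12)
})

test_that("the dominant-variance part of each family is selected", {
  groups <- tibble::tibble(part = paste0("p", 1:6),
                           group = rep(c("g1", "g2", "g3"), each = 2))
  hits <- 0
  for (seed in 1:10) {
    # parts 1, 3, 5 carry 10x the log-ratio variance of their family peers
    Z <- withr::with_seed(seed, matrix(stats::rnorm(60 * 5), 60, 5))
    lg <- cbind(3 * Z[, 1], 0.3 * Z[, 2], 3 * Z[, 3], 0.3 * Z[, 4],
                3 * Z[, 5], 0.3 * Z[, 1] + 0.3 * Z[, 2])
    X <- closure(exp(lg))
    colnames(X) <- groups$part
    sel <- select_representative(coda_pca(X, robust = FALSE), groups)
    hits <- hits + identical(sort(sel$part), c("p1", "p3", "p5"))
    expect_equal(nrow(sel), 3)
  }
  expect_equal(hits, 10)
  single <- tibble::tibble(part = paste0("p", 1:6),
                           group = paste0("g", 1:6))
  X <- random_compositions(20, 6, seed = 30)
  expect_equal(sort(select_representative(coda_pca(X, robust = FALSE),
                                          single)$part),
               paste0("p", 1:6))
})

test_that("PCoA with Gower scaling reconstructs Aitchison distances", {
  X <- random_compositions(15, 6, seed = 31)
  d <- aitchison_dist(X)
  fit <- coda_pcoa(d)
  expect_equal(as.matrix(stats::dist(fit$coordinates)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(order(fit$eigenvalues, decreasing = TRUE),
               seq_along(fit$eigenvalues))
  # column norms equal sqrt(eigenvalue)
  expect_equal(colSums(fit$coordinates^2), fit$eigenvalues,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(coda_pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("identical profiles land on identical coordinates", {
  X <- random_compositions(8, 4, seed = 32)
  X[2, ] <- X[1, ]
  fit <- coda_pcoa(aitchison_dist(X))
  expect_equal(fit$coordinates[1, ], fit$coordinates[2, ], tolerance = 1e-8)
})

test_that("PCoA coordinates agree with classical PCA scores on ilr data", {
  X <- random_compositions(20, 5, seed = 33)
  pcoa <- coda_pcoa(aitchison_dist(X))
  pca <- coda_pca(X, robust = FALSE)
  k <- min(ncol(pcoa$coordinates), ncol(pca$scores))
  # same Euclidean configuration: compare pairwise distances axis-complete
  expect_equal(as.matrix(stats::dist(pcoa$coordinates)),
               as.matrix(stats::dist(pca$scores)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # and per-axis up to sign
  for (j in 1:2) {
    expect_equal(abs(pcoa$coordinates[, j]), abs(pca$scores[, j]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # cross-check double-centering against cmdscale
  cmd <- stats::cmdscale(aitchison_dist(X), k = k, eig = TRUE)
  expect_equal(abs(pcoa$coordinates[, 1:k]), abs(cmd$points), tolerance = 1e-8,
               ignore_attr = TRUE)
})
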