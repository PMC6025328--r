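test_that("closure rescales, is idempotent, and rejects nonpositive parts", {
  expect_equal(closure(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(closure(closure(c(3, 9, 1))), closure(c(3, 9, 1)))
  expect_equal(sum(closure(stats::runif(7), kappa = 100)), 100)
  expect_error(closure(c(1, 0, 2)), "positive")
  # a BaP-dominated 3-part risk subcomposition collapses near one vertex
  p <- closure(c(BaP = 0.152897, gHCH = 0.000164, ppDDT = 0.000493))
  expect_equal(unname(p), c(0.99572, 0.00107, 0.00321), tolerance = 1e-3)
})

test_that("perturbation and powering satisfy the group axioms", {
  neutral <- rep(1 / 4, 4)
  for (seed in 1:5) {
    x <- drop(random_compositions(1, 4, seed))
    y <- drop(random_compositions(1, 4, seed + 50))
    expect_equal(perturb(x, neutral), closure(x), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(perturb(x, closure(1 / x)), neutral, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(comp_power(x, 0), neutral, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(perturb(x, y), perturb(y, x), tolerance = 1e-12)
    expect_equal(comp_power(x, 2), perturb(x, x), tolerance = 1e-12)
  }
})

test_that("clr matches its log-ratio definition and inverts", {
  expect_equal(clr(rep(1 / 3, 3)), rep(0, 3))
  expect_equal(unname(clr(c(0.25, 0.25, 0.5))),
               c(-0.2310, -0.2310, 0.4621), tolerance = 1e-3)
  X <- random_compositions(20, 6, seed = 2)
  expect_true(max(abs(rowSums(clr(X)))) < 1e-12)
  expect_true(max(abs(clr_inv(clr(X)) - X)) < 1e-12)
})

test_that("the ilr basis is an orthonormal zero-sum contrast matrix", {
  for (d in c(2, 3, 7, 31)) {
    psi <- ilr_basis(d)
    expect_equal(psi %*% t(psi), diag(d - 1), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(rowSums(psi), rep(0, d - 1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(ilr_basis(1), "at least 2")
})

test_that("ilr agrees with psi %*% clr, inverts, and matches the 3-part oracle", {
  expect_equal(unname(ilr(c(0.5, 0.5))), 0)
  # coordinate oracle: z1 = sqrt(1/2) ln(x1/x2), z2 = sqrt(2/3) ln(g(x1,x2)/x3)
  x <- c(0.25, 0.25, 0.5)
  expect_equal(unname(ilr(x)),
               c(sqrt(1 / 2) * log(1), sqrt(2 / 3) * log(0.25 / 0.5)),
               tolerance = 1e-12)
  expect_equal(unname(ilr(x)), c(0, -0.5661), tolerance = 1e-3)
  X <- random_compositions(15, 5, seed = 3)
  psi <- ilr_basis(5)
  expect_equal(ilr(X), clr(X) %*% t(psi), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(max(abs(ilr_inv(ilr(X)) - X)) < 1e-12)
})

test_that("ilr, clr and Aitchison distance define the same geometry", {
  X <- random_compositions(10, 8, seed = 4)
  for (i in 1:4) {
    x <- X[2 * i - 1, ]; y <- X[2 * i, ]
    d <- aitchison_dist(x, y)
    expect_equal(sqrt(sum((ilr(x) - ilr(y))^2)), d, tolerance = 1e-10)
    expect_equal(sqrt(sum((clr(x) - clr(y))^2)), d, tolerance = 1e-10)
    # invariances: scaling, perturbation
    expect_equal(aitchison_dist(2 * x, y), d, tolerance = 1e-10)
    p <- X[max(1, i - 1) + 4, ]
    expect_equal(aitchison_dist(perturb(x, p), perturb(y, p)), d,
                 tolerance = 1e-10)
  }
  expect_equal(aitchison_dist(X[1, ], X[1, ]), 0)
})

test_that("variation matrix matches the variance oracle and its symmetries", {
  # two parts with log-ratio values {0, 2}: unbiased variance (n = 2) is 2
  X2 <- rbind(c(1, 1), c(exp(2), 1))
  expect_equal(variation_matrix(X2)[1, 2], 2, tolerance = 1e-12)

  X <- random_compositions(25, 5, seed = 6)
  tv <- variation_matrix(X)
  expect_equal(tv, t(tv))
  expect_equal(diag(tv), rep(0, 5), ignore_attr = TRUE)
  expect_equal(tv[2, 4], stats::var(log(X[, 2] / X[, 4])), tolerance = 1e-12)

  # perfectly proportional parts have zero log-ratio variance
  Xp <- cbind(X[, 1], 3 * X[, 1], X[, 2:3])
  expect_lt(variation_matrix(Xp)[1, 2], 1e-25)
  expect_error(variation_matrix(X[1, , drop = FALSE]), "at least 2")
})

test_that("total ilr variance equals the variation-matrix total", {
  for (seed in c(8, 9)) {
    X <- random_compositions(40, 6, seed = seed)
    z <- ilr(X)
    total_ilr <- sum(apply(z, 2, stats::var))
    tv <- variation_matrix(X)
    expect_equal(total_ilr, sum(tv) / (2 * ncol(X)), tolerance = 1e-8)
  }
})

test_that("centering moves the geometric mean to the barycentre", {
  X <- random_compositions(12, 4, seed = 10)
  cen <- center_composition(X)
  gm <- closure(exp(colMeans(log(cen$centered))))
  expect_equal(unname(gm), rep(1 / 4, 4), tolerance = 1e-10)
  # idempotence and distance preservation
  again <- center_composition(cen$centered)
  expect_equal(again$centered, cen$centered, tolerance = 1e-10)
  expect_equal(as.matrix(aitchison_dist(cen$centered)),
               as.matrix(aitchison_dist(X)), tolerance = 1e-10,
               ignore_attr = TRUE)
  one <- center_composition(X[1, , drop = FALSE])
  expect_equal(drop(one$centered), rep(1 / 4, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("subcompositions re-close and never increase distances", {
  X <- random_compositions(10, 6, seed = 12)
  expect_equal(subcomposition(X, colnames(X)), closure(X))
  sub <- subcomposition(X, c("p1", "p3", "p5"))
  expect_equal(rowSums(sub), rep(1, 10))
  for (i in 1:4) {
    expect_lte(aitchison_dist(sub[i, ], sub[i + 1, ]),
               aitchison_dist(X[i, ], X[i + 1, ]) + 1e-12)
  }
  expect_error(subcomposition(X, c("p1", "nope")), "unknown")
  expect_error(subcomposition(X, "p1"), "at least 2")
})

test_that("ternary coordinates place vertices and barycentre correctly", {
  expect_equal(unlist(ternary_coords(rep(1 / 3, 3))),
               c(u = 0.5, v = sqrt(3) / 6), tolerance = 1e-12)
  eps <- 1e-9
  verts <- rbind(c(1, eps, eps), c(eps, 1, eps), c(eps, eps, 1))
  uv <- ternary_coords(verts)
  expect_equal(uv$u, c(0, 1, 0.5), tolerance = 1e-6)
  expect_equal(uv$v, c(0, 0, sqrt(3) / 2), tolerance = 1e-6)
  expect_error(ternary_coords(c(0.5, 0.5)), "3 parts")
})
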