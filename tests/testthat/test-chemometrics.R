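make_set <- function(X, w = NULL) {
  if (is.null(w)) w <- seq(1000, by = 10, length.out = ncol(X))
  raman_set(w, X,
            data.frame(producer_id = paste0("P", seq_len(nrow(X))),
                       pellet_id = "1", spot_id = "1",
                       instrument = "lab"))
}

test_that("uncentered PCA of a repeated spectrum is rank one", {
  v <- c(1, 3, 2, 5, 4, 1, 0, 2)
  X <- matrix(rep(v, 5), nrow = 5, byrow = TRUE)
  p <- fit_uncentered_pca(make_set(X))
  expect_equal(p$variance_fraction[1], 1)
  expect_equal(p$variance_fraction[-1], rep(0, 4), tolerance = 1e-12)
  expect_equal(abs(p$loadings[1, ]), v / sqrt(sum(v^2)),
               tolerance = 1e-10)
})

test_that("uncentered PCA of a diagonal matrix gives known singular values", {
  X <- matrix(c(3, 0, 0, 4), 2, 2, byrow = TRUE)
  p <- fit_uncentered_pca(make_set(X, w = c(1000, 1010)))
  expect_equal(p$singular_values, c(4, 3))
  expect_equal(p$variance_fraction, c(16, 9) / 25)
})

test_that("PCA reconstructs the data and matches the Gram-matrix oracle", {
  set.seed(31)
  X <- matrix(rexp(12 * 20), 12, 20)
  set <- make_set(X)
  p <- fit_uncentered_pca(set, n_components = 12)
  expect_equal(p$scores %*% p$loadings, X, tolerance = 1e-8,
               ignore_attr = TRUE)
  # oracle: eigenvalues of the uncentered Gram matrix X'X
  ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(p$singular_values[1:12]^2, ev[1:12], tolerance = 1e-8)
  expect_equal(sum(p$variance_fraction), 1)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  # loadings orthonormal
  G <- p$loadings %*% t(p$loadings)
  expect_equal(G, diag(12), tolerance = 1e-8, ignore_attr = TRUE)
  # independent cross-check: prcomp without centering
  pr <- prcomp(X, center = FALSE, scale. = FALSE)
  expect_equal(p$singular_values^2,
               (pr$sdev^2) * (nrow(X) - 1), tolerance = 1e-8)
})

test_that("PCA scores are equivariant under global intensity scaling", {
  set.seed(32)
  X <- matrix(rexp(10 * 15), 10, 15)
  p1 <- fit_uncentered_pca(make_set(X), n_components = 5)
  p2 <- fit_uncentered_pca(make_set(3 * X), n_components = 5)
  expect_equal(p2$scores, 3 * p1$scores, tolerance = 1e-9)
  expect_equal(p2$variance_fraction, p1$variance_fraction,
               tolerance = 1e-12)
  # sign convention: largest-magnitude loading element is positive
  for (j in 1:5)
    expect_gt(p1$loadings[j, which.max(abs(p1$loadings[j, ]))], 0)
})

test_that("PCA range handling intersects with coverage and errors sensibly", {
  set.seed(33)
  X <- matrix(runif(6 * 50), 6, 50)
  set <- make_set(X, w = seq(800, 1780, by = 20))
  expect_warning(p <- fit_uncentered_pca(set, range = c(100, 1700)),
                 "intersection")
  expect_true(all(p$wavenumber >= 800 & p$wavenumber <= 1700))
  expect_error(fit_uncentered_pca(set[1]), "at least 2")
  z <- make_set(matrix(0, 3, 5), w = seq(1000, 1040, 10))
  expect_error(fit_uncentered_pca(z), "degenerate")
})

test_that("Mahalanobis ellipses recover covariance geometry", {
  g <- as.matrix(expand.grid(x = -3:3, y = -3:3))
  cloud <- cbind(2 * g[, 1], g[, 2])  # var ratio 4:1, cov 0
  e <- mahalanobis_ellipse(cloud)
  expect_equal(e$center, c(0, 0), ignore_attr = TRUE)
  expect_equal(e$semi_axes[1] / e$semi_axes[2], 2, tolerance = 1e-10)
  expect_equal(e$angle, 0, tolerance = 1e-10)

  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  er <- mahalanobis_ellipse(cloud %*% t(R))
  expect_equal(er$angle, th, tolerance = 1e-6)
  expect_equal(er$semi_axes, e$semi_axes, tolerance = 1e-10)

  # isotropic cloud -> circle of radius ~ 1
  set.seed(34)
  iso <- matrix(rnorm(4000), 2000, 2)
  ei <- mahalanobis_ellipse(iso)
  expect_equal(ei$semi_axes, c(1, 1), tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("every point on the ellipse boundary has Mahalanobis distance 1", {
  set.seed(35)
  pts <- matrix(rnorm(200), 100, 2) %*%
    matrix(c(2, 0.7, 0, 1), 2, 2) + 5
  e <- mahalanobis_ellipse(pts)
  d <- mahalanobis_distance(e, ellipse_points(e, 360))
  expect_equal(d, rep(1, 360), tolerance = 1e-8)

  expect_error(mahalanobis_ellipse(pts[1:2, ]), "at least 3")
  degen <- cbind(1:5, 2 * (1:5))
  expect_error(mahalanobis_ellipse(degen), "singular|degenerate")
})

test_that("LDA recovers a mean gap along one coordinate", {
  set.seed(36)
  n <- 200
  X <- rbind(matrix(rnorm(n * 10), n, 10),
             matrix(rnorm(n * 10), n, 10))
  X[1:n, 1] <- X[1:n, 1] + 4
  lab <- rep(c("a", "b"), each = n)
  fit <- fit_lda(X, lab)
  expect_equal(ncol(fit$projection), 1L)  # 2 classes -> 1 coordinate
  cosine <- abs(fit$projection[1, 1]) / sqrt(sum(fit$projection[, 1]^2))
  expect_gt(cosine, 0.99)

  # independent cross-check: MASS discriminant direction is collinear
  m <- MASS::lda(X, grouping = lab)
  cs <- abs(sum(fit$projection[, 1] * m$scaling[, 1])) /
    sqrt(sum(fit$projection[, 1]^2) * sum(m$scaling[, 1]^2))
  expect_gt(cs, 0.999)

  # shuffling labels collapses the between-class eigenvalue
  set.seed(37)
  fit_perm <- fit_lda(X, sample(lab))
  expect_lt(fit_perm$eigenvalues[1], 0.05 * fit$eigenvalues[1])
})

test_that("LDA dimensionality is bounded by classes minus one", {
  set.seed(38)
  X <- matrix(rnorm(160 * 10), 160, 10)
  lab <- rep(paste0("P", 1:8), each = 20)
  fit <- fit_lda(X, lab)
  expect_lte(ncol(fit$projection), 7L)
  expect_equal(nrow(fit$class_means), 8L)
  expect_error(fit_lda(X, rep("x", 160)), "2 classes")
  expect_error(fit_lda(X[1:3, ], c("a", "a", "b")), "at least 2")
})

test_that("nearest-mean classification is accurate and deterministic", {
  set.seed(39)
  n <- 100
  X <- rbind(matrix(rnorm(n * 10), n, 10),
             matrix(rnorm(n * 10), n, 10))
  X[1:n, 2] <- X[1:n, 2] + 5
  lab <- rep(c("hi", "lo"), each = n)
  fit <- fit_lda(X, lab)
  expect_gte(mean(classify_groups(fit, X) == lab), 0.95)
  expect_identical(classify_groups(fit, X[0, , drop = FALSE]),
                   character(0))
  expect_error(classify_groups(fit, X[, 1:3]), "columns")

  # exact tie between two class means breaks to the lowest label
  # (x is constant within each class, so W is singular -> regularized)
  Xt <- rbind(c(-1, 0), c(-1, 1), c(-1, -1),
              c(1, 0), c(1, 1), c(1, -1))
  expect_warning(fit2 <- fit_lda(Xt, c("a", "a", "a", "b", "b", "b")),
                 "singular")
  mid <- matrix(c(0, 0), 1, 2)
  expect_equal(classify_groups(fit2, mid), "a")
})
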