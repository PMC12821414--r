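#' Uncentered principal component analysis of a spectrum ensemble
#'
#' Singular value decomposition of the raw spectra matrix restricted to
#' the analysis range, with neither column centering nor scaling
#' (uncentered PCA). The first component therefore captures the shared
#' spectral shape of the ensemble; later components capture
#' between-spectrum variation. Variance fractions are singular values
#' squared over their total, i.e. fractions of the total uncentered sum
#' of squares. The sign of each loading is pinned by making its
#' largest-magnitude element positive.
#'
#' If the requested range extends beyond the recorded axis it is
#' intersected with the available coverage, with a warning.
#'
#' @param set A preprocessed [raman_set()] with at least 2 spectra.
#' @param range Analysis interval `c(lo, hi)` in cm^-1, or `NULL` for
#'   the full axis.
#' @param n_components Number of components to retain (default 10,
#'   capped at the matrix rank bound).
#' @return An object of class `ucpca` with elements `loadings`
#'   (components-by-wavenumber, rows orthonormal), `scores`
#'   (spectra-by-components), `variance_fraction` (over all components,
#'   not just those retained), `singular_values`, `wavenumber`,
#'   `manifest`.
#' @export
fit_uncentered_pca <- function(set, range = NULL, n_components = 10L) {
  stopifnot(inherits(set, "raman_set"))
  if (nrow(set$intensity) < 2L)
    stop("uncentered PCA needs at least 2 spectra")
  w <- set$wavenumber
  if (!is.null(range)) {
    if (length(range) != 2L || range[1] >= range[2])
      stop("`range` must be c(lo, hi) with lo < hi")
    if (range[1] < w[1] || range[2] > w[length(w)]) {
      warning("analysis range [", range[1], ", ", range[2],
              "] cm-1 exceeds the recorded coverage [", w[1], ", ",
              w[length(w)], "]; using the intersection")
      range <- c(max(range[1], w[1]), min(range[2], w[length(w)]))
    }
    keep <- w >= range[1] & w <= range[2]
    if (sum(keep) < 2L) stop("analysis range leaves fewer than 2 points")
  } else keep <- rep(TRUE, length(w))
  X <- set$intensity[, keep, drop = FALSE]
  if (all(X == 0)) stop("degenerate input: all-zero spectra matrix")
  sv <- svd(X)
  total <- sum(sv$d^2)
  k <- min(as.integer(n_components), length(sv$d))
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])
  scores <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = nrow(X))
  for (j in seq_len(k)) {
    if (loadings[j, which.max(abs(loadings[j, ]))] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- rownames(loadings) <- paste0("PC", seq_len(k))
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = sv$d^2 / total,
                 singular_values = sv$d,
                 wavenumber = w[keep], manifest = set$manifest),
            class = "ucpca")
}

#' @export
print.ucpca <- function(x, ...) {
  k <- nrow(x$loadings)
  cat("Uncentered PCA:", nrow(x$scores), "spectra,",
      length(x$wavenumber), "wavenumbers,", k, "components retained\n")
  vf <- x$variance_fraction[seq_len(min(3L, k))]
  cat("  variance fractions:",
      paste(sprintf("PC%d %.2f%%", seq_along(vf), 100 * vf),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ucpca <- function(object, ...) {
  k <- nrow(object$loadings)
  data.frame(component = paste0("PC", seq_len(k)),
             singular_value = object$singular_values[seq_len(k)],
             variance_fraction = object$variance_fraction[seq_len(k)],
             cumulative = cumsum(object$variance_fraction)[seq_len(k)])
}

#' Project spectra onto fitted uncentered components
#'
#' @param object A fitted `ucpca`.
#' @param newdata A [raman_set()] on an axis covering the model's, or a
#'   numeric matrix over exactly the model's wavenumbers.
#' @param ... Unused.
#' @return Score matrix (spectra by components).
#' @export
predict.ucpca <- function(object, newdata, ...) {
  if (inherits(newdata, "raman_set")) {
    idx <- match(object$wavenumber, newdata$wavenumber)
    if (anyNA(idx))
      stop("newdata does not contain the model's wavenumber axis")
    X <- newdata$intensity[, idx, drop = FALSE]
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object$wavenumber))
      stop("newdata has ", ncol(X), " columns; model expects ",
           length(object$wavenumber))
  }
  S <- X %*% t(object$loadings)
  colnames(S) <- rownames(object$loadings)
  S
}

#' @export
plot.ucpca <- function(x, which = c("scores", "loadings"),
                       components = c(1L, 2L), group = NULL,
                       ellipses = TRUE, ...) {
  which <- match.arg(which)
  if (which == "loadings") {
    graphics::matplot(x$wavenumber, t(x$loadings[components, ,
                                                 drop = FALSE]),
                      type = "l", lty = 1,
                      xlab = expression(paste("Raman shift (", cm^-1,
                                              ")")),
                      ylab = "Loading", ...)
    graphics::legend("topleft", legend = paste0("PC", components),
                     lty = 1, col = seq_along(components), bty = "n")
    return(invisible(x))
  }
  s <- x$scores[, components, drop = FALSE]
  if (is.null(group)) group <- x$manifest$producer_id
  group <- as.factor(group)
  cols <- grDevices::hcl.colors(nlevels(group), "Dark 2")
  graphics::plot(s, col = cols[group], pch = as.integer(group) %% 25,
                 xlab = paste0("PC", components[1], " score"),
                 ylab = paste0("PC", components[2], " score"), ...)
  if (ellipses) {
    for (g in seq_len(nlevels(group))) {
      sg <- s[group == levels(group)[g], , drop = FALSE]
      if (nrow(sg) >= 3L) {
        el <- try(mahalanobis_ellipse(sg), silent = TRUE)
        if (!inherits(el, "try-error"))
          graphics::lines(ellipse_points(el), col = cols[g])
      }
    }
  }
  invisible(x)
}

#' Mahalanobis-distance-1 ellipse of a 2-D score cloud
#'
#' The distance-1 contour of a group: the unit circle in the coordinate
#' system given by the eigenvectors of the group's sample covariance
#' matrix. Centered on the group mean, with semi-axes equal to the
#' square roots of the covariance eigenvalues and orientation given by
#' the leading eigenvector.
#'
#' @param scores_2d An n-by-2 matrix of one group's scores, n >= 3.
#' @return A list of class `ellipse_spec`: `center` (length 2),
#'   `semi_axes` (length 2, decreasing), `angle` (radians in
#'   (-pi/2, pi/2]), and `cov`.
#' @export
mahalanobis_ellipse <- function(scores_2d) {
  s <- as.matrix(scores_2d)
  if (ncol(s) != 2L) stop("`scores_2d` must have exactly 2 columns")
  if (nrow(s) < 3L) stop("need at least 3 points for a covariance ellipse")
  ctr <- colMeans(s)
  V <- stats::cov(s)
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) <= .Machine$double.eps * max(e$values))
    stop("degenerate group: singular covariance matrix")
  v1 <- e$vectors[, 1]
  ang <- atan2(v1[2], v1[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  structure(list(center = ctr, semi_axes = sqrt(e$values),
                 angle = ang, cov = V),
            class = "ellipse_spec")
}

#' Points on a Mahalanobis ellipse boundary
#'
#' @param ellipse An `ellipse_spec` from [mahalanobis_ellipse()].
#' @param n Number of boundary points.
#' @return An n-by-2 matrix tracing the distance-1 contour.
#' @export
ellipse_points <- function(ellipse, n = 181L) {
  t <- seq(0, 2 * pi, length.out = n)
  u <- rbind(ellipse$semi_axes[1] * cos(t), ellipse$semi_axes[2] * sin(t))
  R <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  sweep(t(R %*% u), 2, ellipse$center, `+`)
}

#' Mahalanobis distance of points from an ellipse's group
#'
#' @param ellipse An `ellipse_spec`.
#' @param points An n-by-2 matrix.
#' @return Numeric vector of Mahalanobis distances from the group mean;
#'   points inside the ellipse have distance < 1.
#' @export
mahalanobis_distance <- function(ellipse, points) {
  p <- as.matrix(points)
  sqrt(stats::mahalanobis(p, ellipse$center, ellipse$cov))
}

#' Fisher linear discriminant analysis of PC scores
#'
#' Finds the projection maximizing between-class over within-class
#' scatter: the leading eigenvectors of W^-1 B where W and B are the
#' within- and between-class scatter matrices of the score vectors. At
#' most (classes - 1) discriminant coordinates exist. A singular W is
#' regularized by adding lambda * I with
#' lambda = 1e-8 * trace(W) / dim, with a warning.
#'
#' @param scores An n-by-d matrix (typically the first 10 PC scores).
#' @param labels n class labels (e.g. producer ids).
#' @return An object of class `fisher_lda`: `projection` (d by k,
#'   unit-norm columns ordered by discriminant eigenvalue),
#'   `eigenvalues`, `class_means` (class by k, in discriminant space),
#'   `class_labels`, `scores` (training projection).
#' @export
fit_lda <- function(scores, labels) {
  X <- as.matrix(scores)
  labels <- as.character(labels)
  if (nrow(X) != length(labels))
    stop("`labels` must have one entry per row of `scores`")
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("need at least 2 classes")
  d <- ncol(X)
  counts <- table(factor(labels, levels = cls))
  if (any(counts < 2L))
    stop("every class needs at least 2 observations")
  gm <- colMeans(X)
  W <- matrix(0, d, d); B <- matrix(0, d, d)
  for (g in cls) {
    Xg <- X[labels == g, , drop = FALSE]
    mg <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2, mg))
    B <- B + nrow(Xg) * tcrossprod(mg - gm)
  }
  if (rcond(W) < 1e-12) {
    warning("within-class scatter is (near-)singular; ",
            "regularizing with lambda * I")
    W <- W + diag(1e-8 * sum(diag(W)) / d, d)
  }
  # symmetric generalized eigenproblem via Cholesky whitening
  L <- chol(W)
  M <- backsolve(L, t(backsolve(L, t(B), transpose = TRUE)),
                 transpose = TRUE)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- min(length(cls) - 1L, d)
  A <- backsolve(L, e$vectors[, seq_len(k), drop = FALSE])
  A <- sweep(A, 2, sqrt(colSums(A^2)), `/`)
  for (j in seq_len(k))
    if (A[which.max(abs(A[, j])), j] < 0) A[, j] <- -A[, j]
  colnames(A) <- paste0("LD", seq_len(k))
  proj <- X %*% A
  cm <- do.call(rbind, lapply(cls, function(g)
    colMeans(proj[labels == g, , drop = FALSE])))
  rownames(cm) <- cls
  structure(list(projection = A,
                 eigenvalues = pmax(e$values[seq_len(k)], 0),
                 class_means = cm, class_labels = cls,
                 scores = proj, labels = labels),
            class = "fisher_lda")
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat("Fisher LDA:", length(x$class_labels), "classes,",
      ncol(x$projection), "discriminant coordinates\n")
  cat("  discriminant eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Classify score vectors by nearest class mean
#'
#' Projects score vectors into the fitted discriminant space and assigns
#' each to the class with the nearest mean (Euclidean distance in
#' discriminant space). Exact ties break to the lowest class label.
#'
#' @param lda A fitted [fit_lda()] model.
#' @param scores An n-by-d matrix matching the training dimension.
#' @return Character vector of class labels (empty for empty input).
#' @export
classify_groups <- function(lda, scores) {
  stopifnot(inherits(lda, "fisher_lda"))
  X <- as.matrix(scores)
  if (nrow(X) == 0L) return(character(0))
  if (ncol(X) != nrow(lda$projection))
    stop("scores have ", ncol(X), " columns; model expects ",
         nrow(lda$projection))
  P <- X %*% lda$projection
  D <- outer(rowSums(P^2), rep(1, nrow(lda$class_means))) -
    2 * P %*% t(lda$class_means) +
    outer(rep(1, nrow(P)), rowSums(lda$class_means^2))
  # round so exact geometric ties are not broken by float noise,
  # then max.col(ties = "first") takes the lowest label
  Dr <- round(D / max(D[is.finite(D)], 1), 12)
  lda$class_labels[max.col(-Dr, ties.method = "first")]
}

#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  classify_groups(object, newdata)
}
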