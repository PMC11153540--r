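#' @include AllClasses.R
NULL

# deterministic sign convention: the largest-magnitude loading on each
# axis is made positive (ties broken by the first such entry)
.fixSigns <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component analysis of aligned shapes
#'
#' PCA of the tangent-space coordinates (covariance-based, as is standard
#' for Procrustes shape data). Axes carry a deterministic sign convention
#' so scores are reproducible across runs.
#'
#' @param x an \code{AlignedShapes} object, or a plain numeric matrix of
#'   coordinates (rows = specimens).
#' @param tol relative eigenvalue threshold below which axes are dropped
#'   (shape data are rank-deficient by construction).
#' @return an \code{OrdinationResult}.
#' @export
shapePCA <- function(x, tol = 1e-10) {
  X <- if (is(x, "AlignedShapes")) tangentCoords(x) else as.matrix(x)
  if (nrow(X) < 3L) stop("PCA needs at least 3 specimens")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  ev <- sv$d^2 / (nrow(X) - 1L)
  total <- sum(ev)
  if (total <= 0) {
    warning("constant data: all eigenvalues are zero")
    keep <- 1L
    ve <- rep(0, 1L)
  } else {
    keep <- which(ev > tol * ev[1L])
    ve <- ev[keep] / total
  }
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- Xc %*% loadings
  fx <- .fixSigns(loadings, scores)
  rownames(fx$scores) <- rownames(X)
  colnames(fx$scores) <- colnames(fx$loadings) <-
    paste0("PC", seq_along(keep))
  rownames(fx$loadings) <- colnames(X)
  new("OrdinationResult", scores = fx$scores, loadings = fx$loadings,
      eigenvalues = ev[keep], varianceExplained = ve)
}

#' Canonical variate analysis of shape groups
#'
#' Because Procrustes tangent coordinates are rank-deficient (at most
#' 2k - 4 dimensions, usually fewer than the specimen count), the data are
#' first projected onto leading principal components so that the pooled
#' within-group covariance W is invertible; canonical axes, group
#' centroids, and pairwise Mahalanobis distances
#' \eqn{\sqrt{(\mu_i-\mu_j)^\top W^{-1} (\mu_i-\mu_j)}} are then computed
#' in that reduced space. Euclidean distances between group means are
#' measured in the original tangent space.
#'
#' @param x \code{AlignedShapes} or coordinate matrix.
#' @param labels group label per specimen (character or factor).
#' @param priorReduction \code{"auto"} (default: min(n - g, data rank)) or
#'   an integer number of principal components to retain.
#' @param varianceFraction when \code{priorReduction = "auto"}, also cap
#'   the subspace at this cumulative variance fraction.
#' @return a \code{CVAResult}.
#' @export
shapeCVA <- function(x, labels, priorReduction = "auto",
                     varianceFraction = 0.99) {
  X <- if (is(x, "AlignedShapes")) tangentCoords(x) else as.matrix(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(X))
  levs <- unique(labels)
  g <- length(levs)
  if (g < 2L) stop("CVA needs at least 2 groups")
  sizes <- table(factor(labels, levels = levs))
  if (any(sizes < 2L))
    stop("every group needs >= 2 specimens to pool within-group ",
         "covariance (offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")")
  n <- nrow(X)

  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1L)
  rank <- sum(ev > 1e-10 * max(ev[1L], .Machine$double.eps))
  r <- if (identical(priorReduction, "auto")) {
    rAuto <- min(n - g, rank)
    cum <- cumsum(ev[seq_len(rank)]) / sum(ev[seq_len(rank)])
    min(rAuto, max(1L, which(cum >= varianceFraction)[1L]))
  } else {
    min(as.integer(priorReduction), rank)
  }
  P <- sv$v[, seq_len(r), drop = FALSE]
  Z <- Xc %*% P

  means <- rowsum(Z, labels)[levs, , drop = FALSE] / as.vector(sizes[levs])
  W <- matrix(0, r, r)
  for (lv in levs) {
    Zi <- Z[labels == lv, , drop = FALSE]
    Zi <- sweep(Zi, 2L, colMeans(Zi))
    W <- W + crossprod(Zi)
  }
  W <- W / (n - g)
  Winv <- tryCatch(solve(W), error = function(e)
    stop("pooled within-group covariance is singular in the reduced ",
         "space; use a stronger priorReduction"))

  maha <- matrix(0, g, g, dimnames = list(levs, levs))
  for (i in seq_len(g)) for (j in seq_len(g)) if (i < j) {
    d <- means[i, ] - means[j, ]
    maha[i, j] <- maha[j, i] <- sqrt(drop(t(d) %*% Winv %*% d))
  }
  gm <- rowsum(X, labels)[levs, , drop = FALSE] / as.vector(sizes[levs])
  euc <- as.matrix(stats::dist(gm))

  # canonical axes: eigen of W^-1 B, scaled to unit within-group variance
  grand <- colMeans(Z)
  B <- matrix(0, r, r)
  for (i in seq_len(g)) {
    d <- means[i, ] - grand
    B <- B + sizes[levs][i] * tcrossprod(d)
  }
  B <- B / (n - g)
  es <- eigen(Winv %*% B)
  naxes <- min(g - 1L, r)
  A <- Re(es$vectors[, seq_len(naxes), drop = FALSE])
  for (j in seq_len(naxes)) {
    s <- sqrt(drop(t(A[, j]) %*% W %*% A[, j]))
    if (s > 0) A[, j] <- A[, j] / s
  }
  centroids <- means %*% A
  fx <- .fixSigns(A, centroids)
  colnames(fx$scores) <- colnames(fx$loadings) <-
    paste0("CV", seq_len(naxes))

  new("CVAResult", axes = fx$loadings, centroids = fx$scores, W = W,
      projection = P, center = ctr, groupMeans = gm,
      mahalanobis = maha, euclidean = euc, groups = levs)
}

.mahalanobisToCentroids <- function(Z, means, Winv) {
  g <- nrow(means)
  d2 <- matrix(NA_real_, nrow(Z), g)
  for (i in seq_len(g)) {
    D <- sweep(Z, 2L, means[i, ])
    d2[, i] <- rowSums((D %*% Winv) * D)
  }
  d2
}

#' Confusion-matrix classification of specimens to groups
#'
#' Assigns each specimen to the group whose centroid is nearest in
#' Mahalanobis distance (pooled within-group covariance, in the CVA's
#' reduced space), and tabulates true vs predicted group. Resubstitution
#' reuses the fitted means/W; leave-one-out refits the group means and
#' pooled covariance with the specimen held out (the PCA reduction basis
#' is kept fixed).
#'
#' @param cvares a fitted \code{CVAResult}.
#' @param x the same \code{AlignedShapes}/matrix the CVA was fitted on.
#' @param labels the same group labels.
#' @param mode \code{"resubstitution"} or \code{"leave_one_out"}.
#' @return a \code{ConfusionMatrix}.
#' @export
classifyConfusion <- function(cvares, x, labels,
                              mode = c("leave_one_out",
                                       "resubstitution")) {
  mode <- match.arg(mode)
  stopifnot(is(cvares, "CVAResult"))
  X <- if (is(x, "AlignedShapes")) tangentCoords(x) else as.matrix(x)
  labels <- as.character(labels)
  levs <- cvares@groups
  Z <- sweep(X, 2L, cvares@center) %*% cvares@projection
  n <- nrow(Z); g <- length(levs)

  if (mode == "resubstitution") {
    sizes <- table(factor(labels, levels = levs))
    means <- rowsum(Z, labels)[levs, , drop = FALSE] /
      as.vector(sizes[levs])
    d2 <- .mahalanobisToCentroids(Z, means, solve(cvares@W))
    pred <- levs[max.col(-d2, ties.method = "first")]
  } else {
    pred <- character(n)
    for (i in seq_len(n)) {
      Zi <- Z[-i, , drop = FALSE]
      li <- labels[-i]
      sizes <- table(factor(li, levels = levs))
      if (any(sizes < 2L))
        stop("leave-one-out needs >= 3 specimens per group")
      means <- rowsum(Zi, li)[levs, , drop = FALSE] /
        as.vector(sizes[levs])
      W <- matrix(0, ncol(Z), ncol(Z))
      for (lv in levs) {
        Zg <- Zi[li == lv, , drop = FALSE]
        Zg <- sweep(Zg, 2L, colMeans(Zg))
        W <- W + crossprod(Zg)
      }
      W <- W / (n - 1L - g)
      d2 <- .mahalanobisToCentroids(Z[i, , drop = FALSE], means, solve(W))
      pred[i] <- levs[which.min(d2)]
    }
  }
  counts <- table(factor(labels, levels = levs),
                  factor(pred, levels = levs))
  counts <- matrix(as.integer(counts), g, g, dimnames = list(levs, levs))
  rs <- rowSums(counts)
  perGroup <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  new("ConfusionMatrix", counts = counts,
      perGroupCorrect = stats::setNames(perGroup, levs),
      totalCorrect = sum(diag(counts)) / sum(counts), mode = mode)
}
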