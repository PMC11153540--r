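#' @include AllClasses.R
NULL

#' Resample a polyline to equally spaced points
#'
#' Places \code{n} points at equal arc-length spacing along an open
#' polyline, the first and last coinciding with its endpoints. This is the
#' semi-landmark scheme used for outline curves (e.g. mandible/pronotum/
#' elytron contours resampled to 50/25/50 points); the resampled points are
#' subsequently treated as fixed landmarks, with no sliding.
#'
#' @param curve 2-column coordinate matrix with at least 2 distinct points.
#' @param n number of output points (>= 2).
#' @return n x 2 coordinate matrix.
#' @export
resamplePolyline <- function(curve, n) {
  curve <- as.matrix(curve)
  if (nrow(curve) < 2L) stop("curve must have at least 2 points")
  if (n < 2L) stop("n must be >= 2")
  seg <- sqrt(rowSums((curve[-1L, , drop = FALSE] -
                       curve[-nrow(curve), , drop = FALSE])^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate input: zero-length curve")
  cum <- c(0, cumsum(seg))
  target <- seq(0, L, length.out = n)
  out <- matrix(NA_real_, n, 2L)
  out[1L, ] <- curve[1L, ]
  out[n, ] <- curve[nrow(curve), ]
  j <- 1L
  for (i in seq.int(2L, n - 1L)) {
    s <- target[i]
    while (cum[j + 1L] < s && j < length(seg)) j <- j + 1L
    denom <- cum[j + 1L] - cum[j]
    w <- if (denom > 0) (s - cum[j]) / denom else 0
    out[i, ] <- (1 - w) * curve[j, ] + w * curve[j + 1L, ]
  }
  out
}

#' Convert specimen records to landmark configurations
#'
#' Resamples each record's curves to the requested semi-landmark counts,
#' then concatenates them (in curve order) with any fixed landmarks into a
#' single configuration — the "semi-landmarks to landmarks" conversion that
#' precedes superimposition.
#'
#' @param records list of \code{SpecimenRecord} for one character.
#' @param resampleCounts integer vector, one semi-landmark count per curve
#'   (recycled across records); \code{NULL} keeps curves at their digitized
#'   point counts.
#' @param reverseCurves logical vector flagging curves whose digitization
#'   direction should be flipped before resampling (recycled).
#' @return list with \code{configs} (n x k x 2 array... returned as a list
#'   of k x 2 matrices named by specimen id) and \code{k}.
#' @export
specimensToConfigs <- function(records, resampleCounts = NULL,
                               reverseCurves = FALSE) {
  if (!length(records)) stop("no specimen records supplied")
  configs <- lapply(records, function(r) {
    pieces <- list()
    if (length(r@curves)) {
      nc <- length(r@curves)
      counts <- if (is.null(resampleCounts)) {
        vapply(r@curves, nrow, 1L)
      } else rep_len(resampleCounts, nc)
      rev <- rep_len(reverseCurves, nc)
      for (ci in seq_len(nc)) {
        cv <- r@curves[[ci]]
        if (rev[ci]) cv <- cv[rev(seq_len(nrow(cv))), , drop = FALSE]
        pieces[[length(pieces) + 1L]] <- resamplePolyline(cv, counts[ci])
      }
    }
    if (nrow(r@landmarks))
      pieces[[length(pieces) + 1L]] <- r@landmarks
    do.call(rbind, pieces)
  })
  ks <- vapply(configs, nrow, 1L)
  if (length(unique(ks)) != 1L)
    stop("specimens yield differing landmark counts: ",
         paste(unique(ks), collapse = ", "))
  names(configs) <- vapply(records, function(r) r@specimenID, "")
  list(configs = configs, k = ks[1L])
}

.centroidSize <- function(cfg) {
  ctr <- colMeans(cfg)
  sqrt(sum(sweep(cfg, 2L, ctr)^2))
}

# Optimal rotation (no reflection) aligning X onto Y, both pre-centered.
.optimalRotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes alignment
#'
#' Removes translation, scale and rotation (full Procrustes: every
#' configuration is scaled to unit centroid size; reflections are not
#' allowed, all specimens being digitized in a consistent orientation).
#' The consensus is estimated iteratively: rotate all configurations to the
#' current consensus, recompute it, and repeat until the consensus moves by
#' less than \code{tol} (Frobenius norm) or \code{maxIterations} is
#' reached. Aligned coordinates are also orthogonally projected onto the
#' tangent space at the consensus, where PCA/CVA operate.
#'
#' @param configs list of k x 2 landmark matrices (k identical), ideally
#'   named by specimen id.
#' @param tol consensus-change convergence tolerance.
#' @param maxIterations iteration cap.
#' @return an \code{AlignedShapes} object.
#' @export
gpaAlign <- function(configs, tol = 1e-10, maxIterations = 100L) {
  if (length(configs) < 2L) stop("need at least 2 configurations")
  k <- nrow(configs[[1L]])
  if (any(vapply(configs, nrow, 1L) != k))
    stop("all configurations must share the same landmark count")
  cs <- vapply(configs, .centroidSize, 0)
  if (any(cs <= 0))
    stop("degenerate input: configuration with zero centroid size")
  # center + unit scale
  shapes <- mapply(function(cfg, s) {
    sweep(cfg, 2L, colMeans(cfg)) / s
  }, configs, cs, SIMPLIFY = FALSE)

  consensus <- shapes[[1L]]
  consensus <- consensus / sqrt(sum(consensus^2))
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    shapes <- lapply(shapes, function(s) s %*% .optimalRotation(s, consensus))
    newCons <- Reduce(`+`, shapes) / length(shapes)
    newCons <- sweep(newCons, 2L, colMeans(newCons))
    newCons <- newCons / sqrt(sum(newCons^2))
    delta <- sqrt(sum((newCons - consensus)^2))
    consensus <- newCons
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= maxIterations) break
  }
  shapes <- lapply(shapes, function(s) s %*% .optimalRotation(s, consensus))

  asRow <- function(m) as.vector(t(m))  # x1 y1 x2 y2 ...
  coords <- do.call(rbind, lapply(shapes, asRow))
  rownames(coords) <- names(configs)
  colnames(coords) <- paste0(rep(c("x", "y"), k),
                             rep(seq_len(k), each = 2L))
  # orthogonal tangent projection at the consensus
  cvec <- asRow(consensus)
  proj <- coords - (coords %*% cvec) %*% t(cvec)
  tangent <- sweep(proj, 2L, cvec, `+`)
  dimnames(tangent) <- dimnames(coords)

  new("AlignedShapes", coords = coords, tangent = tangent,
      centroidSizes = unname(cs), consensus = consensus,
      iterations = iterations, converged = converged, k = as.integer(k))
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centered and scaled to unit centroid size, one
#' is optimally rotated onto the other (no reflection), and the root summed
#' squared difference is returned.
#'
#' @param a,b k x 2 landmark matrices.
#' @return non-negative scalar.
#' @export
procrustesDistance <- function(a, b) {
  norm1 <- function(m) {
    m <- sweep(as.matrix(m), 2L, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm1(a); b <- norm1(b)
  a <- a %*% .optimalRotation(a, b)
  sqrt(sum((a - b)^2))
}

#' Per-group mean shapes
#'
#' Arithmetic mean of the aligned (tangent-space) coordinates within each
#' terminal group; these means are the terminal taxa's shapes for ancestral
#' reconstruction.
#'
#' @param aligned an \code{AlignedShapes} whose rownames are specimen ids.
#' @param groups a \code{GroupTable} covering every specimen.
#' @return a \code{NodeShapes} object holding one k x 2 mean configuration
#'   per terminal group.
#' @export
groupMeanShapes <- function(aligned, groups) {
  stopifnot(is(aligned, "AlignedShapes"), is(groups, "GroupTable"))
  tb <- groups@table
  ids <- rownames(tangentCoords(aligned))
  if (is.null(ids)) stop("aligned coordinates must carry specimen ids")
  grp <- tb$terminal_group[match(ids, tb$specimen_id)]
  if (anyNA(grp))
    stop("specimen(s) missing from group table: ",
         paste(ids[is.na(grp)], collapse = ", "))
  levs <- unique(tb$terminal_group)
  levs <- levs[levs %in% grp]
  empty <- setdiff(unique(tb$terminal_group), levs)
  if (length(empty))
    stop("validation error: group(s) with zero specimens after filtering: ",
         paste(empty, collapse = ", "))
  k <- aligned@k
  arr <- array(NA_real_, dim = c(k, 2L, length(levs)),
               dimnames = list(NULL, c("x", "y"), levs))
  X <- tangentCoords(aligned)
  for (g in levs) {
    mu <- colMeans(X[grp == g, , drop = FALSE])
    arr[, , g] <- matrix(mu, ncol = 2L, byrow = TRUE)
  }
  new("NodeShapes", coords = arr,
      isTerminal = stats::setNames(rep(TRUE, length(levs)), levs))
}
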