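#' @include AllClasses.R
NULL

#' Per-branch deformation ratios (DR)
#'
#' For every edge of the dated tree, measures the morphological distance
#' between the parent and child node shapes and divides it by the elapsed
#' mean divergence time \eqn{\Delta t} (Ma), yielding the deformation
#' ratio DR — a per-branch rate of shape change. Two variants are always
#' computed: Euclidean distance in the tangent space, and Mahalanobis
#' distance after projecting both node shapes into a CVA's reduced space
#' and standardizing by the terminal pooled within-group covariance. CI
#' bounds on node ages, when present, are carried through for reporting
#' but never enter the DR computation (mean ages drive all \eqn{\Delta t}).
#'
#' @param tree a \code{TimeTree}.
#' @param nodeShapes a \code{NodeShapes} object covering every tree node.
#' @param distanceSpace optional \code{CVAResult} defining the Mahalanobis
#'   space; when \code{NULL}, Mahalanobis columns are \code{NA}.
#' @param zeroLengthEdges \code{"error"} (default) or \code{"epsilon"}:
#'   what to do when \eqn{\Delta t \le 0} (epsilon substitutes 1e-8 Ma
#'   with a warning).
#' @return data.frame with one row per edge: \code{parent}, \code{child},
#'   \code{parent_age}, \code{child_age}, \code{dt}, \code{dt_lo},
#'   \code{dt_hi}, \code{d_mahalanobis}, \code{d_euclidean},
#'   \code{dr_mahalanobis}, \code{dr_euclidean}.
#' @export
edgeDeformations <- function(tree, nodeShapes, distanceSpace = NULL,
                             zeroLengthEdges = c("error", "epsilon")) {
  zeroLengthEdges <- match.arg(zeroLengthEdges)
  stopifnot(is(tree, "TimeTree"), is(nodeShapes, "NodeShapes"))
  et <- edgeTable(tree)
  have <- dimnames(nodeShapes@coords)[[3L]]
  miss <- setdiff(unique(c(et$parent, et$child)), have)
  if (length(miss))
    stop("validation error: node(s) without a shape: ",
         paste(miss, collapse = ", "))

  vec <- function(lbl) as.vector(t(nodeShapes@coords[, , lbl]))
  if (!is.null(distanceSpace)) {
    stopifnot(is(distanceSpace, "CVAResult"))
    Winv <- solve(distanceSpace@W)
    projectNode <- function(lbl)
      drop((vec(lbl) - distanceSpace@center) %*% distanceSpace@projection)
  }

  dt <- et$dt
  if (any(dt <= 0)) {
    if (zeroLengthEdges == "error")
      stop("edge(s) with non-positive elapsed time: ",
           paste(paste(et$parent, et$child, sep = "->")[dt <= 0],
                 collapse = ", "))
    warning("substituting dt = 1e-8 Ma on ", sum(dt <= 0),
            " zero-length edge(s)")
    dt[dt <= 0] <- 1e-8
  }

  dEuc <- dMaha <- rep(NA_real_, nrow(et))
  for (i in seq_len(nrow(et))) {
    diffv <- vec(et$parent[i]) - vec(et$child[i])
    dEuc[i] <- sqrt(sum(diffv^2))
    if (!is.null(distanceSpace)) {
      dz <- projectNode(et$parent[i]) - projectNode(et$child[i])
      dMaha[i] <- sqrt(drop(t(dz) %*% Winv %*% dz))
    }
  }
  ages <- nodeAges(tree)
  lo <- stats::setNames(tree@agesLo, names(ages))
  hi <- stats::setNames(tree@agesHi, names(ages))
  data.frame(
    parent = et$parent, child = et$child,
    parent_age = et$parent_age, child_age = et$child_age, dt = dt,
    dt_lo = unname(lo[et$parent] - hi[et$child]),
    dt_hi = unname(hi[et$parent] - lo[et$child]),
    d_mahalanobis = dMaha, d_euclidean = dEuc,
    dr_mahalanobis = dMaha / dt, dr_euclidean = dEuc / dt,
    stringsAsFactors = FALSE
  )
}

.rootToTipPaths <- function(tree) {
  phy <- tree@phy
  ntip <- ape::Ntip(phy)
  labs <- nodeLabels(tree)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  lapply(seq_len(ntip), function(tp) {
    path <- tp
    nd <- tp
    while (parent[nd] != 0L) {
      nd <- parent[nd]
      path <- c(nd, path)
    }
    labs[path]
  })
}

#' Sequential growth rates (SGR) along root-to-tip lineages
#'
#' Orders each lineage's DR values from the root down (edges by decreasing
#' age) and computes the relative change between consecutive values,
#' \eqn{SGR_i = (DR_{i+1} - DR_i) / DR_i}. Each root-to-tip path gets its
#' own series, so edges basal to several tips are repeated across paths
#' (column \code{shared} flags them). A zero previous DR makes the SGR
#' undefined: it is emitted as \code{NA} with a warning, never as an
#' infinity.
#'
#' @param tree a \code{TimeTree}.
#' @param edges edge table from \code{\link{edgeDeformations}}.
#' @param variant \code{"mahalanobis"} (default, matching the index's
#'   standard presentation) or \code{"euclidean"}.
#' @return data.frame with columns \code{path_id} (tip label),
#'   \code{step} (1-based index of the later edge), \code{parent},
#'   \code{child}, \code{midpoint_age} (of the later edge, Ma),
#'   \code{dr_prev}, \code{dr_next}, \code{sgr}, \code{shared}.
#' @export
sgrAlongPaths <- function(tree, edges,
                          variant = c("mahalanobis", "euclidean")) {
  variant <- match.arg(variant)
  drcol <- paste0("dr_", variant)
  if (anyNA(edges[[drcol]]))
    stop("DR variant '", variant, "' not available in the edge table")
  key <- paste(edges$parent, edges$child)
  paths <- .rootToTipPaths(tree)
  out <- list()
  zeroWarned <- FALSE
  for (p in paths) {
    tip <- p[length(p)]
    ek <- paste(p[-length(p)], p[-1L])
    idx <- match(ek, key)
    dr <- edges[[drcol]][idx]
    if (length(dr) < 2L) next
    prev <- dr[-length(dr)]
    nxt <- dr[-1L]
    sgr <- ifelse(prev > 0, (nxt - prev) / prev, NA_real_)
    if (anyNA(sgr) && !zeroWarned) {
      warning("zero previous DR on some path step(s); SGR emitted as NA")
      zeroWarned <- TRUE
    }
    later <- idx[-1L]
    out[[tip]] <- data.frame(
      path_id = tip, step = seq_along(sgr),
      parent = edges$parent[later], child = edges$child[later],
      midpoint_age = (edges$parent_age[later] +
                      edges$child_age[later]) / 2,
      dr_prev = prev, dr_next = nxt, sgr = sgr,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # an edge is shared when it appears on more than one root-to-tip path
  tab <- table(paste(res$parent, res$child))
  res$shared <- tab[paste(res$parent, res$child)] > 1L
  res$shared <- as.vector(res$shared)
  res
}

#' Piecewise-constant DR series for step line charts
#'
#' Each edge contributes its DR as a constant over the age interval
#' [child age, parent age]; one series per root-to-tip lineage so that
#' overlapping branches remain distinguishable.
#'
#' @param edges edge table from \code{\link{edgeDeformations}}.
#' @param tree a \code{TimeTree}.
#' @param variant \code{"mahalanobis"} or \code{"euclidean"}.
#' @return data.frame with columns \code{lineage} (tip label),
#'   \code{parent}, \code{child}, \code{age_start} (older bound),
#'   \code{age_end}, \code{dr}.
#' @export
stepChartSeries <- function(edges, tree,
                            variant = c("mahalanobis", "euclidean")) {
  variant <- match.arg(variant)
  drcol <- paste0("dr_", variant)
  key <- paste(edges$parent, edges$child)
  paths <- .rootToTipPaths(tree)
  out <- lapply(paths, function(p) {
    tip <- p[length(p)]
    idx <- match(paste(p[-length(p)], p[-1L]), key)
    data.frame(
      lineage = tip,
      parent = edges$parent[idx], child = edges$child[idx],
      age_start = edges$parent_age[idx], age_end = edges$child_age[idx],
      dr = edges[[drcol]][idx], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Best-fit trend curve through (age, SGR) points
#'
#' Deterministic smooth summarizing how an index varies along the
#' timeline: either a polynomial least-squares fit or a loess smooth,
#' sampled on a uniform age grid for plotting.
#'
#' @param points data.frame (or 2-column matrix) with columns \code{age}
#'   and \code{value} (e.g. SGR).
#' @param method \code{"ols_poly"} or \code{"loess"}.
#' @param degree polynomial degree for \code{ols_poly}.
#' @param span loess span.
#' @param gridLength number of grid samples.
#' @return list with \code{method}, \code{coefficients} (ols_poly only,
#'   intercept first), \code{grid} (data.frame \code{age},
#'   \code{fitted}), and the fitted model object.
#' @export
fitTrend <- function(points, method = c("ols_poly", "loess"), degree = 2L,
                     span = 0.75, gridLength = 100L) {
  method <- match.arg(method)
  points <- as.data.frame(points)
  if (is.null(points$age) || is.null(points$value)) {
    names(points)[1:2] <- c("age", "value")
  }
  points <- points[is.finite(points$age) & is.finite(points$value), ]
  if (nrow(points) < 3L) stop("need at least 3 finite points")
  grid <- data.frame(age = seq(min(points$age), max(points$age),
                               length.out = gridLength))
  if (method == "ols_poly") {
    if (nrow(points) < degree + 1L)
      stop("validation error: fewer points than polynomial coefficients")
    # tied ages (e.g. balanced trees) support fewer polynomial terms
    degree <- min(degree, length(unique(points$age)) - 1L)
    fit <- stats::lm(value ~ poly(age, degree, raw = TRUE), data = points)
    co <- unname(stats::coef(fit))
    grid$fitted <- drop(stats::predict(fit, newdata = grid))
    list(method = method, coefficients = co, grid = grid, model = fit)
  } else {
    fit <- stats::loess(value ~ age, data = points, span = span,
                        degree = 2L)
    grid$fitted <- drop(stats::predict(fit, newdata = grid))
    list(method = method, coefficients = NULL, grid = grid, model = fit)
  }
}
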