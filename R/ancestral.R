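#' @include AllClasses.R
NULL

#' Ancestral landmark configurations by squared-change parsimony
#'
#' Estimates the landmark configuration at every internal node as the
#' minimizer of the branch-length-weighted sum of squared changes,
#' \eqn{\sum_{edges} \|x_{parent} - x_{child}\|^2 / \Delta t}. Solved
#' exactly, coordinate by coordinate, through the tree's weighted Laplacian
#' linear system; with \code{weighting = "equal"} all edges get unit
#' weight. The weighted solution coincides with the maximum-likelihood
#' point estimate of ancestral states under Brownian motion.
#'
#' @param tree a \code{TimeTree}.
#' @param tipShapes a \code{NodeShapes} object (or named list of k x 2
#'   matrices) providing one configuration per tree terminal, in the common
#'   tangent space.
#' @param weighting \code{"branch_length"} (weights \eqn{1/\Delta t}; zero
#'   -length edges get \eqn{\Delta t = 10^{-8}} Ma) or \code{"equal"}.
#' @return a \code{NodeShapes} object covering every node of the tree
#'   (terminals carry their input shapes).
#' @export
reconstructShapes <- function(tree, tipShapes,
                              weighting = c("branch_length", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(is(tree, "TimeTree"))
  if (is(tipShapes, "NodeShapes")) {
    labs3 <- dimnames(tipShapes@coords)[[3L]]
    tipList <- stats::setNames(
      lapply(labs3, function(l) tipShapes@coords[, , l]), labs3)
  } else tipList <- tipShapes
  phy <- tree@phy
  tips <- phy$tip.label
  miss <- setdiff(tips, names(tipList))
  if (length(miss))
    stop("validation error: missing tip shape(s): ",
         paste(miss, collapse = ", "))
  k <- nrow(tipList[[tips[1L]]])
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  nn <- ntip + nnode

  tipMat <- do.call(rbind, lapply(tips, function(tp)
    as.vector(t(tipList[[tp]]))))  # ntip x 2k

  w <- if (weighting == "branch_length") {
    dt <- tree@ages[phy$edge[, 1L]] - tree@ages[phy$edge[, 2L]]
    1 / pmax(dt, 1e-8)
  } else rep(1, nrow(phy$edge))

  # weighted Laplacian restricted to internal nodes
  L <- matrix(0, nnode, nnode)
  B <- matrix(0, nnode, 2L * k)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L] - ntip
    ch <- phy$edge[e, 2L]
    L[p, p] <- L[p, p] + w[e]
    if (ch > ntip) {
      ci <- ch - ntip
      L[ci, ci] <- L[ci, ci] + w[e]
      L[p, ci] <- L[p, ci] - w[e]
      L[ci, p] <- L[ci, p] - w[e]
    } else {
      B[p, ] <- B[p, ] + w[e] * tipMat[ch, ]
    }
  }
  anc <- solve(L, B)  # nnode x 2k

  labs <- nodeLabels(tree)
  arr <- array(NA_real_, dim = c(k, 2L, nn),
               dimnames = list(NULL, c("x", "y"), labs))
  for (i in seq_len(ntip)) arr[, , i] <- tipList[[labs[i]]]
  for (i in seq_len(nnode))
    arr[, , ntip + i] <- matrix(anc[i, ], ncol = 2L, byrow = TRUE)
  new("NodeShapes", coords = arr,
      isTerminal = stats::setNames(seq_len(nn) <= ntip, labs))
}

#' Ancestral discrete states by parsimony (Sankoff)
#'
#' Minimum-cost reconstruction of a discrete character (e.g. feeding type)
#' over the tree under an arbitrary substitution-cost matrix; uniform
#' costs give Fitch parsimony. Per node, the full set of states attained
#' in at least one minimum-cost assignment is reported — ties are never
#' broken silently.
#'
#' @param tree a \code{TimeTree}.
#' @param tipStates named character vector, tip label -> state.
#' @param costs square cost matrix with state dimnames, or \code{NULL} for
#'   uniform (0 diagonal, 1 elsewhere) costs.
#' @param states state vocabulary (defaults to the sorted unique tip
#'   states, or the cost matrix's dimnames).
#' @return a \code{DiscreteReconstruction} with per-node state sets and
#'   \code{treeLength} = minimal total cost.
#' @export
fitchSankoff <- function(tree, tipStates, costs = NULL, states = NULL) {
  stopifnot(is(tree, "TimeTree"))
  phy <- tree@phy
  tips <- phy$tip.label
  miss <- setdiff(tips, names(tipStates))
  if (length(miss))
    stop("validation error: missing tip state(s): ",
         paste(miss, collapse = ", "))
  if (is.null(states))
    states <- if (!is.null(costs)) rownames(costs)
              else sort(unique(unname(tipStates[tips])))
  bad <- setdiff(unique(unname(tipStates[tips])), states)
  if (length(bad))
    stop("validation error: state(s) outside vocabulary: ",
         paste(bad, collapse = ", "))
  ns <- length(states)
  if (is.null(costs)) {
    costs <- matrix(1, ns, ns, dimnames = list(states, states))
    diag(costs) <- 0
  } else costs <- costs[states, states]

  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  BIG <- 1e12

  S <- matrix(BIG, nn, ns)  # min cost of subtree with node fixed to state
  up <- function(nd) {
    if (nd <= ntip) {
      S[nd, ] <<- BIG
      S[nd, match(tipStates[[tips[nd]]], states)] <<- 0
      return(invisible())
    }
    for (ch in kids[[as.character(nd)]]) up(ch)
    tot <- rep(0, ns)
    for (ch in kids[[as.character(nd)]]) {
      cmin <- apply(costs + rep(S[ch, ], each = ns), 1L, min)
      tot <- tot + cmin
    }
    S[nd, ] <<- tot
    invisible()
  }
  root <- ntip + 1L
  up(root)
  best <- min(S[root, ])

  # outside-subtree cost U; node state is optimal iff S + U == best
  U <- matrix(BIG, nn, ns)
  U[root, ] <- 0
  down <- function(nd) {
    if (nd <= ntip) return(invisible())
    ch <- kids[[as.character(nd)]]
    sibSum <- lapply(ch, function(c1) {
      tot <- rep(0, ns)
      for (c2 in setdiff(ch, c1)) {
        tot <- tot + apply(costs + rep(S[c2, ], each = ns), 1L, min)
      }
      tot
    })
    for (ci in seq_along(ch)) {
      base <- U[nd, ] + sibSum[[ci]]  # per parent state s
      U[ch[ci], ] <<- apply(costs + base, 2L, min)
      down(ch[ci])
    }
    invisible()
  }
  down(root)

  labs <- nodeLabels(tree)
  sets <- lapply(seq_len(nn), function(nd) {
    states[which(S[nd, ] + U[nd, ] <= best + 1e-9)]
  })
  names(sets) <- labs
  new("DiscreteReconstruction", stateSets = sets,
      weights = matrix(numeric(0), 0L, 0L), treeLength = best,
      method = "parsimony", states = states)
}

# equal-rates transition probability: k-state ER model, off-diagonal rate q
.erTransition <- function(q, t, ns) {
  e <- exp(-ns * q * t)
  same <- 1 / ns + (1 - 1 / ns) * e
  diff <- 1 / ns - e / ns
  M <- matrix(diff, ns, ns)
  diag(M) <- same
  M
}

#' Ancestral discrete states by equal-rates Markov likelihood
#'
#' Fits a k-state equal-rates Markov (Mk/ER) model on the dated tree by
#' 1-D maximization of the pruning-algorithm likelihood over the transition
#' rate (per Ma), then reports normalized marginal state weights at every
#' node (uniform root prior).
#'
#' @param tree a \code{TimeTree} (branch durations in Ma).
#' @param tipStates named character vector, tip label -> state.
#' @param states state vocabulary (default: sorted unique tip states).
#' @param rate fixed transition rate; \code{NULL} (default) maximizes it.
#' @return a \code{DiscreteReconstruction} with a nodes x states weight
#'   matrix and the fitted \code{rate}.
#' @export
mkMLStates <- function(tree, tipStates, states = NULL, rate = NULL) {
  stopifnot(is(tree, "TimeTree"))
  phy <- tree@phy
  tips <- phy$tip.label
  miss <- setdiff(tips, names(tipStates))
  if (length(miss))
    stop("validation error: missing tip state(s): ",
         paste(miss, collapse = ", "))
  if (is.null(states)) states <- sort(unique(unname(tipStates[tips])))
  bad <- setdiff(unique(unname(tipStates[tips])), states)
  if (length(bad))
    stop("validation error: state(s) outside vocabulary: ",
         paste(bad, collapse = ", "))
  ns <- length(states)
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  edgeDt <- rep(NA_real_, nn)
  edgeDt[phy$edge[, 2L]] <- pmax(
    tree@ages[phy$edge[, 1L]] - tree@ages[phy$edge[, 2L]], 1e-8)

  partials <- function(q) {
    Lk <- matrix(NA_real_, nn, ns)
    scale <- 0
    up <- function(nd) {
      if (nd <= ntip) {
        Lk[nd, ] <<- as.numeric(states == tipStates[[tips[nd]]])
        return(invisible())
      }
      v <- rep(1, ns)
      for (ch in kids[[as.character(nd)]]) {
        up(ch)
        P <- .erTransition(q, edgeDt[ch], ns)
        v <- v * drop(P %*% Lk[ch, ])
      }
      m <- max(v)
      if (m > 0) { v <- v / m; scale <<- scale + log(m) }
      Lk[nd, ] <<- v
      invisible()
    }
    up(root)
    list(Lk = Lk, scale = scale)
  }
  loglik <- function(q) {
    pr <- partials(q)
    log(sum(pr$Lk[root, ] / ns)) + pr$scale
  }

  diag <- character(0)
  if (is.null(rate)) {
    H <- max(tree@ages)
    opt <- tryCatch(
      stats::optimize(function(lq) loglik(exp(lq)),
                      interval = log(c(1e-8 / max(H, 1), 1e3 / max(H, 1))),
                      maximum = TRUE),
      error = function(e) NULL)
    if (is.null(opt)) {
      diag <- "rate optimization failed; fell back to 1/tree height"
      rate <- 1 / max(H, 1)
    } else rate <- exp(opt$maximum)
  }

  pr <- partials(rate)
  Lk <- pr$Lk
  # downward pass for marginals: D[nd, s] = likelihood of data outside
  # nd's subtree given nd is in state s (root prior folded in)
  D <- matrix(NA_real_, nn, ns)
  D[root, ] <- 1 / ns
  down <- function(nd) {
    if (nd <= ntip) return(invisible())
    ch <- kids[[as.character(nd)]]
    condo <- lapply(ch, function(c1) {
      P <- .erTransition(rate, edgeDt[c1], ns)
      drop(P %*% Lk[c1, ])  # per parent state
    })
    for (ci in seq_along(ch)) {
      other <- rep(1, ns)
      for (cj in seq_along(ch)) if (cj != ci) other <- other * condo[[cj]]
      P <- .erTransition(rate, edgeDt[ch[ci]], ns)
      D[ch[ci], ] <<- drop(t(P) %*% (D[nd, ] * other))
      m <- max(D[ch[ci], ])
      if (m > 0) D[ch[ci], ] <<- D[ch[ci], ] / m
      down(ch[ci])
    }
    invisible()
  }
  down(root)
  w <- Lk * D
  w <- w / rowSums(w)
  dimnames(w) <- list(nodeLabels(tree), states)
  obj <- new("DiscreteReconstruction", stateSets = list(), weights = w,
             treeLength = NA_real_, method = "mk_ml", rate = rate,
             states = states)
  if (length(diag)) attr(obj, "diagnostics") <- diag
  obj
}
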