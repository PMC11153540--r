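# shared test fixtures and independent oracles (kept deliberately separate
# from the package's own code paths)

# load oracle packages up front so no individual test alters global state
loadNamespace("phangorn")

# random k-landmark configuration
randConfig <- function(k, sd = 1) {
  matrix(rnorm(2L * k, sd = sd), ncol = 2L)
}

# TimeTree from a newick string plus explicit ages (ape node-number order)
tinyTree <- function(text, ages) {
  phy <- ape::read.tree(text = text)
  TimeTree(phy, ages)
}

# ordinary 2-D Procrustes fit of X onto Y via the complex-number closed
# form (centers both, scales X to unit centroid size, rotates by the
# optimal angle) — independent of the package's SVD route
oracleOPA <- function(X, Y) {
  ctr <- function(m) sweep(m, 2L, colMeans(m))
  X <- ctr(X); Y <- ctr(Y)
  X <- X / sqrt(sum(X^2))
  zx <- complex(real = X[, 1L], imaginary = X[, 2L])
  zy <- complex(real = Y[, 1L], imaginary = Y[, 2L])
  w <- sum(Conj(zx) * zy)
  rot <- w / Mod(w)
  zr <- zx * rot
  cbind(Re(zr), Im(zr))
}

# alternating-OPA generalized Procrustes oracle: explicit ordinary fits to
# the running consensus until the consensus stabilizes
oracleGPA <- function(configs, tol = 1e-12, maxit = 2000L) {
  shapes <- lapply(configs, function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / sqrt(sum(m^2))
  })
  cons <- shapes[[1L]]
  repeat {
    shapes <- lapply(shapes, oracleOPA, Y = cons)
    newCons <- Reduce(`+`, shapes) / length(shapes)
    newCons <- sweep(newCons, 2L, colMeans(newCons))
    newCons <- newCons / sqrt(sum(newCons^2))
    if (sqrt(sum((newCons - cons)^2)) < tol) break
    cons <- newCons
    maxit <- maxit - 1L
    if (maxit <= 0L) break
  }
  newCons
}

# exhaustive minimum-cost parsimony oracle: enumerates every assignment of
# states to internal nodes
oracleParsimony <- function(phy, tipStates, states) {
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  ns <- length(states)
  tipIdx <- match(tipStates[phy$tip.label], states)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nnode)))
  cost <- apply(grid, 1L, function(assign) {
    full <- c(tipIdx, assign)
    sum(full[phy$edge[, 1L]] != full[phy$edge[, 2L]])
  })
  best <- min(cost)
  sets <- lapply(seq_len(nnode), function(i)
    sort(states[unique(grid[cost == best, i])]))
  list(length = best, sets = sets)
}

# brute-force marginal likelihoods for the equal-rates Mk model by summing
# over every internal assignment with explicit transition matrices
oracleMkMarginals <- function(phy, ages, tipStates, states, rate) {
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  ns <- length(states)
  Pmat <- function(t) {
    e <- exp(-ns * rate * t)
    M <- matrix(1 / ns - e / ns, ns, ns)
    diag(M) <- 1 / ns + (1 - 1 / ns) * e
    M
  }
  tipIdx <- match(tipStates[phy$tip.label], states)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nnode)))
  lik <- apply(grid, 1L, function(assign) {
    full <- c(tipIdx, assign)
    p <- 1 / ns
    for (e in seq_len(nrow(phy$edge))) {
      a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
      p <- p * Pmat(ages[a] - ages[b])[full[a], full[b]]
    }
    p
  })
  marg <- matrix(0, ntip + nnode, ns)
  for (i in seq_len(ntip)) marg[i, tipIdx[i]] <- 1
  for (j in seq_len(nnode)) for (s in seq_len(ns))
    marg[ntip + j, s] <- sum(lik[grid[, j] == s])
  marg / rowSums(marg)
}

# NodeShapes from a named list of k x 2 matrices (all terminal)
tipShapeSet <- function(shapeList) {
  k <- nrow(shapeList[[1L]])
  arr <- array(NA_real_, dim = c(k, 2L, length(shapeList)),
               dimnames = list(NULL, c("x", "y"), names(shapeList)))
  for (nm in names(shapeList)) arr[, , nm] <- shapeList[[nm]]
  new("NodeShapes", coords = arr,
      isTerminal = setNames(rep(TRUE, length(shapeList)),
                            names(shapeList)))
}
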