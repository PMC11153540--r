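#' @include AllClasses.R
NULL

# run expr with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate
#' the structure of a multi-character landmark study on a dated tree:
#' group mean shapes evolving by multivariate Brownian motion (variance
#' \code{baseRate} per coordinate per Ma, optionally multiplied on named
#' branches), i.i.d. Gaussian digitization noise on each specimen, and a
#' discrete feeding type evolving under an equal-rates Markov model.
#'
#' @param nTips number of terminal groups.
#' @param treeType \code{"balanced"} (nTips must be a power of 2) or
#'   \code{"random"} (coalescent topology rescaled to \code{rootAge}).
#' @param rootAge root age in Ma.
#' @param characters named integer vector: landmark count per character.
#' @param baseRate Brownian variance per coordinate per Ma.
#' @param shifts named numeric vector: child-node label -> rate
#'   multiplier applied to the edge above that node.
#' @param noiseSd per-specimen digitization noise (sd per coordinate).
#' @param nSpecimensPerTip replicate specimens per terminal group.
#' @param states discrete-state vocabulary.
#' @param discreteRate transition rate of the feeding-type Markov model
#'   (per Ma).
#' @param jitter apply a random rotation/translation/scale to each emitted
#'   specimen (exercises the Procrustes superimposition).
#' @param seed integer seed governing one hierarchical random stream.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nTips = 8L, treeType = c("balanced", "random"),
                             rootAge = 150,
                             characters = c(character1 = 12L),
                             baseRate = 1e-4, shifts = numeric(0),
                             noiseSd = 0.005, nSpecimensPerTip = 10L,
                             states = c("omnivory", "coprophagy",
                                        "phytophagy"),
                             discreteRate = 0.005, jitter = FALSE,
                             seed = 1L) {
  treeType <- match.arg(treeType)
  stopifnot(nTips >= 2L, rootAge > 0, baseRate >= 0, noiseSd >= 0,
            nSpecimensPerTip >= 1L, discreteRate >= 0)
  if (any(characters < 3L)) stop("every character needs k >= 3 landmarks")
  if (length(shifts) && (is.null(names(shifts)) || any(shifts <= 0)))
    stop("shifts must be a named vector of positive multipliers")
  if (!length(states)) stop("state set must be non-empty")
  if (is.null(names(characters)))
    names(characters) <- paste0("character", seq_along(characters))
  structure(list(nTips = as.integer(nTips), treeType = treeType,
                 rootAge = rootAge, characters = characters,
                 baseRate = baseRate, shifts = shifts, noiseSd = noiseSd,
                 nSpecimensPerTip = as.integer(nSpecimensPerTip),
                 states = states, discreteRate = discreteRate,
                 jitter = isTRUE(jitter), seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' The four-character study configuration
#'
#' Landmark counts matching the standard scarab design: outline characters
#' resampled to 50/25/50 semi-landmarks (mandible/pronotum/elytron) plus a
#' 16-landmark hindwing.
#'
#' @param ... overrides passed on to \code{\link{simulationConfig}}.
#' @return a \code{SimulationConfig}.
#' @export
fourCharacterConfig <- function(...) {
  simulationConfig(characters = c(mandible = 50L, pronotum = 25L,
                                  elytron = 50L, hindwing = 16L), ...)
}

#' Balanced dated tree
#'
#' Fully balanced topology over \code{2^d} tips with node ages split evenly
#' by depth (root at \code{rootAge}, tips at 0).
#'
#' @param nTips power of 2.
#' @param rootAge root age, Ma.
#' @return a \code{TimeTree}.
#' @export
balancedTimeTree <- function(nTips, rootAge) {
  d <- log2(nTips)
  if (abs(d - round(d)) > 1e-9)
    stop("balanced tree needs a power-of-2 tip count")
  d <- as.integer(round(d))
  build <- function(lo, hi, depth) {
    if (depth == d) return(paste0("t", lo))
    mid <- (lo + hi + 1L) %/% 2L
    age <- rootAge * (d - depth) / d
    ageCh <- rootAge * (d - depth - 1L) / d
    paste0("(", build(lo, mid - 1L, depth + 1L), ":", age - ageCh, ",",
           build(mid, hi, depth + 1L), ":", age - ageCh, ")")
  }
  txt <- paste0(build(1L, nTips, 0L), ";")
  phy <- ape::read.tree(text = txt)
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth[seq_len(nTips)]) - depth
  ages[seq_len(nTips)] <- 0
  TimeTree(phy, ages)
}

#' Random dated tree
#'
#' Coalescent topology (\code{ape::rcoal}) rescaled so the root sits at
#' \code{rootAge}.
#'
#' @param nTips tip count.
#' @param rootAge root age, Ma.
#' @param seed integer seed.
#' @return a \code{TimeTree}.
#' @export
randomTimeTree <- function(nTips, rootAge, seed = 1L) {
  phy <- .withSeed(seed, ape::rcoal(nTips, tip.label = paste0("t",
                                                       seq_len(nTips))))
  depth <- ape::node.depth.edgelength(phy)
  H <- max(depth[seq_len(nTips)])
  phy$edge.length <- phy$edge.length * rootAge / H
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth[seq_len(nTips)]) - depth
  ages[seq_len(nTips)] <- 0
  TimeTree(phy, ages)
}

.regularPolygon <- function(k) {
  th <- 2 * pi * (seq_len(k) - 1L) / k
  cfg <- cbind(cos(th), sin(th))
  cfg <- sweep(cfg, 2L, colMeans(cfg))
  cfg / sqrt(sum(cfg^2))
}

# BM evolution of one character's mean shapes over the tree; returns the
# node-shape truth plus per-edge displacement norms and realized rates
.simulateCharacter <- function(tree, k, sigma2, shifts, template = NULL) {
  phy <- tree@phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  labs <- nodeLabels(tree)
  root <- ntip + 1L
  if (is.null(template)) template <- .regularPolygon(k)
  X <- matrix(NA_real_, nn, 2L * k)
  X[root, ] <- as.vector(t(template))
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  edgeRate <- stats::setNames(rep(sigma2, nrow(phy$edge)),
                              labs[phy$edge[, 2L]])
  for (s in names(shifts))
    edgeRate[names(edgeRate) == s] <- sigma2 * shifts[[s]]
  disp <- numeric(nrow(phy$edge))
  ord <- ape::reorder.phylo(phy, "cladewise")$edge  # parents before kids
  eIndex <- stats::setNames(seq_len(nrow(phy$edge)),
                            paste(phy$edge[, 1L], phy$edge[, 2L]))
  for (r in seq_len(nrow(ord))) {
    p <- ord[r, 1L]; ch <- ord[r, 2L]
    dt <- tree@ages[p] - tree@ages[ch]
    rate <- edgeRate[[labs[ch]]]
    step <- stats::rnorm(2L * k, 0, sqrt(rate * dt))
    X[ch, ] <- X[p, ] + step
    disp[eIndex[[paste(p, ch)]]] <- sqrt(sum(step^2))
  }
  arr <- array(NA_real_, dim = c(k, 2L, nn),
               dimnames = list(NULL, c("x", "y"), labs))
  for (i in seq_len(nn)) arr[, , i] <- matrix(X[i, ], ncol = 2L,
                                              byrow = TRUE)
  shapes <- new("NodeShapes", coords = arr,
                isTerminal = stats::setNames(seq_len(nn) <= ntip, labs))
  list(shapes = shapes,
       edges = data.frame(parent = labs[phy$edge[, 1L]],
                          child = labs[phy$edge[, 2L]],
                          displacement = disp,
                          rate = unname(edgeRate),
                          stringsAsFactors = FALSE))
}

.jitterSpecimen <- function(cfg) {
  th <- stats::runif(1L, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  s <- exp(stats::rnorm(1L, 0, 0.2))
  shift <- stats::rnorm(2L, 0, 0.5)
  sweep(s * cfg %*% R, 2L, shift, `+`)
}

#' Simulate Brownian-motion shape data on a dated tree
#'
#' Generates the full synthetic dataset described by a
#' \code{\link{simulationConfig}}: a dated tree, per-character true mean
#' shapes at every node (root = regular polygon, children = parent plus
#' independent Gaussian displacements of variance rate x \eqn{\Delta t}
#' per coordinate), noisy replicate specimens at each tip, and a discrete
#' feeding type at every node. Deterministic for a fixed seed.
#'
#' @param config a \code{SimulationConfig}.
#' @return list with \code{tree} (\code{TimeTree}), \code{groups}
#'   (\code{GroupTable}), \code{specimens} (named list per character of
#'   \code{SpecimenRecord} lists), and \code{truth} (per-character node
#'   shapes and edge displacements, plus node states).
#' @export
simulateBMShapes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  tree <- if (config$treeType == "balanced")
    balancedTimeTree(config$nTips, config$rootAge)
  else randomTimeTree(config$nTips, config$rootAge, seed = config$seed)

  disc <- simulateDiscreteTrait(tree, config$states, config$discreteRate,
                                seed = config$seed + 1L)
  tips <- tree@phy$tip.label
  truth <- list(states = disc, characters = list())
  specimens <- list()
  for (ci in seq_along(config$characters)) {
    chName <- names(config$characters)[ci]
    k <- config$characters[[ci]]
    sim <- .withSeed(config$seed + 1000L * ci,
                     .simulateCharacter(tree, k, config$baseRate,
                                        config$shifts))
    recs <- .withSeed(config$seed + 1000L * ci + 500L, {
      out <- list()
      for (tp in tips) {
        mu <- sim$shapes@coords[, , tp]
        for (j in seq_len(config$nSpecimensPerTip)) {
          cfg <- mu + matrix(stats::rnorm(2L * k, 0, config$noiseSd),
                             ncol = 2L)
          if (config$jitter) cfg <- .jitterSpecimen(cfg)
          out[[length(out) + 1L]] <- SpecimenRecord(
            specimenID = sprintf("%s_%s_s%02d", chName, tp, j),
            characterName = chName, landmarks = cfg, taxon = tp)
        }
      }
      out
    })
    specimens[[chName]] <- recs
    truth$characters[[chName]] <- sim
  }
  tipStates <- vapply(tips, function(tp)
    disc$nodeStates[[tp]], "")
  groups <- GroupTable(data.frame(
    specimen_id = unlist(lapply(specimens, function(rl)
      vapply(rl, function(r) r@specimenID, ""))),
    terminal_group = unlist(lapply(specimens, function(rl)
      vapply(rl, function(r) r@taxon, ""))),
    feeding_type = unlist(lapply(specimens, function(rl)
      vapply(rl, function(r) tipStates[[r@taxon]], ""))),
    stringsAsFactors = FALSE), feedingVocabulary = config$states)
  list(tree = tree, groups = groups, specimens = specimens, truth = truth)
}

#' Simulate a discrete trait under an equal-rates Markov model
#'
#' Root state uniform over the vocabulary; along each edge the child state
#' is drawn from the equal-rates transition probability for the edge's
#' duration. Truth is recorded at every node.
#'
#' @param tree a \code{TimeTree}.
#' @param states state vocabulary.
#' @param rate transition rate per Ma (>= 0; 0 keeps the root state
#'   everywhere).
#' @param seed integer seed.
#' @return list with \code{nodeStates} (named list over all node labels)
#'   and \code{tipStates} (named character vector).
#' @export
simulateDiscreteTrait <- function(tree, states, rate, seed = 1L) {
  stopifnot(is(tree, "TimeTree"), rate >= 0)
  if (!length(states)) stop("state set must be non-empty")
  phy <- tree@phy
  ntip <- ape::Ntip(phy)
  labs <- nodeLabels(tree)
  ns <- length(states)
  .withSeed(seed, {
    st <- character(ntip + phy$Nnode)
    root <- ntip + 1L
    st[root] <- sample(states, 1L)
    ord <- ape::reorder.phylo(phy, "cladewise")$edge
    for (r in seq_len(nrow(ord))) {
      p <- ord[r, 1L]; ch <- ord[r, 2L]
      dt <- tree@ages[p] - tree@ages[ch]
      P <- .erTransition(rate, dt, ns)
      st[ch] <- sample(states, 1L,
                       prob = P[match(st[p], states), ])
    }
    list(nodeStates = stats::setNames(as.list(st), labs),
         tipStates = stats::setNames(st[seq_len(ntip)],
                                     labs[seq_len(ntip)]))
  })
}

#' Write a synthetic fixture to disk
#'
#' Emits the dataset in the pipeline's own input formats: one TPS file per
#' character, an age-annotated Newick tree, a specimen/group CSV, and a
#' JSON ground-truth file keyed by the same node labels — so every reader
#' in the package can be exercised end to end without external data.
#'
#' @param config a \code{SimulationConfig}.
#' @param dir output directory.
#' @param force overwrite a non-empty existing directory.
#' @return invisible list of written paths plus the in-memory dataset.
#' @export
makeFixture <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory ", dir, " is non-empty; use force = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulateBMShapes(config)
  paths <- list()
  for (chName in names(ds$specimens)) {
    p <- file.path(dir, paste0(chName, ".tps"))
    writeTPS(ds$specimens[[chName]], p)
    paths[[paste0("tps_", chName)]] <- p
  }
  paths$tree <- file.path(dir, "tree.nwk")
  writeTimeTree(ds$tree, paths$tree)
  paths$groups <- file.path(dir, "groups.csv")
  utils::write.csv(ds$groups@table, paths$groups, row.names = FALSE)
  paths$truth <- file.path(dir, "truth.json")
  truthJSON <- list(
    node_states = ds$truth$states$nodeStates,
    characters = lapply(ds$truth$characters, function(sim) {
      labs <- dimnames(sim$shapes@coords)[[3L]]
      list(node_shapes = stats::setNames(lapply(labs, function(l)
        unclass(sim$shapes@coords[, , l])), labs),
        edges = sim$edges)
    }))
  jsonlite::write_json(truthJSON, paths$truth, digits = NA,
                       auto_unbox = TRUE)
  invisible(c(paths, list(dataset = ds)))
}
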