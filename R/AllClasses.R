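#' @import methods
NULL

setOldClass("phylo")

#' A single digitized specimen
#'
#' Holds the raw digitization of one specimen for one morphological
#' character: zero or more open curves (polylines, as produced by outline
#' tracing) and/or a set of fixed landmarks, plus identifiers and optional
#' scale metadata.
#'
#' @slot specimenID character scalar, unique within a dataset.
#' @slot taxon character scalar (may be \code{NA}).
#' @slot characterName character scalar naming the character
#'   (e.g. \code{"mandible"}, \code{"hindwing"}).
#' @slot curves list of numeric matrices with two columns (x, y); each
#'   polyline has at least two points.
#' @slot landmarks numeric matrix with two columns (possibly zero rows).
#' @slot scale numeric scalar, units per pixel, or \code{NA_real_}.
#' @slot imageRef character scalar or \code{NA_character_}.
#' @slot metadata character vector of opaque lines (COMMENT= etc.)
#'   preserved verbatim on round trip.
#'
#' @exportClass SpecimenRecord
setClass("SpecimenRecord",
  representation(
    specimenID = "character",
    taxon = "character",
    characterName = "character",
    curves = "list",
    landmarks = "matrix",
    scale = "numeric",
    imageRef = "character",
    metadata = "character"
  ),
  prototype(
    taxon = NA_character_,
    curves = list(),
    landmarks = matrix(numeric(0), ncol = 2),
    scale = NA_real_,
    imageRef = NA_character_,
    metadata = character(0)
  )
)

setValidity("SpecimenRecord", function(object) {
  msg <- character(0)
  if (length(object@specimenID) != 1L || is.na(object@specimenID) ||
      !nzchar(object@specimenID))
    msg <- c(msg, "specimenID must be a non-empty character scalar")
  for (cv in object@curves) {
    if (!is.matrix(cv) || ncol(cv) != 2L || nrow(cv) < 2L)
      msg <- c(msg, "every curve must be a 2-column matrix with >= 2 points")
    else if (anyNA(cv))
      msg <- c(msg, "curves must not contain NA coordinates")
  }
  if (ncol(object@landmarks) != 2L)
    msg <- c(msg, "landmarks must have 2 columns")
  if (anyNA(object@landmarks))
    msg <- c(msg, "landmarks must not contain NA coordinates")
  if (!is.na(object@scale) && object@scale <= 0)
    msg <- c(msg, "scale must be positive")
  if (length(msg)) msg else TRUE
})

#' Specimen-to-group assignment table
#'
#' Maps each specimen to its terminal group (the tip taxon it belongs to on
#' the tree) and that group's feeding type. Feeding type is constant within
#' a terminal group.
#'
#' @slot table data.frame with columns \code{specimen_id},
#'   \code{terminal_group}, \code{feeding_type}.
#' @slot feedingVocabulary character vector of admissible feeding-type
#'   tokens.
#'
#' @exportClass GroupTable
setClass("GroupTable",
  representation(table = "data.frame", feedingVocabulary = "character"),
  prototype(feedingVocabulary = c("omnivory", "coprophagy", "phytophagy",
                                  "other"))
)

setValidity("GroupTable", function(object) {
  tb <- object@table
  msg <- character(0)
  need <- c("specimen_id", "terminal_group", "feeding_type")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$specimen_id))
    msg <- c(msg, "each specimen_id must map to exactly one terminal_group")
  bad <- setdiff(unique(tb$feeding_type), object@feedingVocabulary)
  if (length(bad))
    msg <- c(msg, paste0("unknown feeding_type token(s): ",
                         paste(bad, collapse = ", ")))
  ft <- tapply(tb$feeding_type, tb$terminal_group,
               function(x) length(unique(x)))
  if (any(ft > 1L))
    msg <- c(msg, "feeding_type must be constant within a terminal_group")
  if (length(msg)) msg else TRUE
})

#' Rooted, dated phylogeny with node ages
#'
#' Wraps an \pkg{ape} \code{phylo} tree with per-node mean ages (Ma) and
#' optional 95\% CI bounds. Internal nodes always carry labels (unlabeled
#' nodes are auto-labeled \code{"NodeK"} in preorder, root first, so that
#' tabular outputs are joinable across runs).
#'
#' @slot phy a rooted \code{phylo} object with tip and node labels.
#' @slot ages numeric vector of mean node ages in Ma, one per node in
#'   ape node-number order (tips then internals).
#' @slot agesLo,agesHi numeric vectors of optional 95\% CI bounds
#'   (\code{NA} where absent), aligned with \code{ages}.
#'
#' @exportClass TimeTree
setClass("TimeTree",
  representation(phy = "phylo", ages = "numeric", agesLo = "numeric",
                 agesHi = "numeric")
)

setValidity("TimeTree", function(object) {
  phy <- object@phy
  nn <- ape::Ntip(phy) + phy$Nnode
  msg <- character(0)
  if (length(object@ages) != nn)
    return("ages must have one entry per node")
  if (any(object@ages < -1e-9, na.rm = TRUE))
    msg <- c(msg, "node ages must be >= 0")
  dt <- object@ages[phy$edge[, 1L]] - object@ages[phy$edge[, 2L]]
  if (any(dt < -1e-9))
    msg <- c(msg, "parent age must be >= child age on every edge")
  if (anyDuplicated(phy$tip.label))
    msg <- c(msg, "terminal labels must be unique")
  ok <- is.na(object@agesLo) | is.na(object@agesHi) |
    (object@agesLo <= object@ages + 1e-9 &
     object@ages <= object@agesHi + 1e-9)
  if (!all(ok))
    msg <- c(msg, "age CI bounds must bracket the mean age")
  if (length(msg)) msg else TRUE
})

#' Procrustes-superimposed shapes
#'
#' Result of generalized Procrustes analysis: all configurations centered
#' at the origin, scaled to unit centroid size, and rotated to the iterative
#' consensus, plus the orthogonal tangent-space projection at the consensus
#' in which all linear multivariate analyses operate.
#'
#' @slot coords numeric matrix, n specimens x 2k Procrustes coordinates
#'   (columns x1, y1, ..., xk, yk); rownames are specimen IDs.
#' @slot tangent numeric matrix of the same shape: coordinates after
#'   orthogonal projection onto the tangent space at the consensus.
#' @slot centroidSizes numeric vector of original centroid sizes.
#' @slot consensus numeric k x 2 matrix, the converged mean shape.
#' @slot iterations integer, GPA iterations used.
#' @slot converged logical.
#' @slot k integer, landmarks per configuration.
#'
#' @exportClass AlignedShapes
setClass("AlignedShapes",
  representation(coords = "matrix", tangent = "matrix",
                 centroidSizes = "numeric", consensus = "matrix",
                 iterations = "integer", converged = "logical",
                 k = "integer")
)

setValidity("AlignedShapes", function(object) {
  msg <- character(0)
  if (ncol(object@coords) != 2L * object@k)
    msg <- c(msg, "coords must have 2k columns")
  if (nrow(object@coords) != length(object@centroidSizes))
    msg <- c(msg, "one centroid size per specimen required")
  for (i in seq_len(nrow(object@coords))) {
    cfg <- matrix(object@coords[i, ], ncol = 2L, byrow = TRUE)
    if (max(abs(colMeans(cfg))) > 1e-8)
      msg <- c(msg, "aligned centroids must lie at the origin")
    if (abs(sqrt(sum(cfg^2)) - 1) > 1e-8)
      msg <- c(msg, "aligned centroid sizes must equal 1")
    if (length(msg)) break
  }
  if (length(msg)) msg else TRUE
})

#' Principal component ordination of shapes
#'
#' @slot scores n x m matrix of PC scores.
#' @slot loadings 2k x m orthonormal matrix with a deterministic sign
#'   convention (largest-magnitude loading per axis positive).
#' @slot eigenvalues non-increasing numeric vector.
#' @slot varianceExplained fractions summing to 1 over retained axes.
#'
#' @exportClass OrdinationResult
setClass("OrdinationResult",
  representation(scores = "matrix", loadings = "matrix",
                 eigenvalues = "numeric", varianceExplained = "numeric")
)

setValidity("OrdinationResult", function(object) {
  msg <- character(0)
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(ev < -1e-12))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Canonical variate analysis of groups in shape space
#'
#' CVA fitted in a PCA-reduced subspace (Procrustes data are rank-deficient,
#' so the pooled within-group covariance W is estimated after projection
#' onto leading principal components). Stores everything needed to project
#' new configurations (e.g. reconstructed ancestral shapes) into the same
#' space and measure Mahalanobis distances with the terminal pooled W.
#'
#' @slot axes r x a matrix of canonical axes (a = min(g-1, r)), scaled so
#'   that within-group variance along each axis is 1.
#' @slot centroids g x a group centroids in canonical space.
#' @slot W r x r pooled within-group covariance in the reduced space.
#' @slot projection 2k x r PCA basis used for the reduction.
#' @slot center length-2k centering vector (grand mean) applied before
#'   projection.
#' @slot groupMeans g x 2k group means in the original tangent space.
#' @slot mahalanobis,euclidean g x g symmetric distance matrices between
#'   group means (Mahalanobis via W in reduced space; Euclidean in the
#'   tangent space).
#' @slot groups character vector of group levels.
#'
#' @exportClass CVAResult
setClass("CVAResult",
  representation(axes = "matrix", centroids = "matrix", W = "matrix",
                 projection = "matrix", center = "numeric",
                 groupMeans = "matrix", mahalanobis = "matrix",
                 euclidean = "matrix", groups = "character")
)

setValidity("CVAResult", function(object) {
  msg <- character(0)
  M <- object@mahalanobis
  if (!isSymmetric(unname(M), tol = 1e-8))
    msg <- c(msg, "mahalanobis matrix must be symmetric")
  if (any(diag(M) != 0))
    msg <- c(msg, "mahalanobis diagonal must be zero")
  if (any(M < 0))
    msg <- c(msg, "mahalanobis distances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Confusion matrix from group classification
#'
#' @slot counts g x g integer matrix, rows = true group, columns =
#'   predicted group.
#' @slot perGroupCorrect named numeric vector of per-group correct
#'   fractions.
#' @slot totalCorrect numeric scalar, trace / total.
#' @slot mode character, \code{"resubstitution"} or \code{"leave_one_out"}.
#'
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", perGroupCorrect = "numeric",
                 totalCorrect = "numeric", mode = "character")
)

setValidity("ConfusionMatrix", function(object) {
  tot <- sum(object@counts)
  if (tot > 0 &&
      abs(object@totalCorrect - sum(diag(object@counts)) / tot) > 1e-12)
    return("totalCorrect must equal trace/total")
  TRUE
})

#' Landmark configurations attached to tree nodes
#'
#' One mean (terminal) or reconstructed (ancestral) landmark configuration
#' per tree node, all in the common Procrustes/tangent coordinate system.
#'
#' @slot coords k x 2 x n_nodes numeric array; dimnames[[3]] are node
#'   labels.
#' @slot isTerminal named logical vector aligned with the third dimension.
#'
#' @exportClass NodeShapes
setClass("NodeShapes",
  representation(coords = "array", isTerminal = "logical")
)

setValidity("NodeShapes", function(object) {
  d <- dim(object@coords)
  msg <- character(0)
  if (length(d) != 3L || d[2L] != 2L)
    return("coords must be a k x 2 x n array")
  if (is.null(dimnames(object@coords)[[3L]]))
    msg <- c(msg, "coords must carry node labels in dimnames[[3]]")
  if (length(object@isTerminal) != d[3L])
    msg <- c(msg, "isTerminal must align with the node dimension")
  if (anyNA(object@coords))
    msg <- c(msg, "node shapes must not contain NA coordinates")
  if (length(msg)) msg else TRUE
})

#' Ancestral reconstruction of a discrete character
#'
#' Parsimony reconstructions store, per node, the set of states attained in
#' at least one minimum-cost assignment; likelihood reconstructions store
#' normalized marginal weights per node.
#'
#' @slot stateSets named list (node label -> character vector of states),
#'   empty for likelihood reconstructions.
#' @slot weights numeric matrix (nodes x states) of normalized marginal
#'   weights, 0 x 0 for parsimony reconstructions.
#' @slot treeLength numeric, minimal total cost (parsimony steps under
#'   uniform costs); \code{NA} for likelihood reconstructions.
#' @slot method character, \code{"parsimony"} or \code{"mk_ml"}.
#' @slot rate numeric, fitted transition rate per Ma (\code{NA} for
#'   parsimony).
#' @slot states character vector, the state vocabulary.
#'
#' @exportClass DiscreteReconstruction
setClass("DiscreteReconstruction",
  representation(stateSets = "list", weights = "matrix",
                 treeLength = "numeric", method = "character",
                 rate = "numeric", states = "character"),
  prototype(rate = NA_real_, treeLength = NA_real_)
)
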