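#' @include AllClasses.R
NULL

# ---- generics ---------------------------------------------------------------

#' Node labels of a dated tree
#'
#' @param x a \code{TimeTree} (or object with labeled nodes).
#' @return character vector of labels in ape node-number order
#'   (tips first, then internal nodes).
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Mean node ages in Ma
#'
#' @param x a \code{TimeTree}.
#' @return named numeric vector of mean node ages (Ma), names are node
#'   labels.
#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))

#' Per-edge table of a dated tree
#'
#' @param x a \code{TimeTree}.
#' @return data.frame with columns \code{parent}, \code{child} (labels),
#'   \code{parent_age}, \code{child_age}, \code{dt} (all Ma).
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Aligned Procrustes coordinates
#'
#' @param x an \code{AlignedShapes} object.
#' @return n x 2k coordinate matrix.
#' @export
setGeneric("alignedCoords", function(x) standardGeneric("alignedCoords"))

#' Tangent-space coordinates
#'
#' @param x an \code{AlignedShapes} object.
#' @return n x 2k matrix of coordinates orthogonally projected onto the
#'   tangent space at the consensus.
#' @export
setGeneric("tangentCoords", function(x) standardGeneric("tangentCoords"))

#' Consensus (mean) shape
#'
#' @param x an \code{AlignedShapes} object.
#' @return k x 2 matrix.
#' @export
setGeneric("consensusShape", function(x) standardGeneric("consensusShape"))

#' Centroid sizes before scaling
#'
#' @param x an \code{AlignedShapes} object.
#' @return numeric vector of original centroid sizes.
#' @export
setGeneric("centroidSizes", function(x) standardGeneric("centroidSizes"))

#' Pairwise Mahalanobis distances between groups
#'
#' @param x a \code{CVAResult}.
#' @return symmetric g x g matrix.
#' @export
setGeneric("mahalanobisDistances",
           function(x) standardGeneric("mahalanobisDistances"))

#' Pairwise Euclidean distances between group means
#'
#' @param x a \code{CVAResult}.
#' @return symmetric g x g matrix.
#' @export
setGeneric("euclideanDistances",
           function(x) standardGeneric("euclideanDistances"))

#' Shape attached to one tree node
#'
#' @param x a \code{NodeShapes} object.
#' @param label node label.
#' @return k x 2 landmark matrix.
#' @export
setGeneric("nodeShape", function(x, label) standardGeneric("nodeShape"))

# ---- methods ----------------------------------------------------------------

#' @describeIn nodeLabels labels of a TimeTree
#' @export
setMethod("nodeLabels", "TimeTree", function(x) {
  c(x@phy$tip.label, x@phy$node.label)
})

#' @describeIn nodeAges ages of a TimeTree
#' @export
setMethod("nodeAges", "TimeTree", function(x) {
  stats::setNames(x@ages, nodeLabels(x))
})

#' @describeIn edgeTable edge table of a TimeTree
#' @export
setMethod("edgeTable", "TimeTree", function(x) {
  labs <- nodeLabels(x)
  e <- x@phy$edge
  data.frame(
    parent = labs[e[, 1L]],
    child = labs[e[, 2L]],
    parent_age = x@ages[e[, 1L]],
    child_age = x@ages[e[, 2L]],
    dt = x@ages[e[, 1L]] - x@ages[e[, 2L]],
    stringsAsFactors = FALSE
  )
})

#' @describeIn alignedCoords coordinates of AlignedShapes
#' @export
setMethod("alignedCoords", "AlignedShapes", function(x) x@coords)

#' @describeIn tangentCoords tangent coordinates of AlignedShapes
#' @export
setMethod("tangentCoords", "AlignedShapes", function(x) x@tangent)

#' @describeIn consensusShape consensus of AlignedShapes
#' @export
setMethod("consensusShape", "AlignedShapes", function(x) x@consensus)

#' @describeIn centroidSizes centroid sizes of AlignedShapes
#' @export
setMethod("centroidSizes", "AlignedShapes", function(x) x@centroidSizes)

#' @describeIn mahalanobisDistances distances from a CVAResult
#' @export
setMethod("mahalanobisDistances", "CVAResult", function(x) x@mahalanobis)

#' @describeIn euclideanDistances distances from a CVAResult
#' @export
setMethod("euclideanDistances", "CVAResult", function(x) x@euclidean)

#' @describeIn nodeShape extract one node's configuration
#' @export
setMethod("nodeShape", "NodeShapes", function(x, label) {
  if (!label %in% dimnames(x@coords)[[3L]])
    stop("no shape stored for node '", label, "'")
  x@coords[, , label]
})

# ---- show -------------------------------------------------------------------

setMethod("show", "SpecimenRecord", function(object) {
  cat("SpecimenRecord '", object@specimenID, "' (", object@characterName,
      ")\n", sep = "")
  cat("  curves: ", length(object@curves),
      if (length(object@curves))
        paste0(" (", paste(vapply(object@curves, nrow, 1L), collapse = "/"),
               " pts)") else "",
      "; fixed landmarks: ", nrow(object@landmarks), "\n", sep = "")
  if (!is.na(object@scale))
    cat("  scale:", format(object@scale), "units/pixel\n")
})

setMethod("show", "GroupTable", function(object) {
  tb <- object@table
  cat("GroupTable:", nrow(tb), "specimens,",
      length(unique(tb$terminal_group)), "terminal groups,",
      length(unique(tb$feeding_type)), "feeding types\n")
})

setMethod("show", "TimeTree", function(object) {
  cat("TimeTree:", ape::Ntip(object@phy), "tips,", object@phy$Nnode,
      "internal nodes; root age",
      format(max(object@ages), digits = 5), "Ma\n")
})

setMethod("show", "AlignedShapes", function(object) {
  cat("AlignedShapes:", nrow(object@coords), "configurations of",
      object@k, "landmarks;",
      if (object@converged) "GPA converged in" else
        "GPA NOT converged after",
      object@iterations, "iterations\n")
})

setMethod("show", "OrdinationResult", function(object) {
  cat("OrdinationResult:", ncol(object@scores), "axes;",
      "PC1 explains",
      sprintf("%.1f%%", 100 * object@varianceExplained[1L]), "\n")
})

setMethod("show", "CVAResult", function(object) {
  cat("CVAResult:", length(object@groups), "groups,",
      ncol(object@axes), "canonical axes,",
      "reduced dimension", nrow(object@axes), "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (", object@mode, "): total correct ",
      sprintf("%.2f%%", 100 * object@totalCorrect), "\n", sep = "")
  print(object@counts)
})

setMethod("show", "NodeShapes", function(object) {
  d <- dim(object@coords)
  cat("NodeShapes:", d[3L], "nodes (", sum(object@isTerminal),
      "terminal ),", d[1L], "landmarks each\n")
})

setMethod("show", "DiscreteReconstruction", function(object) {
  cat("DiscreteReconstruction (", object@method, ")",
      if (!is.na(object@treeLength))
        paste0(": tree length ", object@treeLength) else
        paste0(": rate ", format(object@rate, digits = 4), "/Ma"),
      "\n", sep = "")
})
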