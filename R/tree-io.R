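#' @include AllClasses.R
NULL

#' Construct a TimeTree from a phylo object and node ages
#'
#' Unlabeled internal nodes are auto-labeled \code{"NodeK"} in preorder
#' (root = Node1), so outputs are joinable across runs.
#'
#' @param phy rooted \code{phylo} object.
#' @param ages numeric vector of node ages (Ma) in ape node-number order.
#' @param agesLo,agesHi optional 95\% CI bounds (NA where absent).
#' @return a validated \code{TimeTree}.
#' @export
TimeTree <- function(phy, ages, agesLo = rep(NA_real_, length(ages)),
                     agesHi = rep(NA_real_, length(ages))) {
  # the newick outermost grouping is taken as the root; basal polytomies
  # (which ape::is.rooted flags as unrooted) are legitimate dated trees
  phy <- .autoLabelNodes(phy)
  new("TimeTree", phy = phy, ages = as.numeric(ages),
      agesLo = as.numeric(agesLo), agesHi = as.numeric(agesHi))
}

# Assign "NodeK" labels to unlabeled internal nodes, K running in preorder
# (cladewise edge order, root first). Stable for a fixed topology.
.autoLabelNodes <- function(phy) {
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  labs <- phy$node.label
  if (is.null(labs)) labs <- rep("", nnode)
  labs[is.na(labs)] <- ""
  phy2 <- ape::reorder.phylo(phy, "cladewise")
  root <- ntip + 1L
  pre <- c(root, phy2$edge[phy2$edge[, 2L] > ntip, 2L])
  k <- 0L
  for (nd in pre) {
    k <- k + 1L
    if (!nzchar(labs[nd - ntip])) labs[nd - ntip] <- paste0("Node", k)
  }
  phy$node.label <- labs
  phy
}

# Extract "[&...]" comments from a newick string, splicing a sentinel into
# the label of the node each comment follows; returns the cleaned string
# plus the comment bodies. ape::read.tree drops bracket comments, hence
# this pre-pass.
.extractNewickComments <- function(txt) {
  comments <- character(0)
  out <- character(0)
  i <- 1L
  chars <- strsplit(txt, "")[[1L]]
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "[") {
      j <- i
      depth <- 0L
      repeat {
        if (j > n) stop("unterminated '[' comment in tree file")
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        if (depth == 0L) break
        j <- j + 1L
      }
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      comments <- c(comments, body)
      out <- c(out, sprintf("MRCMT%dTMCRM", length(comments)))
      i <- j + 1L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  list(text = paste(out, collapse = ""), comments = comments)
}

.parseAgeComment <- function(body) {
  body <- sub("^&", "", body)
  res <- list(age = NA_real_, lo = NA_real_, hi = NA_real_)
  m <- regmatches(body,
    regexec("age_95=\\{\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\s*\\}",
            body))[[1L]]
  if (length(m)) {
    res$lo <- as.numeric(m[2L]); res$hi <- as.numeric(m[3L])
  }
  m <- regmatches(body, regexec("(^|[,&])age=([-0-9.eE+]+)", body))[[1L]]
  if (length(m)) res$age <- as.numeric(m[3L])
  res
}

#' Read a time-calibrated tree
#'
#' Accepts a single rooted tree in Newick or (simple, untranslated) Nexus
#' form. Node ages (Ma) come either from bracketed annotations
#' (\code{[&age=93]}, \code{[&age=93,age_95={66,122}]}) — in which case all
#' internal nodes must be annotated and unannotated tips are extant (age
#' 0) — or, when no annotations are present, from branch lengths on an
#' ultrametric tree (age = depth above the tips). A non-ultrametric tree
#' without explicit ages is rejected: its node ages would be ambiguous.
#'
#' @param path path to the tree file.
#' @param dialect \code{"newick"} or \code{"nexus"}.
#' @return a \code{TimeTree}.
#' @export
readTimeTree <- function(path, dialect = c("newick", "nexus")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("tree file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (dialect == "nexus") {
    m <- regmatches(txt,
      regexec("(?is)tree\\s+[^=]+=\\s*(\\[[^][]*\\])?\\s*([^;]+;)", txt,
              perl = TRUE))[[1L]]
    if (length(m) == 0L)
      stop("no tree statement found in Nexus file ", path)
    if (grepl("(?i)translate", txt, perl = TRUE))
      stop("Nexus translate tables are not supported; ",
           "export the tree with full labels")
    txt <- m[3L]
  }
  ex <- .extractNewickComments(txt)
  phy <- ape::read.tree(text = ex$text)
  if (is.null(phy)) stop("could not parse tree in ", path)
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("validation error: negative branch length in ", path)

  # recover comments spliced into labels
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  labs <- c(phy$tip.label,
            if (is.null(phy$node.label)) rep("", phy$Nnode)
            else phy$node.label)
  labs[is.na(labs)] <- ""
  ann <- vector("list", nn)
  for (i in seq_len(nn)) {
    m <- regmatches(labs[i], regexec("^(.*?)MRCMT([0-9]+)TMCRM$",
                                     labs[i]))[[1L]]
    if (length(m)) {
      labs[i] <- m[2L]
      ann[[i]] <- .parseAgeComment(ex$comments[as.integer(m[3L])])
    }
  }
  phy$tip.label <- labs[seq_len(ntip)]
  phy$node.label <- labs[(ntip + 1L):nn]

  hasAnn <- !vapply(ann, is.null, TRUE)
  ages <- rep(NA_real_, nn)
  lo <- rep(NA_real_, nn); hi <- rep(NA_real_, nn)
  if (any(hasAnn)) {
    for (i in which(hasAnn)) {
      ages[i] <- ann[[i]]$age
      lo[i] <- ann[[i]]$lo; hi[i] <- ann[[i]]$hi
      if (is.na(ages[i]) && !is.na(lo[i]))
        ages[i] <- (lo[i] + hi[i]) / 2
    }
    internal <- (ntip + 1L):nn
    if (anyNA(ages[internal]))
      stop("validation error: age annotations present but not on every ",
           "internal node in ", path)
    ages[seq_len(ntip)][is.na(ages[seq_len(ntip)])] <- 0
  } else {
    if (is.null(phy$edge.length))
      stop("validation error: tree has neither branch lengths nor age ",
           "annotations")
    depth <- ape::node.depth.edgelength(phy)  # root -> node path lengths
    tipDepth <- depth[seq_len(ntip)]
    H <- max(tipDepth)
    if (diff(range(tipDepth)) > 1e-6 * max(H, 1))
      stop("validation error: tree is not ultrametric and carries no age ",
           "annotations; node ages are ambiguous")
    ages <- H - depth
    ages[seq_len(ntip)] <- 0
  }
  TimeTree(phy, ages, lo, hi)
}

#' Write a TimeTree as annotated Newick
#'
#' Emits branch lengths (Ma, from mean ages) plus \code{[&age=]} (and
#' \code{age_95=} when present) annotations on internal nodes, a form
#' \code{\link{readTimeTree}} parses back losslessly.
#'
#' @param tree a \code{TimeTree}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTimeTree <- function(tree, path) {
  phy <- tree@phy
  ntip <- ape::Ntip(phy)
  labs <- nodeLabels(tree)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  rec <- function(nd) {
    age <- tree@ages[nd]
    if (nd <= ntip) return(labs[nd])
    ann <- sprintf("[&age=%.10g", age)
    if (!is.na(tree@agesLo[nd]))
      ann <- paste0(ann, sprintf(",age_95={%.10g,%.10g}",
                                 tree@agesLo[nd], tree@agesHi[nd]))
    ann <- paste0(ann, "]")
    parts <- vapply(kids[[as.character(nd)]], function(ch) {
      paste0(rec(ch), ":", sprintf("%.10g", age - tree@ages[ch]))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")", labs[nd], ann)
  }
  writeLines(paste0(rec(ntip + 1L), ";"), path)
  invisible(path)
}
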