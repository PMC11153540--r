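#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Declarative description of one end-to-end run. Every default is echoed
#' into the run log so a published run is self-describing.
#'
#' @param tpsPaths named character vector: character name -> TPS path.
#' @param treePath dated tree file.
#' @param groupPath specimen/group CSV.
#' @param resampleCounts named list: character name -> integer vector of
#'   per-curve semi-landmark counts (\code{NULL} entries keep digitized
#'   point counts).
#' @param treeDialect \code{"newick"} or \code{"nexus"}.
#' @param cvaReduction \code{"auto"} or integer, see
#'   \code{\link{shapeCVA}}.
#' @param weighting ancestral-reconstruction weighting, see
#'   \code{\link{reconstructShapes}}.
#' @param drVariant \code{"mahalanobis"} or \code{"euclidean"} for the
#'   default step-chart/SGR series.
#' @param sgrWindows list of \code{c(lo, hi)} age windows (Ma) for spread
#'   summaries.
#' @param trendMethod \code{"ols_poly"} or \code{"loess"}.
#' @param trendDegree polynomial degree for the trend fit.
#' @param outDir output directory.
#' @param seed integer seed echoed into outputs (the pipeline itself is
#'   deterministic).
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(tpsPaths, treePath, groupPath,
                           resampleCounts = NULL,
                           treeDialect = "newick",
                           cvaReduction = "auto",
                           weighting = "branch_length",
                           drVariant = c("mahalanobis", "euclidean"),
                           sgrWindows = list(),
                           trendMethod = "ols_poly", trendDegree = 2L,
                           outDir = tempfile("morphorates_run_"),
                           seed = 1L) {
  drVariant <- match.arg(drVariant)
  if (is.null(names(tpsPaths)))
    stop("tpsPaths must be named by character")
  for (w in sgrWindows)
    if (length(w) != 2L || w[1L] >= w[2L])
      stop("each SGR window must be c(lo, hi) with lo < hi")
  structure(list(tpsPaths = tpsPaths, treePath = treePath,
                 groupPath = groupPath, resampleCounts = resampleCounts,
                 treeDialect = treeDialect, cvaReduction = cvaReduction,
                 weighting = weighting, drVariant = drVariant,
                 sgrWindows = sgrWindows, trendMethod = trendMethod,
                 trendDegree = as.integer(trendDegree), outDir = outDir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

.logLine <- function(log, ...) c(log, paste0(format(Sys.time(),
  "%H:%M:%S "), paste0(...)))

#' Run the full morphological-rate pipeline
#'
#' Chains every stage for each character: TPS input, semi-landmark
#' resampling and conversion to landmarks, Procrustes superimposition,
#' PCA, CVA with confusion matrices (by feeding type and by terminal
#' group, resubstitution and leave-one-out), squared-change-parsimony
#' ancestral shapes, discrete ancestral feeding types (parsimony), per
#' -branch deformation ratios, SGR series, step-chart tables, window
#' spreads and trend fits. All artifacts are written as CSV/JSON under
#' \code{config$outDir} together with a checksum manifest and a run log;
#' reruns with identical inputs give identical checksums.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisible list with the in-memory results per character plus
#'   \code{manifest} and \code{outDir}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$seed)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  log <- .logLine(log, "pipeline start; configuration:")
  for (nm in setdiff(names(config), "tpsPaths"))
    log <- .logLine(log, "  ", nm, " = ",
                    paste(deparse(config[[nm]]), collapse = ""))
  for (nm in names(config$tpsPaths))
    log <- .logLine(log, "  tps[", nm, "] = ", config$tpsPaths[[nm]])

  tree <- readTimeTree(config$treePath, config$treeDialect)
  groups <- readGroupTable(config$groupPath)

  # aggregated cross-consistency report
  problems <- character(0)
  xc <- withCallingHandlers(
    checkGroupsAgainstTree(groups, tree),
    warning = function(w) {
      problems <<- c(problems, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (length(xc$missing_from_table))
    stop("cross-consistency failure:\n  ",
         paste(problems, collapse = "\n  "))

  tipStates <- groupFeedingTypes(groups)[tree@phy$tip.label]
  feedRec <- fitchSankoff(tree, tipStates,
                          states = groups@feedingVocabulary)

  results <- list()
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  for (chName in names(config$tpsPaths)) {
    log <- .logLine(log, "character '", chName, "'")
    records <- readTPS(config$tpsPaths[[chName]], characterName = chName)
    rc <- config$resampleCounts[[chName]]
    cfgs <- specimensToConfigs(records, resampleCounts = rc)
    aligned <- gpaAlign(cfgs$configs)
    log <- .logLine(log, "  ", length(records), " specimens, k = ",
                    cfgs$k, "; GPA ",
                    if (aligned@converged) "converged" else
                      "did not converge",
                    " in ", aligned@iterations, " iterations")
    ids <- rownames(tangentCoords(aligned))
    tb <- groups@table
    idx <- match(ids, tb$specimen_id)
    if (anyNA(idx))
      stop("cross-consistency failure: specimen(s) in ", chName,
           " TPS absent from group table: ",
           paste(ids[is.na(idx)], collapse = ", "))
    grpLab <- tb$terminal_group[idx]
    feedLab <- tb$feeding_type[idx]

    pcaRes <- shapePCA(aligned)
    cvaGroups <- shapeCVA(aligned, grpLab,
                          priorReduction = config$cvaReduction)
    if (length(unique(feedLab)) >= 2L) {
      cvaFeeding <- shapeCVA(aligned, feedLab,
                             priorReduction = config$cvaReduction)
      cmFeedResub <- classifyConfusion(cvaFeeding, aligned, feedLab,
                                       mode = "resubstitution")
      cmFeedLoo <- classifyConfusion(cvaFeeding, aligned, feedLab,
                                     mode = "leave_one_out")
    } else {
      cvaFeeding <- cmFeedResub <- cmFeedLoo <- NULL
      log <- .logLine(log, chName, ": single feeding type present; ",
                      "feeding-type CVA skipped")
    }

    means <- groupMeanShapes(aligned, groups)
    recon <- reconstructShapes(tree, means, weighting = config$weighting)
    edges <- edgeDeformations(tree, recon, distanceSpace = cvaGroups)
    sgr <- sgrAlongPaths(tree, edges, variant = config$drVariant)
    steps <- stepChartSeries(edges, tree, variant = config$drVariant)
    trend <- tryCatch(
      fitTrend(data.frame(age = sgr$midpoint_age, value = sgr$sgr),
               method = config$trendMethod,
               degree = config$trendDegree),
      error = function(e) NULL)

    emit(data.frame(specimen_id = ids, grpLab, feedLab,
                    round(tangentCoords(aligned), 10)),
         paste0(chName, "_aligned.csv"))
    emit(data.frame(specimen_id = ids,
                    round(pcaRes@scores[, seq_len(min(10L,
                      ncol(pcaRes@scores))), drop = FALSE], 10)),
         paste0(chName, "_pca_scores.csv"))
    emit(as.data.frame(cvaGroups@mahalanobis),
         paste0(chName, "_mahalanobis_groups.csv"))
    if (!is.null(cmFeedLoo))
      emit(as.data.frame(cmFeedLoo@counts),
           paste0(chName, "_confusion_feeding_loo.csv"))
    emit(edges, paste0(chName, "_edges.csv"))
    emit(sgr, paste0(chName, "_sgr.csv"))
    emit(steps, paste0(chName, "_steps.csv"))
    p <- file.path(config$outDir, paste0(chName, "_summary.json"))
    jsonlite::write_json(list(
      character = chName, k = cfgs$k, n_specimens = length(ids),
      pc1_variance = pcaRes@varianceExplained[1L],
      confusion_feeding = if (!is.null(cmFeedLoo)) list(
        resubstitution = cmFeedResub@totalCorrect,
        leave_one_out = cmFeedLoo@totalCorrect) else NULL,
      trend = if (!is.null(trend))
        list(method = trend$method,
             coefficients = trend$coefficients) else NULL
    ), p, digits = NA, auto_unbox = TRUE)
    files <- c(files, p)

    results[[chName]] <- list(
      aligned = aligned, pca = pcaRes, cvaGroups = cvaGroups,
      cvaFeeding = cvaFeeding,
      confusionFeeding = list(resubstitution = cmFeedResub,
                              leave_one_out = cmFeedLoo),
      meanShapes = means, nodeShapes = recon, edges = edges,
      sgr = sgr, steps = steps, trend = trend)
  }

  sgrTables <- lapply(results, `[[`, "sgr")
  windows <- NULL
  if (length(config$sgrWindows)) {
    windows <- sgrWindowSummary(sgrTables, config$sgrWindows)
    emit(windows, "sgr_window_summary.csv")
  }
  feedDf <- data.frame(
    node = names(feedRec@stateSets),
    states = vapply(feedRec@stateSets, paste, "", collapse = "|"),
    stringsAsFactors = FALSE)
  emit(feedDf, "ancestral_feeding_types.csv")

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(config$outDir, "manifest.csv"),
                   row.names = FALSE)
  log <- .logLine(log, "wrote ", length(files), " artifacts")
  writeLines(log, file.path(config$outDir, "run.log"))

  invisible(list(characters = results, tree = tree, groups = groups,
                 feedingReconstruction = feedRec, windows = windows,
                 manifest = manifest, outDir = config$outDir))
}

#' Per-window SGR spread summary
#'
#' For each age window and character, summarizes the SGR values whose edge
#' midpoint age falls inside the window: maximum, minimum and spread
#' (max - min). Edges shared by several root-to-tip paths are counted
#' once. Characters can then be ranked by spread within a window.
#'
#' @param sgrTables named list (character -> SGR table from
#'   \code{\link{sgrAlongPaths}}).
#' @param windows list of \code{c(lo, hi)} age bounds in Ma.
#' @return data.frame with columns \code{window_lo}, \code{window_hi},
#'   \code{character}, \code{n}, \code{max}, \code{min}, \code{spread}.
#' @export
sgrWindowSummary <- function(sgrTables, windows) {
  out <- list()
  for (w in windows) {
    for (chName in names(sgrTables)) {
      tb <- sgrTables[[chName]]
      tb <- tb[!duplicated(paste(tb$parent, tb$child)), ]
      sel <- tb$sgr[tb$midpoint_age >= w[1L] & tb$midpoint_age <= w[2L] &
                    is.finite(tb$sgr)]
      if (!length(sel)) {
        warning("empty SGR window [", w[1L], ", ", w[2L], "] for ",
                chName)
        row <- data.frame(window_lo = w[1L], window_hi = w[2L],
                          character = chName, n = 0L, max = NA_real_,
                          min = NA_real_, spread = NA_real_)
      } else {
        row <- data.frame(window_lo = w[1L], window_hi = w[2L],
                          character = chName, n = length(sel),
                          max = max(sel), min = min(sel),
                          spread = max(sel) - min(sel))
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$window_lo, -res$spread), ]
}
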