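#' @include AllClasses.R
NULL

#' Construct a SpecimenRecord
#'
#' @param specimenID unique specimen identifier.
#' @param characterName name of the morphological character.
#' @param curves list of 2-column coordinate matrices (open polylines).
#' @param landmarks 2-column matrix of fixed landmarks.
#' @param taxon optional taxon name.
#' @param scale optional positive scale factor (units per pixel).
#' @param imageRef optional image file reference.
#' @param metadata character vector of opaque metadata lines.
#' @return a validated \code{SpecimenRecord}.
#' @export
SpecimenRecord <- function(specimenID, characterName, curves = list(),
                           landmarks = matrix(numeric(0), ncol = 2),
                           taxon = NA_character_, scale = NA_real_,
                           imageRef = NA_character_,
                           metadata = character(0)) {
  curves <- lapply(curves, function(cv) {
    cv <- as.matrix(cv)
    storage.mode(cv) <- "double"
    dimnames(cv) <- NULL
    cv
  })
  landmarks <- as.matrix(landmarks)
  storage.mode(landmarks) <- "double"
  dimnames(landmarks) <- NULL
  new("SpecimenRecord", specimenID = as.character(specimenID),
      characterName = as.character(characterName), curves = curves,
      landmarks = landmarks, taxon = as.character(taxon),
      scale = as.numeric(scale), imageRef = as.character(imageRef),
      metadata = as.character(metadata))
}

.parseCoordLine <- function(line, path, lineno) {
  parts <- strsplit(trimws(line), "[ \t]+")[[1L]]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) != 2L || anyNA(vals))
    stop("TPS parse error at ", path, ":", lineno,
         ": expected 'x y' coordinate pair, got '", line, "'")
  vals
}

#' Read a TPS landmark/curve file
#'
#' Parses the tps-Dig dialect: blocks beginning with \code{LM=} containing
#' fixed landmarks and, optionally, \code{CURVES=}/\code{POINTS=} outline
#' sections, followed by \code{IMAGE=}, \code{ID=}, \code{SCALE=} and
#' \code{COMMENT=} lines. Coordinates use the TPS y-up convention and are
#' kept raw: \code{SCALE=} is recorded but only applied when
#' \code{applyScale = TRUE} (size is removed later by Procrustes
#' superimposition anyway).
#'
#' @param path path to the TPS file.
#' @param characterName character name stored on every record.
#' @param applyScale multiply coordinates by the block's SCALE factor.
#' @return list of \code{SpecimenRecord}, one per TPS block (empty list for
#'   an empty file).
#' @export
readTPS <- function(path, characterName = "character1",
                    applyScale = FALSE) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  i <- 1L
  n <- length(lines)
  blockIndex <- 0L

  readPoints <- function(count, i) {
    pts <- matrix(NA_real_, nrow = count, ncol = 2L)
    for (j in seq_len(count)) {
      if (i > n)
        stop("TPS parse error at ", path, ":", n,
             ": file ends inside a coordinate block")
      pts[j, ] <- .parseCoordLine(lines[i], path, i)
      i <- i + 1L
    }
    list(pts = pts, i = i)
  }

  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    m <- regmatches(lines[i], regexec("^LM=([0-9]+)\\s*$", lines[i]))[[1L]]
    if (length(m) == 0L)
      stop("TPS parse error at ", path, ":", i,
           ": expected 'LM=<count>' block header, got '", lines[i], "'")
    blockIndex <- blockIndex + 1L
    nlm <- as.integer(m[2L])
    i <- i + 1L
    got <- readPoints(nlm, i)
    landmarks <- got$pts
    i <- got$i

    curves <- list()
    id <- NULL; scale <- NA_real_; image <- NA_character_
    meta <- character(0)
    while (i <= n && !grepl("^LM=", lines[i])) {
      line <- lines[i]
      if (!nzchar(trimws(line))) { i <- i + 1L; next }
      if (grepl("^CURVES=", line)) {
        ncurves <- suppressWarnings(as.integer(sub("^CURVES=", "", line)))
        if (is.na(ncurves))
          stop("TPS parse error at ", path, ":", i, ": bad CURVES= line")
        i <- i + 1L
        for (ci in seq_len(ncurves)) {
          if (i > n || !grepl("^POINTS=", lines[i]))
            stop("TPS parse error at ", path, ":", min(i, n),
                 ": expected 'POINTS=' header for curve ", ci)
          np <- suppressWarnings(as.integer(sub("^POINTS=", "", lines[i])))
          if (is.na(np))
            stop("TPS parse error at ", path, ":", i, ": bad POINTS= line")
          i <- i + 1L
          got <- readPoints(np, i)
          curves[[ci]] <- got$pts
          i <- got$i
        }
      } else if (grepl("^ID=", line)) {
        id <- sub("^ID=", "", line); i <- i + 1L
      } else if (grepl("^IMAGE=", line)) {
        image <- sub("^IMAGE=", "", line); i <- i + 1L
      } else if (grepl("^SCALE=", line)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE=", "", line)))
        if (is.na(scale))
          stop("TPS parse error at ", path, ":", i, ": bad SCALE= line")
        i <- i + 1L
      } else if (grepl("^[A-Z]+=", line)) {
        meta <- c(meta, line); i <- i + 1L  # opaque keyword (COMMENT= etc.)
      } else {
        stop("TPS parse error at ", path, ":", i,
             ": unexpected line '", line, "'")
      }
    }
    if (is.null(id)) id <- paste0("specimen_", blockIndex)
    if (applyScale && !is.na(scale)) {
      landmarks <- landmarks * scale
      curves <- lapply(curves, function(cv) cv * scale)
    }
    records[[blockIndex]] <- SpecimenRecord(
      specimenID = id, characterName = characterName, curves = curves,
      landmarks = landmarks, scale = scale, imageRef = image,
      metadata = meta)
  }

  ids <- vapply(records, function(r) r@specimenID, "")
  if (anyDuplicated(ids))
    stop("TPS validation error: duplicate specimen id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  nlms <- vapply(records, function(r) nrow(r@landmarks), 1L)
  if (length(unique(nlms)) > 1L)
    stop("TPS validation error: landmark count differs across blocks (",
         paste(unique(nlms), collapse = ", "), ")")
  records
}

#' Write SpecimenRecords as a TPS file
#'
#' Inverse of \code{\link{readTPS}}: coordinates are written to 6 decimal
#' places, so \code{readTPS(writeTPS(R))} recovers \code{R} up to that
#' precision (ids, scale and metadata exactly).
#'
#' @param records list of \code{SpecimenRecord}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTPS <- function(records, path) {
  fmt <- function(pts)
    apply(pts, 1L, function(p) sprintf("%.6f %.6f", p[1L], p[2L]))
  out <- character(0)
  for (r in records) {
    out <- c(out, sprintf("LM=%d", nrow(r@landmarks)))
    if (nrow(r@landmarks)) out <- c(out, fmt(r@landmarks))
    if (length(r@curves)) {
      out <- c(out, sprintf("CURVES=%d", length(r@curves)))
      for (cv in r@curves)
        out <- c(out, sprintf("POINTS=%d", nrow(cv)), fmt(cv))
    }
    if (!is.na(r@imageRef)) out <- c(out, paste0("IMAGE=", r@imageRef))
    out <- c(out, paste0("ID=", r@specimenID))
    if (!is.na(r@scale)) out <- c(out, sprintf("SCALE=%.6f", r@scale))
    out <- c(out, r@metadata)
  }
  tryCatch(writeLines(out, path),
           error = function(e) stop("cannot write TPS file ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
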