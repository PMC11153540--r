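#' @include AllClasses.R
NULL

#' Construct a GroupTable
#'
#' @param table data.frame with columns \code{specimen_id},
#'   \code{terminal_group}, \code{feeding_type}.
#' @param feedingVocabulary admissible feeding-type tokens; the default is
#'   the scarab vocabulary plus \code{"other"}.
#' @return a validated \code{GroupTable}.
#' @export
GroupTable <- function(table,
                       feedingVocabulary = c("omnivory", "coprophagy",
                                             "phytophagy", "other")) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  for (cl in c("specimen_id", "terminal_group", "feeding_type"))
    if (cl %in% names(table)) table[[cl]] <- as.character(table[[cl]])
  new("GroupTable", table = table,
      feedingVocabulary = as.character(feedingVocabulary))
}

#' Read a specimen-to-group CSV table
#'
#' @param path CSV file with header columns \code{specimen_id},
#'   \code{terminal_group}, \code{feeding_type} (UTF-8).
#' @param feedingVocabulary admissible feeding-type tokens.
#' @return a validated \code{GroupTable}.
#' @export
readGroupTable <- function(path,
                           feedingVocabulary = c("omnivory", "coprophagy",
                                                 "phytophagy", "other")) {
  if (!file.exists(path)) stop("group table not found: ", path)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("specimen_id", "terminal_group", "feeding_type")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("group table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  GroupTable(tb[need], feedingVocabulary)
}

#' Feeding type of each terminal group
#'
#' @param groups a \code{GroupTable}.
#' @return named character vector, terminal_group -> feeding_type.
#' @export
groupFeedingTypes <- function(groups) {
  stopifnot(is(groups, "GroupTable"))
  tb <- groups@table
  vapply(split(tb$feeding_type, tb$terminal_group), `[[`, "", 1L)
}

#' Cross-check groups against tree terminals
#'
#' Warns about terminal groups absent from the tree and tree tips absent
#' from the table; returns the discrepancies invisibly.
#'
#' @param groups a \code{GroupTable}.
#' @param tree a \code{TimeTree}.
#' @return invisible list with elements \code{missing_from_tree} and
#'   \code{missing_from_table}.
#' @export
checkGroupsAgainstTree <- function(groups, tree) {
  stopifnot(is(groups, "GroupTable"), is(tree, "TimeTree"))
  gg <- unique(groups@table$terminal_group)
  tips <- tree@phy$tip.label
  mt <- setdiff(gg, tips)
  mg <- setdiff(tips, gg)
  if (length(mt))
    warning("terminal group(s) absent from tree tips: ",
            paste(mt, collapse = ", "))
  if (length(mg))
    warning("tree tip(s) absent from group table: ",
            paste(mg, collapse = ", "))
  invisible(list(missing_from_tree = mt, missing_from_table = mg))
}
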