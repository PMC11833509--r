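#' Construct a TMT channel design
#'
#' Describes a six-plex (or larger) TMT experiment in which each reporter
#' channel belongs to one of three groups: the bait proximity-labeling
#' condition (`TRT`), a membrane-anchored spatial reference (`SR`), or a
#' negative control with a required labeling reagent omitted (`NC`).  The
#' per-protein linear model treats `NC` as baseline and `TRT`/`SR` as
#' indicator variables.
#'
#' @param channels character vector of unique channel labels
#'   (e.g. `c("126","127N",...)`).
#' @param groups character vector, same length, each one of
#'   `"TRT"`, `"SR"`, `"NC"`.
#' @param replicates optional integer replicate index per channel; defaults
#'   to 1..k within each group.
#' @return An object of class `tmt_design`: a data.frame with columns
#'   `channel`, `group`, `replicate`.
#' @examples
#' tmt_design(c("126","127","128","129","130","131"),
#'            c("TRT","TRT","SR","SR","NC","NC"))
#' @export
tmt_design <- function(channels, groups, replicates = NULL) {
  channels <- as.character(channels)
  groups <- as.character(groups)
  if (length(channels) != length(groups))
    stop("channels and groups must have equal length")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  bad <- setdiff(unique(groups), c("TRT", "SR", "NC"))
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "))
  missing_grp <- setdiff(c("TRT", "SR", "NC"), groups)
  if (length(missing_grp))
    stop("every group must have at least one channel; missing: ",
         paste(missing_grp, collapse = ", "))
  if (length(channels) - 3L < 1L)
    stop("design leaves no residual degrees of freedom (need > 3 channels)")
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  }
  d <- data.frame(channel = channels, group = groups,
                  replicate = as.integer(replicates),
                  stringsAsFactors = FALSE)
  class(d) <- c("tmt_design", "data.frame")
  d
}

#' Read a TMT design from a YAML file
#'
#' The file maps channel labels to groups, e.g.
#' \preformatted{
#' channels:
#'   "126": TRT
#'   "127": TRT
#'   "128": SR
#'   "129": SR
#'   "130": NC
#'   "131": NC
#' }
#'
#' @param path path to a YAML design file.
#' @return A [tmt_design()] object.
#' @export
read_tmt_design <- function(path) {
  y <- yaml::read_yaml(path)
  ch <- y$channels
  if (is.null(ch)) stop("design file must contain a 'channels' map")
  tmt_design(names(ch), unname(unlist(ch)))
}

#' Model matrix for a TMT design
#'
#' Columns: intercept, TRT indicator, SR indicator (NC is baseline).
#'
#' @param design a [tmt_design()] object.
#' @return numeric matrix, one row per channel.
#' @export
design_matrix <- function(design) {
  stopifnot(inherits(design, "tmt_design"))
  X <- cbind(intercept = 1,
             TRT = as.numeric(design$group == "TRT"),
             SR = as.numeric(design$group == "SR"))
  rownames(X) <- design$channel
  X
}
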