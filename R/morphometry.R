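#' Identify the stem axon of a traced neuron
#'
#' The stem axon is the thickest root-to-leaf path: among all root-to-leaf
#' paths, the one maximizing the path-length-weighted mean radius (each
#' edge weighted by its length, radius taken as the mean of its two
#' endpoint radii).  Ties are broken by greater geodesic length, then by
#' lexicographic leaf id.
#'
#' @param tree a [neurite_tree()].
#' @return integer vector of node row indices, root first.
#' @export
identify_stem_axon <- function(tree) {
  if (nrow(tree$nodes) < 2L)
    stop("single-node tree: no path to identify")
  leaves <- tree_leaves(tree)
  best <- NULL
  best_score <- -Inf
  best_len <- -Inf
  best_leaf_id <- ""
  r <- tree$nodes$radius
  for (lf in leaves) {
    p <- path_to_root(tree, lf)
    seg_len <- tree$edge_length[p[-1]]
    seg_rad <- (r[p[-1]] + r[p[-length(p)]]) / 2
    len <- sum(seg_len)
    score <- if (len > 0) sum(seg_len * seg_rad) / len else mean(r[p])
    leaf_id <- as.character(tree$nodes$id[lf])
    better <- score > best_score ||
      (score == best_score && (len > best_len ||
        (len == best_len && leaf_id < best_leaf_id)))
    if (better) {
      best <- p; best_score <- score; best_len <- len; best_leaf_id <- leaf_id
    }
  }
  best
}

#' Locate the antennal lobe entry point and stem end point
#'
#' The entry point is the first stem node (in root-to-tip order) inside
#' the antennal lobe region; the end point is the stem node at maximal
#' geodesic distance along the stem from the entry point, and the stem
#' length is that distance.
#'
#' @param tree a [neurite_tree()].
#' @param stem_path row indices from [identify_stem_axon()].
#' @param regions a [region_set()] (only `antennal_lobe` is used).
#' @return object of class `stem_annotation`: list with `stem_path`,
#'   `entry_row`, `end_row`, `entry_node`, `end_node` (SWC ids),
#'   `stem_length` (um), and `arc` (per-stem-node geodesic position from
#'   the entry point, negative on the root side).
#' @export
locate_entry_and_end <- function(tree, stem_path, regions) {
  pts <- node_coords(tree, stem_path)
  inside <- region_contains(regions$antennal_lobe, pts)
  if (!any(inside))
    stop("no stem node lies inside the antennal lobe region")
  entry_i <- which(inside)[1]
  cum <- c(0, cumsum(tree$edge_length[stem_path[-1]]))
  arc <- cum - cum[entry_i]
  # the end point is the farthest *distal* stem node; if the stem meets the
  # lobe only at its tip, entry and end coincide and the stem length is 0
  end_i <- which.max(arc)
  structure(list(stem_path = stem_path,
                 entry_row = stem_path[entry_i],
                 end_row = stem_path[end_i],
                 entry_node = tree$nodes$id[stem_path[entry_i]],
                 end_node = tree$nodes$id[stem_path[end_i]],
                 stem_length = arc[end_i],
                 arc = arc),
            class = "stem_annotation")
}

#' @export
print.stem_annotation <- function(x, ...) {
  cat(sprintf(
    "stem_annotation: %d stem nodes, entry id %d, end id %d, length %.1f um\n",
    length(x$stem_path), x$entry_node, x$end_node, x$stem_length))
  invisible(x)
}

#' Classify the developmental stage from stem axon length
#'
#' Stage 1: stem axon length < 100 um (usually before midline crossing);
#' stage 2: 100-170 um (crossed the midline, not yet at contralateral PN
#' dendrites); stage 3: > 170 um.  The middle interval is closed on both
#' ends so the three intervals partition the line.
#'
#' @param stem_length stem axon length (um), vectorized.
#' @param thresholds length-2 numeric `(t1, t2)`, default `c(100, 170)`.
#' @return integer stage(s) in `1:3`.
#' @export
classify_stage <- function(stem_length, thresholds = c(100, 170)) {
  stopifnot(all(stem_length >= 0), thresholds[1] < thresholds[2])
  ifelse(stem_length < thresholds[1], 1L,
         ifelse(stem_length <= thresholds[2], 2L, 3L))
}

#' Extract primary branches off the stem axon
#'
#' Every stem node with at least one off-stem child yields one record per
#' collateral child subtree.  The branch position is normalized along the
#' stem with the antennal lobe entry point at 0 and the end point at 1;
#' branch points proximal to the entry point fall outside \[0, 1\] and are
#' excluded (recorded in the `excluded` attribute).  A branch contacts the
#' PN dendrites when any node of its collateral subtree lies inside the PN
#' region (point-cloud regions carry their contact tolerance).  A primary
#' branch with at least one secondary branch (an internal branch point in
#' the collateral subtree) is multifurcated.
#'
#' @param tree a [neurite_tree()].
#' @param stem a [locate_entry_and_end()] annotation.
#' @param regions a [region_set()]; `pn_dendrites` may be NULL (contact
#'   calls become NA), `midline` may be NULL (side becomes NA).
#' @return data.frame of class `branch_records`: `branch_point_node`,
#'   `child_node` (SWC ids), `normalized_position`, `order`,
#'   `contacts_pn`, `multifurcated`, `n_secondary`, `side`.
#' @export
extract_primary_branches <- function(tree, stem, regions) {
  if (stem$stem_length <= 0)
    stop("zero-length stem: normalized positions undefined")
  on_stem <- rep(FALSE, nrow(tree$nodes))
  on_stem[stem$stem_path] <- TRUE
  recs <- list()
  excluded <- list()
  for (i in seq_along(stem$stem_path)) {
    row <- stem$stem_path[i]
    for (ch in child_rows(tree, row)) {
      if (on_stem[ch]) next
      pos <- stem$arc[i] / stem$stem_length
      sub <- subtree_rows(tree, ch)
      contacts <- if (is.null(regions$pn_dendrites)) NA else
        any(region_contains(regions$pn_dendrites, node_coords(tree, sub)))
      # one secondary branch per extra child at any node inside the subtree
      nsec <- sum(vapply(sub, function(r) {
        max(0L, length(child_rows(tree, r)) - 1L)
      }, integer(1)))
      side <- NA_character_
      if (!is.null(regions$midline)) {
        bp <- node_coords(tree, row)
        root_side <- sum((node_coords(tree, tree$root) -
                            regions$midline$point) * regions$midline$normal)
        this_side <- sum((bp - regions$midline$point) * regions$midline$normal)
        side <- if (sign(this_side) == sign(root_side) || this_side == 0)
          "ipsilateral" else "contralateral"
      }
      rec <- data.frame(branch_point_node = tree$nodes$id[row],
                        child_node = tree$nodes$id[ch],
                        normalized_position = pos,
                        order = "primary",
                        contacts_pn = contacts,
                        multifurcated = nsec >= 1L,
                        n_secondary = nsec,
                        side = side,
                        stringsAsFactors = FALSE)
      if (pos < 0 || pos > 1) excluded[[length(excluded) + 1L]] <- rec
      else recs[[length(recs) + 1L]] <- rec
    }
  }
  empty <- data.frame(branch_point_node = integer(), child_node = integer(),
                      normalized_position = numeric(), order = character(),
                      contacts_pn = logical(), multifurcated = logical(),
                      n_secondary = integer(), side = character(),
                      stringsAsFactors = FALSE)
  out <- if (length(recs)) do.call(rbind, recs) else empty
  rownames(out) <- NULL
  class(out) <- c("branch_records", "data.frame")
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
                           else empty
  out
}

#' Summary statistics over a set of primary branches
#'
#' @param records a [extract_primary_branches()] data.frame.
#' @param stem the matching [locate_entry_and_end()] annotation.
#' @param bins number of histogram bins over the normalized \[0, 1\] stem
#'   axis (default 20).
#' @return list of class `branch_summary`: `branch_density` (primaries per
#'   um of stem), `total_branches`, `contacting_fraction`,
#'   `multifurcated_contacting_fraction` (among multifurcated primaries),
#'   `n_secondary_contacting` (secondary branches carried by contacting
#'   primaries), `position_histogram` (counts; breaks as attribute), and
#'   per-side branch densities (`branch_density_by_side`).
#' @export
branch_statistics <- function(records, stem, bins = 20L) {
  n <- nrow(records)
  dens <- n / stem$stem_length
  contacting <- records$contacts_pn
  multif <- records$multifurcated
  cf <- if (n > 0 && !all(is.na(contacting))) mean(contacting) else NA_real_
  mcf <- if (any(multif) && !all(is.na(contacting)))
    mean(contacting[multif]) else NA_real_
  nsec_c <- if (n > 0 && !all(is.na(contacting)))
    sum(records$n_secondary[contacting %in% TRUE]) else NA_integer_
  breaks <- seq(0, 1, length.out = bins + 1L)
  h <- if (n > 0) {
    graphics::hist(records$normalized_position, breaks = breaks, plot = FALSE,
                   include.lowest = TRUE, right = TRUE)$counts
  } else integer(bins)
  attr(h, "breaks") <- breaks
  by_side <- if (n > 0 && !all(is.na(records$side))) {
    tab <- table(factor(records$side,
                        levels = c("ipsilateral", "contralateral")))
    as.numeric(tab) / stem$stem_length
  } else c(NA_real_, NA_real_)
  names(by_side) <- c("ipsilateral", "contralateral")
  structure(list(branch_density = dens,
                 total_branches = n,
                 contacting_fraction = cf,
                 multifurcated_contacting_fraction = mcf,
                 n_secondary_contacting = nsec_c,
                 position_histogram = h,
                 branch_density_by_side = by_side,
                 stem_length = stem$stem_length),
            class = "branch_summary")
}

#' Full morphometry of one traced axon
#'
#' Convenience wrapper: stem identification, entry/end location, stage
#' classification, primary-branch extraction and summary statistics.
#'
#' @param tree a [neurite_tree()].
#' @param regions a [region_set()].
#' @param bins histogram bins for [branch_statistics()].
#' @param stage_thresholds passed to [classify_stage()].
#' @return list of class `axon_morphometry` with `stem`, `stage`,
#'   `records`, `summary`.
#' @export
axon_morphometry <- function(tree, regions, bins = 20L,
                             stage_thresholds = c(100, 170)) {
  sp <- identify_stem_axon(tree)
  stem <- locate_entry_and_end(tree, sp, regions)
  stage <- classify_stage(stem$stem_length, stage_thresholds)
  records <- extract_primary_branches(tree, stem, regions)
  summ <- branch_statistics(records, stem, bins)
  structure(list(stem = stem, stage = stage, records = records,
                 summary = summ),
            class = "axon_morphometry")
}

#' @export
print.axon_morphometry <- function(x, ...) {
  cat(sprintf("axon_morphometry: stage %d, stem %.1f um, %d primary branches (density %.3f /um)\n",
              x$stage, x$stem$stem_length, x$summary$total_branches,
              x$summary$branch_density))
  invisible(x)
}
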