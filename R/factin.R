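#' Sample an intensity field along a traced neuron
#'
#' For each tree node, the field is sampled as the mean over voxels within
#' a sphere of `radius_vox` voxels (in voxel index space, matching the
#' line-profile tool convention on possibly anisotropic grids) centered on
#' the node's voxel.  `radius_vox = 0` is a nearest-voxel lookup.  Nodes
#' whose center voxel falls outside the field are marked missing and are
#' excluded from downstream normalization.
#'
#' @param tree a [neurite_tree()].
#' @param field a [labeled_volume()] co-registered with the trace (grid
#'   corner at `origin`).
#' @param radius_vox sphere radius in voxels (default 1).
#' @param origin physical coordinate of the field's grid corner (um).
#' @return data.frame: `node` (SWC id), `raw` (sampled intensity, NA when
#'   missing), `missing` (logical).
#' @export
sample_along_trace <- function(tree, field, radius_vox = 1L,
                               origin = c(0, 0, 0)) {
  stopifnot(inherits(field, "labeled_volume"), radius_vox >= 0)
  d <- dim(field$voxels)
  pts <- node_coords(tree)
  ijk <- sweep(sweep(pts, 2L, origin), 2L, field$voxel_size, `/`)
  ijk <- floor(ijk) + 1L
  r <- as.integer(radius_vox)
  offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  offs <- offs[rowSums(offs^2) <= r^2, , drop = FALSE]
  raw <- rep(NA_real_, nrow(pts))
  missing <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    c0 <- ijk[i, ]
    if (any(c0 < 1L) || any(c0 > d)) {
      missing[i] <- TRUE
      next
    }
    nb <- sweep(offs, 2L, c0, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- (nb[, 3] - 1) * d[1] * d[2] + (nb[, 2] - 1) * d[1] + nb[, 1]
    raw[i] <- mean(field$voxels[lin])
  }
  data.frame(node = tree$nodes$id, raw = raw, missing = missing)
}

#' Min-max normalize a sampled intensity profile per axon
#'
#' Each node is normalized against the maximum and minimum sampled
#' intensities of the axon: the maximum maps to 1 and the minimum to 0.
#' Missing samples stay missing and do not inform the extremes.
#'
#' @param samples a [sample_along_trace()] data.frame.
#' @param axon_id identifier stored in the profile.
#' @return data.frame of class `factin_profile`: `node`, `raw`,
#'   `normalized`, `missing`.
#' @export
normalize_profile <- function(samples, axon_id = "") {
  v <- samples$raw[!samples$missing & !is.na(samples$raw)]
  if (length(unique(v)) < 2L)
    stop("degenerate profile: fewer than 2 distinct sample values")
  lo <- min(v); hi <- max(v)
  out <- samples
  out$normalized <- (samples$raw - lo) / (hi - lo)
  class(out) <- c("factin_profile", "data.frame")
  attr(out, "axon_id") <- axon_id
  attr(out, "range") <- c(lo, hi)
  out
}

#' F-actin density of a trace segment
#'
#' Divides the total normalized signal of a segment by its length.  The
#' default reading of "total signal" is the trapezoidal arc-length
#' integral of the normalized profile over the segment (invariant to
#' trace resampling); dividing by segment length gives the
#' arc-length-weighted mean normalized intensity.  `method = "node_sum"`
#' instead sums the node values and divides by the length.
#'
#' @param profile a [normalize_profile()] result for the same tree.
#' @param tree the [neurite_tree()].
#' @param path integer vector of node row indices forming a contiguous
#'   path (each consecutive pair parent-child in either direction).
#' @param method `"integral"` (default) or `"node_sum"`.
#' @return list of class `segment_density`: `density`, `length`, `n_nodes`.
#' @export
segment_density <- function(profile, tree, path,
                            method = c("integral", "node_sum")) {
  method <- match.arg(method)
  v <- profile$normalized[match(tree$nodes$id[path], profile$node)]
  if (anyNA(v)) {
    keep <- !is.na(v)
    path <- path[keep]
    v <- v[keep]
  }
  if (length(path) < 2L) stop("segment needs at least 2 sampled nodes")
  pts <- node_coords(tree, path)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  len <- sum(seg)
  if (len <= 0) stop("zero-length segment")
  dens <- if (method == "integral") {
    sum(0.5 * (v[-1] + v[-length(v)]) * seg) / len
  } else {
    sum(v) / len
  }
  structure(list(density = dens, length = len, n_nodes = length(path)),
            class = "segment_density")
}

# density over an arbitrary set of tree edges (child rows), trapezoid rule
edge_set_density <- function(profile, tree, child_edge_rows,
                             method = "integral") {
  v <- profile$normalized[match(tree$nodes$id, profile$node)]
  par <- tree$parent_idx[child_edge_rows]
  ok <- !is.na(v[child_edge_rows]) & !is.na(v[par])
  ce <- child_edge_rows[ok]
  if (!length(ce)) return(NULL)
  seg <- tree$edge_length[ce]
  len <- sum(seg)
  if (len <= 0) return(NULL)
  dens <- if (method == "integral") {
    sum(0.5 * (v[ce] + v[tree$parent_idx[ce]]) * seg) / len
  } else {
    sum(v[unique(c(ce, tree$parent_idx[ce]))]) / len
  }
  list(density = dens, length = len)
}

#' Per-branch F-actin densities with contact partitioning
#'
#' For every primary branch of an axon, computes the whole-branch density
#' (all edges of the collateral subtree) and, when a PN dendrite region is
#' given, the densities of the PN-contacting (`plus`) and non-contacting
#' (`minus`) sub-segments.  An edge is assigned to the class of its child
#' node (inside/outside the PN region), so sub-segment lengths sum exactly
#' to the branch length.
#'
#' @param tree a [neurite_tree()].
#' @param profile a [normalize_profile()] result.
#' @param records a [extract_primary_branches()] data.frame.
#' @param pn_region the PN dendrite `region` (or NULL to skip the split).
#' @param method passed to the density rule (`"integral"`/`"node_sum"`).
#' @return data.frame of class `branch_densities`: `branch_point_node`,
#'   `child_node`, `contacts_pn`, `length`, `density_whole`,
#'   `density_plus`, `density_minus` (NA when a class has no edges).
#' @export
branch_densities <- function(tree, profile, records, pn_region = NULL,
                             method = "integral") {
  out <- records[, c("branch_point_node", "child_node", "contacts_pn")]
  out$length <- NA_real_
  out$density_whole <- NA_real_
  out$density_plus <- NA_real_
  out$density_minus <- NA_real_
  in_pn <- if (is.null(pn_region)) rep(FALSE, nrow(tree$nodes)) else
    region_contains(pn_region, node_coords(tree))
  for (i in seq_len(nrow(records))) {
    ch <- match(records$child_node[i], tree$nodes$id)
    sub <- subtree_rows(tree, ch)     # child rows of all subtree edges
    whole <- edge_set_density(profile, tree, sub, method)
    if (is.null(whole)) next
    out$length[i] <- whole$length
    out$density_whole[i] <- whole$density
    if (!is.null(pn_region)) {
      plus <- edge_set_density(profile, tree, sub[in_pn[sub]], method)
      minus <- edge_set_density(profile, tree, sub[!in_pn[sub]], method)
      if (!is.null(plus)) out$density_plus[i] <- plus$density
      if (!is.null(minus)) out$density_minus[i] <- minus$density
    }
  }
  class(out) <- c("branch_densities", "data.frame")
  out
}

#' Compare F-actin densities between and within branches
#'
#' Between branches: contacting versus non-contacting whole-branch
#' densities by the Mann-Whitney U test.  Within branches: for contacting
#' primary branches carrying both a PN-contacting (`plus`) and a
#' non-contacting (`minus`) sub-segment, a paired t test on the per-branch
#' (plus, minus) density pairs.  Zero-variance paired differences with a
#' nonzero mean are reported as p = 0 with a degeneracy warning.
#'
#' @param dens a [branch_densities()] data.frame (rows may come from many
#'   axons; axons should be at developmental stage 3).
#' @return list of class `factin_comparison` with `between`
#'   (Mann-Whitney: statistic, p, group sizes; NULL with a notice when a
#'   class is empty) and `within` (paired t: statistic, p, n pairs,
#'   mean difference; NULL when no usable pairs).
#' @export
factin_compare <- function(dens) {
  between <- NULL
  ok <- !is.na(dens$density_whole) & !is.na(dens$contacts_pn)
  x <- dens$density_whole[ok & dens$contacts_pn %in% TRUE]
  y <- dens$density_whole[ok & dens$contacts_pn %in% FALSE]
  if (length(x) && length(y)) {
    mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    between <- list(statistic = unname(mw$statistic), p = mw$p.value,
                    n_contacting = length(x), n_noncontacting = length(y),
                    median_contacting = stats::median(x),
                    median_noncontacting = stats::median(y))
  } else {
    message("between-branch comparison skipped: a class has no branches")
  }
  within <- NULL
  pair_ok <- dens$contacts_pn %in% TRUE & !is.na(dens$density_plus) &
    !is.na(dens$density_minus)
  if (sum(pair_ok) >= 2L) {
    dif <- dens$density_plus[pair_ok] - dens$density_minus[pair_ok]
    if (isTRUE(all.equal(stats::sd(dif), 0))) {
      if (mean(dif) != 0) {
        warning("zero-variance paired differences: p reported as 0")
        within <- list(statistic = sign(mean(dif)) * Inf, p = 0,
                       n_pairs = length(dif), mean_diff = mean(dif))
      } else {
        within <- list(statistic = 0, p = 1, n_pairs = length(dif),
                       mean_diff = 0)
      }
    } else {
      tt <- stats::t.test(dens$density_plus[pair_ok],
                          dens$density_minus[pair_ok], paired = TRUE)
      within <- list(statistic = unname(tt$statistic), p = tt$p.value,
                     n_pairs = length(dif), mean_diff = mean(dif))
    }
  }
  structure(list(between = between, within = within),
            class = "factin_comparison")
}

#' @export
print.factin_comparison <- function(x, ...) {
  cat("F-actin density comparison\n")
  if (!is.null(x$between))
    cat(sprintf("  between branches (Mann-Whitney): U = %.4g, p = %.3g (n = %d vs %d)\n",
                x$between$statistic, x$between$p, x$between$n_contacting,
                x$between$n_noncontacting))
  if (!is.null(x$within))
    cat(sprintf("  within branches (paired t): t = %.4g, p = %.3g (%d pairs, mean diff %.3f)\n",
                x$within$statistic, x$within$p, x$within$n_pairs,
                x$within$mean_diff))
  invisible(x)
}
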