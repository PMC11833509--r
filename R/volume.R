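#' Construct a labeled 3D volume
#'
#' A voxel grid with physical voxel size and a channel name.  Volumes are
#' the common currency of the volumetric indices and the intensity
#' profiler.
#'
#' @param voxels numeric 3D array.
#' @param voxel_size numeric length-3 vector (x, y, z) in micrometres.
#' @param channel channel name.
#' @return object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, voxel_size = c(1, 1, 1), channel = "") {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers")
  if (any(!is.finite(voxels))) stop("voxel values must be finite")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 channel = as.character(channel)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("labeled_volume '%s': %d x %d x %d voxels @ (%g, %g, %g) um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Label connected components of a 3D logical array
#'
#' 6- or 26-connectivity; components are found on a voxel adjacency graph
#' built from half-space neighbor offsets.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @return integer array of the same shape: 0 = background, 1..K component
#'   labels.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6, 26))
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  if (!length(fg)) return(lab)
  # half set of neighbor offsets (the other half is implied by symmetry)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    o[o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0))), ,
      drop = FALSE]
  }
  idx <- arrayInd(fg, d)
  vid <- integer(prod(d))
  vid[fg] <- seq_along(fg)        # dense vertex ids for foreground voxels
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2L, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- mask[lin]
    edges[[k]] <- cbind(vid[fg[ok][hit]], vid[lin[hit]])
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(fg)]
  lab[fg] <- as.integer(comp)
  lab
}

#' Otsu threshold of a volume
#'
#' Global histogram-based threshold maximizing between-class variance,
#' computed over all voxels.
#'
#' @param vol a [labeled_volume()] or numeric array.
#' @param levels histogram resolution.
#' @return scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(vol, levels = 256L) {
  x <- if (inherits(vol, "labeled_volume")) vol$voxels else vol
  r <- range(x)
  if (r[1] == r[2]) return(r[2])   # constant volume: threshold at the value
  im <- EBImage::Image(matrix(as.vector(x), ncol = 1))
  EBImage::otsu(im, range = r, levels = levels)
}

#' Segment a volume into a binary mask
#'
#' Thresholds the volume (fixed value or automatic Otsu) and removes
#' connected components smaller than `min_size` voxels.
#'
#' @param vol a [labeled_volume()].
#' @param threshold numeric threshold, or `"auto"` for Otsu.
#' @param min_size minimum component size in voxels (0 keeps everything).
#' @param connectivity 6 or 26 (default), used for component removal.
#' @return object of class `binary_mask`: logical array plus provenance
#'   (`source_channel`, `threshold_used`, `min_object_size`, `voxel_size`).
#' @export
segment_volume <- function(vol, threshold = "auto", min_size = 0L,
                           connectivity = 26) {
  stopifnot(inherits(vol, "labeled_volume"))
  auto <- identical(threshold, "auto")
  thr <- if (auto) otsu_threshold(vol) else as.numeric(threshold)
  # fixed thresholds are inclusive; the automatic threshold separates the
  # histogram strictly above it (so a constant volume segments to empty)
  m <- if (auto) vol$voxels > thr else vol$voxels >= thr
  if (min_size > 0 && any(m)) {
    lab <- label_components(m, connectivity)
    sz <- tabulate(lab[lab > 0L])
    keep <- which(sz >= min_size)
    m <- array(lab %in% keep, dim(m))
  }
  if (!any(m)) warning("segmentation produced an empty mask")
  binary_mask(m, source_channel = vol$channel, threshold_used = thr,
              min_object_size = min_size, voxel_size = vol$voxel_size)
}

#' Construct a binary mask
#'
#' @param voxels logical 3D array.
#' @param source_channel originating channel name.
#' @param threshold_used threshold that produced it (NA if constructed
#'   directly).
#' @param min_object_size minimum object size applied.
#' @param voxel_size voxel size in micrometres.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, source_channel = "", threshold_used = NA_real_,
                        min_object_size = 0L, voxel_size = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  structure(list(voxels = as.array(voxels == TRUE),
                 source_channel = source_channel,
                 threshold_used = threshold_used,
                 min_object_size = as.integer(min_object_size),
                 voxel_size = as.numeric(voxel_size)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary_mask (%s): %d x %d x %d, %d foreground voxels\n",
              x$source_channel, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}
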