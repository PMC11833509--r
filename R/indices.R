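#' Volumetric synaptic partner matching indices
#'
#' Voxel-overlap and intensity ratios quantifying axon-dendrite
#' coincidence in glomerular neuropil.  All three indices are ratios over
#' the same voxel grid, so voxel size cancels and values lie in \[0, 1\].
#'
#' @name volumetric_indices
NULL

as_mask_array <- function(m, arg) {
  v <- if (inherits(m, "binary_mask")) m$voxels else m
  if (length(dim(v)) != 3L) stop(arg, " must be a 3D mask")
  v == TRUE
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must share the same grid shape")
}

#' Match index: axon coverage of partner dendrites
#'
#' The ratio of the overlapping volume between the axon mask and the
#' dendrite mask to the total volume of the dendrite mask,
#' `|A n D| / |D|`, in voxel counts.
#'
#' @param axon,dendrite `binary_mask` objects (or logical 3D arrays) on
#'   the same grid.
#' @return scalar in \[0, 1\].
#' @export
match_index <- function(axon, dendrite) {
  a <- as_mask_array(axon, "axon")
  d <- as_mask_array(dendrite, "dendrite")
  check_same_grid(a, d)
  nd <- sum(d)
  if (nd == 0L) stop("empty dendrite mask: match index undefined")
  sum(a & d) / nd
}

#' Mismatch index: axon volume inside non-partner dendrites
#'
#' The ratio of the overlapping volume between the axon mask and the
#' dendrite mask to the total volume of the axon mask, `|A n D| / |A|`.
#'
#' @inheritParams match_index
#' @return scalar in \[0, 1\].
#' @export
mismatch_index <- function(axon, dendrite) {
  a <- as_mask_array(axon, "axon")
  d <- as_mask_array(dendrite, "dendrite")
  check_same_grid(a, d)
  na <- sum(a)
  if (na == 0L) stop("empty axon mask: mismatch index undefined")
  sum(a & d) / na
}

#' Mistarget index: fluorescence fraction in the wrong glomerulus
#'
#' The ratio of total fluorescence intensity within glomerulus A to the
#' total within glomeruli A and B combined,
#' `sum(I[A]) / (sum(I[A]) + sum(I[B]))`.
#'
#' @param intensity a [labeled_volume()] of fluorescence.
#' @param glomA,glomB disjoint `binary_mask` objects on the intensity grid.
#' @return scalar in \[0, 1\].
#' @export
mistarget_index <- function(intensity, glomA, glomB) {
  stopifnot(inherits(intensity, "labeled_volume"))
  a <- as_mask_array(glomA, "glomA")
  b <- as_mask_array(glomB, "glomB")
  check_same_grid(a, intensity$voxels)
  check_same_grid(a, b)
  if (any(a & b)) stop("glomerulus masks overlap")
  sa <- sum(intensity$voxels[a])
  sb <- sum(intensity$voxels[b])
  if (sa + sb <= 0) stop("zero combined signal in the two glomeruli")
  sa / (sa + sb)
}

#' Min-max normalize a regional mean intensity
#'
#' `(region_mean - image_min) / (image_max - image_min)`, the per-image
#' normalization used for expression-level quantification.
#'
#' @param region_mean mean signal within the region of interest.
#' @param image_max,image_min extreme signal intensities within the image.
#' @return scalar in \[0, 1\].
#' @export
normalize_mean_intensity <- function(region_mean, image_max, image_min) {
  if (image_max <= image_min) stop("degenerate image: max <= min")
  if (region_mean < image_min || region_mean > image_max)
    stop("region_mean outside [image_min, image_max]")
  (region_mean - image_min) / (image_max - image_min)
}
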