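#' Spatial regions for morphometry
#'
#' Regions test whether 3D points (in micrometres) fall inside an
#' anatomical compartment: spheres and boxes for synthetic geometry, voxel
#' masks for segmented image channels, and point clouds with a contact
#' tolerance for traced dendrite regions.
#'
#' @name regions
NULL

#' Spherical region
#' @param center length-3 numeric center (um).
#' @param radius sphere radius (um).
#' @return object of class `region`.
#' @export
region_sphere <- function(center, radius) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = radius), class = "region")
}

#' Axis-aligned box region
#' @param lower,upper length-3 numeric corners (um), `lower <= upper`.
#' @return object of class `region`.
#' @export
region_box <- function(lower, upper) {
  stopifnot(length(lower) == 3L, length(upper) == 3L, all(lower <= upper))
  structure(list(kind = "box", lower = as.numeric(lower),
                 upper = as.numeric(upper)), class = "region")
}

#' Voxel-mask region
#'
#' A point is inside when the voxel containing it is foreground.  Voxel
#' (1,1,1) spans `origin` to `origin + voxel_size`.
#'
#' @param mask a `binary_mask` or logical 3D array.
#' @param voxel_size length-3 voxel size (um); taken from the mask when
#'   available.
#' @param origin physical coordinate of the grid corner (um).
#' @return object of class `region`.
#' @export
region_mask <- function(mask, voxel_size = NULL, origin = c(0, 0, 0)) {
  v <- if (inherits(mask, "binary_mask")) mask$voxels else (mask == TRUE)
  if (is.null(voxel_size))
    voxel_size <- if (inherits(mask, "binary_mask")) mask$voxel_size
                  else c(1, 1, 1)
  structure(list(kind = "mask", mask = v, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)), class = "region")
}

#' Point-cloud region with contact tolerance
#'
#' A point is inside when it lies within `eps` of any cloud point; the
#' default tolerance is 2 um.
#'
#' @param points numeric matrix (n x 3) of cloud coordinates (um).
#' @param eps contact tolerance (um).
#' @return object of class `region`.
#' @export
region_points <- function(points, eps = 2) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, eps >= 0)
  structure(list(kind = "points", points = points, eps = eps),
            class = "region")
}

#' Test points against a region
#'
#' @param region a `region` object.
#' @param pts numeric matrix (n x 3) or length-3 vector of coordinates (um).
#' @return logical vector, one per point.
#' @export
region_contains <- function(region, pts) {
  stopifnot(inherits(region, "region"))
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  pts <- as.matrix(pts)
  switch(region$kind,
    sphere = {
      d2 <- (pts[, 1] - region$center[1])^2 +
            (pts[, 2] - region$center[2])^2 +
            (pts[, 3] - region$center[3])^2
      d2 <= region$radius^2
    },
    box = {
      pts[, 1] >= region$lower[1] & pts[, 1] <= region$upper[1] &
      pts[, 2] >= region$lower[2] & pts[, 2] <= region$upper[2] &
      pts[, 3] >= region$lower[3] & pts[, 3] <= region$upper[3]
    },
    mask = {
      d <- dim(region$mask)
      ijk <- sweep(sweep(pts, 2L, region$origin), 2L, region$voxel_size, `/`)
      ijk <- floor(ijk) + 1L
      ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= d[3]
      res <- rep(FALSE, nrow(pts))
      if (any(ok)) {
        lin <- (ijk[ok, 3] - 1) * d[1] * d[2] + (ijk[ok, 2] - 1) * d[1] +
          ijk[ok, 1]
        res[ok] <- region$mask[lin]
      }
      res
    },
    points = {
      eps2 <- region$eps^2
      apply(pts, 1L, function(p) {
        any((region$points[, 1] - p[1])^2 + (region$points[, 2] - p[2])^2 +
            (region$points[, 3] - p[3])^2 <= eps2)
      })
    },
    stop("unknown region kind: ", region$kind))
}

#' Bundle the regions a morphometry run needs
#'
#' @param antennal_lobe `region` delimiting the antennal lobe (entry-point
#'   detection).
#' @param pn_dendrites `region` for the partner-PN dendrites (contact
#'   calls); may be NULL when contacts are not scored.
#' @param midline optional list `list(point =, normal =)` defining the
#'   midline plane for ipsi/contralateral assignment.
#' @return object of class `region_set`.
#' @export
region_set <- function(antennal_lobe, pn_dendrites = NULL, midline = NULL) {
  stopifnot(inherits(antennal_lobe, "region"))
  if (!is.null(pn_dendrites)) stopifnot(inherits(pn_dendrites, "region"))
  if (!is.null(midline))
    stopifnot(length(midline$point) == 3L, length(midline$normal) == 3L)
  structure(list(antennal_lobe = antennal_lobe, pn_dendrites = pn_dendrites,
                 midline = midline), class = "region_set")
}
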