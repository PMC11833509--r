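#' Configuration for the synthetic TMT proximity-labeling dataset
#'
#' The default scenario plants, among `n_proteins` rows, a bait row, 50
#' true interactors (enriched over both the negative control and the
#' spatial reference), 200 generic membrane-background proteins (enriched
#' over NC but not over SR), and 100 endogenously biotinylated
#' contaminants (equally high in all three groups, hence flat in ratio
#' space); the remainder are null proteins.  Channel values are class
#' means plus i.i.d. Gaussian noise on the log2-ratio scale.
#'
#' @param n_proteins total rows including the bait.
#' @param n_interactors,n_membrane,n_endo_biotin planted class sizes.
#' @param fc_interactor_nc,fc_interactor_sr interactor log2 fold changes
#'   versus NC and versus SR.
#' @param fc_membrane_nc,fc_membrane_sr membrane-background fold changes.
#' @param fc_endo_nc endogenously-biotinylated fold change versus NC
#'   (0: equally high everywhere, so flat after ratio normalization).
#' @param noise_sd replicate noise sd (log2 units).
#' @param bait_fc_nc,bait_fc_sr the bait's own fold changes; the bait's
#'   fc_nc anchors filter step 2.
#' @param peptide_lambda unique-peptide counts are `1 + Poisson(lambda)`.
#' @param seed RNG seed.
#' @return list of class `tmt_sim_config`.
#' @export
tmt_sim_config <- function(n_proteins = 2000L, n_interactors = 50L,
                           n_membrane = 200L, n_endo_biotin = 100L,
                           fc_interactor_nc = 3, fc_interactor_sr = 2,
                           fc_membrane_nc = 3, fc_membrane_sr = 0,
                           fc_endo_nc = 0,
                           noise_sd = 0.25,
                           bait_fc_nc = 2, bait_fc_sr = 1,
                           peptide_lambda = 4, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (1L + n_interactors + n_membrane + n_endo_biotin > n_proteins)
    stop("planted classes exceed n_proteins")
  structure(as.list(environment()), class = "tmt_sim_config")
}

#' Generate a synthetic TMT quantification table with known truth
#'
#' @param cfg a [tmt_sim_config()].
#' @return list with `quant` (a `protein_quant` in precomputed log2-ratio
#'   mode, design attached), `truth` (data.frame `protein_id`, `class`),
#'   and `design`.
#' @examples
#' sim <- gen_tmt_dataset(tmt_sim_config(n_proteins = 300, n_interactors = 20,
#'                                       n_membrane = 30, n_endo_biotin = 20,
#'                                       seed = 7))
#' table(sim$truth$class)
#' @export
gen_tmt_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "tmt_sim_config"))
  set.seed(cfg$seed)
  design <- tmt_design(c("126", "127", "128", "129", "130", "131"),
                       c("TRT", "TRT", "SR", "SR", "NC", "NC"))
  n_null <- cfg$n_proteins - 1L - cfg$n_interactors - cfg$n_membrane -
    cfg$n_endo_biotin
  cls <- c("bait",
           rep("interactor", cfg$n_interactors),
           rep("membrane", cfg$n_membrane),
           rep("endo_biotin", cfg$n_endo_biotin),
           rep("null", n_null))
  # group means on the log2-ratio scale (NC baseline = 0)
  mean_trt <- c(bait = cfg$bait_fc_nc,
                interactor = cfg$fc_interactor_nc,
                membrane = cfg$fc_membrane_nc,
                endo_biotin = cfg$fc_endo_nc, null = 0)
  mean_sr <- c(bait = cfg$bait_fc_nc - cfg$bait_fc_sr,
               interactor = cfg$fc_interactor_nc - cfg$fc_interactor_sr,
               membrane = cfg$fc_membrane_nc - cfg$fc_membrane_sr,
               endo_biotin = cfg$fc_endo_nc, null = 0)
  mu <- cbind(mean_trt[cls], mean_trt[cls], mean_sr[cls], mean_sr[cls],
              0, 0)
  vals <- mu + matrix(stats::rnorm(length(mu), sd = cfg$noise_sd),
                      nrow = nrow(mu))
  ids <- c("BAIT", sprintf("P%04d", seq_len(cfg$n_proteins - 1L)))
  pep <- 1L + stats::rpois(cfg$n_proteins, cfg$peptide_lambda)
  pep[1L] <- max(2L, pep[1L])
  tab <- data.frame(protein_id = ids,
                    gene_symbol = tolower(ids),
                    unique_peptides = pep,
                    stringsAsFactors = FALSE)
  for (j in seq_len(6L)) tab[[design$channel[j]]] <- vals[, j]
  quant <- protein_quant(tab, design)
  list(quant = quant,
       truth = data.frame(protein_id = ids, class = cls,
                          stringsAsFactors = FALSE),
       design = design)
}

#' Configuration for paired glomerular volumes
#'
#' Two equal-radius spherical "glomeruli" (axon and dendrite channels) on
#' one voxel grid, separated so that the voxelized overlap fraction of the
#' dendrite volume equals the programmed match index.  Intensity volumes
#' are `level * mask + Gaussian noise`.
#'
#' @param grid_dim length-3 voxel grid dimensions.
#' @param radius sphere radius in voxels.
#' @param overlap_fraction programmed `|A n D| / |D|` in \[0, 1\].
#' @param level foreground intensity.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return list of class `volume_sim_config`.
#' @export
volume_sim_config <- function(grid_dim = c(64L, 64L, 64L), radius = 18,
                              overlap_fraction = 0.4, level = 100,
                              noise_sd = 5, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  if (2 * radius + 2 > min(grid_dim))
    stop("spheres do not fit the grid")
  structure(as.list(environment()), class = "volume_sim_config")
}

sphere_mask <- function(grid_dim, center, radius) {
  i <- seq_len(grid_dim[1]); j <- seq_len(grid_dim[2]); k <- seq_len(grid_dim[3])
  d2 <- outer(outer((i - center[1])^2, (j - center[2])^2, `+`),
              (k - center[3])^2, `+`)
  d2 <= radius^2
}

#' Generate paired axon/dendrite volumes with programmed overlap
#'
#' The center separation for the requested overlap fraction is solved from
#' the analytic sphere-lens volume, then the ground-truth indices are
#' recorded from the noiseless voxel masks.
#'
#' @param cfg a [volume_sim_config()].
#' @return list with `axon`, `dendrite` ([labeled_volume()] intensities),
#'   `axon_mask`, `dendrite_mask` (noiseless truth masks) and `truth`
#'   (voxel-exact `match_index`, `mismatch_index`, and the programmed
#'   fraction).
#' @export
gen_glomerular_volumes <- function(cfg) {
  stopifnot(inherits(cfg, "volume_sim_config"))
  set.seed(cfg$seed)
  r <- cfg$radius
  f <- cfg$overlap_fraction
  # lens volume of two equal spheres at separation d:
  # V(d) = pi (4r + d) (2r - d)^2 / 12 ; V(0) = sphere volume
  vol_sphere <- 4 / 3 * pi * r^3
  sep <- if (f >= 1) 0 else if (f <= 0) 2 * r + 2 else {
    stats::uniroot(function(d) pi * (4 * r + d) * (2 * r - d)^2 / 12 -
                     f * vol_sphere,
                   interval = c(0, 2 * r), tol = 1e-10)$root
  }
  mid <- cfg$grid_dim / 2
  c_d <- mid - c(sep / 2, 0, 0)
  c_a <- mid + c(sep / 2, 0, 0)
  m_d <- sphere_mask(cfg$grid_dim, c_d, r)
  m_a <- sphere_mask(cfg$grid_dim, c_a, r)
  if (f <= 0 && any(m_a & m_d))
    stop("could not realize disjoint spheres on this grid")
  truth <- list(match_index = sum(m_a & m_d) / sum(m_d),
                mismatch_index = sum(m_a & m_d) / sum(m_a),
                programmed_fraction = f)
  noise <- function() array(stats::rnorm(prod(cfg$grid_dim), sd = cfg$noise_sd),
                            cfg$grid_dim)
  list(axon = labeled_volume(cfg$level * m_a + noise(), channel = "axon"),
       dendrite = labeled_volume(cfg$level * m_d + noise(),
                                 channel = "dendrite"),
       axon_mask = binary_mask(m_a, "axon"),
       dendrite_mask = binary_mask(m_d, "dendrite"),
       truth = truth)
}

#' Configuration for a synthetic traced axon with an intensity field
#'
#' Emulates a single olfactory receptor neuron axon developing through the
#' antennal lobe: a thick stem of stage-consistent length entering the
#' lobe, primary collateral branches at drawn normalized positions, a
#' programmed probability of contacting the partner-PN dendrite region
#' (geometrically realized), optional multifurcation, and a co-registered
#' F-actin-like field whose contact-zone voxels carry an intensity boost.
#'
#' @param stage developmental stage 1, 2 or 3 (sets the stem length range:
#'   60-95, 105-165, 180-230 um).
#' @param n_branches_lambda primary branch count is `Poisson(lambda)`
#'   (a draw of 0 yields a bare stem).
#' @param position_dist `"uniform"` or `"pn_peaked"` (Beta(4, 2), shifted
#'   toward the PN region) for normalized branch positions.
#' @param p_contact probability a primary branch contacts the PN region.
#' @param p_multifurcate probability a primary branch carries a secondary.
#' @param pn_center_frac PN region center as a fraction of stem length.
#' @param pn_offset,pn_radius PN sphere offset from the stem and radius (um).
#' @param delta contact-zone field boost (raw intensity units).
#' @param baseline field baseline intensity.
#' @param noise_sd field additive noise sd.
#' @param blur apply a 3-point separable smoothing kernel.
#' @param voxel_size field voxel size (um, isotropic scalar or length 3).
#' @param stem_step node spacing along the stem and branches (um).
#' @param seed RNG seed.
#' @return list of class `axon_sim_config`.
#' @export
axon_sim_config <- function(stage = 3L, n_branches_lambda = 10,
                            position_dist = c("uniform", "pn_peaked"),
                            p_contact = 0.5, p_multifurcate = 0.3,
                            pn_center_frac = 0.7, pn_offset = 15,
                            pn_radius = 12,
                            delta = 0.3, baseline = 0.5, noise_sd = 0.1,
                            blur = TRUE, voxel_size = 1, stem_step = 2,
                            seed = 1L) {
  position_dist <- match.arg(position_dist)
  stopifnot(stage %in% 1:3, p_contact >= 0, p_contact <= 1,
            p_multifurcate >= 0, p_multifurcate <= 1,
            pn_offset > pn_radius)   # the stem itself never enters the PN
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(as.list(environment()), class = "axon_sim_config")
}

# separable 3-point blur with edge replication
blur3 <- function(a) {
  d <- dim(a)
  for (ax in 1:3) {
    lo <- seq_len(d[ax]); up <- pmin(lo + 1L, d[ax]); dn <- pmax(lo - 1L, 1L)
    a <- switch(ax,
      0.5 * a + 0.25 * a[up, , , drop = FALSE] + 0.25 * a[dn, , , drop = FALSE],
      0.5 * a + 0.25 * a[, up, , drop = FALSE] + 0.25 * a[, dn, , drop = FALSE],
      0.5 * a + 0.25 * a[, , up, drop = FALSE] + 0.25 * a[, , dn, drop = FALSE])
  }
  a
}

#' Generate a synthetic traced axon, regions, field and truth records
#'
#' The stem runs along +x with radius 1 um (branches 0.4 um, secondaries
#' 0.3 um, so the stem is always the thickest path), starting 20 um before
#' the antennal lobe boundary at x = 0.  Contacting branches are routed
#' into the PN dendrite sphere; non-contacting branches head the opposite
#' way and can never reach it.  The field covers the trace bounding box
#' plus a margin; voxels around PN-contact-zone nodes carry the configured
#' boost, then the field is blurred and noised.
#'
#' @param cfg an [axon_sim_config()].
#' @return list with `tree` ([neurite_tree()]), `regions` ([region_set()]),
#'   `field` ([labeled_volume()]), `origin` (field grid corner, um),
#'   `stem_length` (truth), and `truth` (data.frame per primary branch:
#'   `branch_point_node`, `normalized_position`, `contacts_pn`,
#'   `multifurcated`, `n_secondary`).
#' @export
gen_axon_with_field <- function(cfg) {
  stopifnot(inherits(cfg, "axon_sim_config"))
  set.seed(cfg$seed)
  len_range <- switch(cfg$stage, c(60, 95), c(105, 165), c(180, 230))
  L <- stats::runif(1, len_range[1], len_range[2])
  step <- cfg$stem_step
  xs <- seq(-20, L, by = step)
  if (max(xs) < L) xs <- c(xs, L)
  n_stem <- length(xs)
  nodes <- data.frame(id = seq_len(n_stem), type = 2L,
                      x = xs, y = 0, z = 0, radius = 1,
                      parent = c(-1L, seq_len(n_stem - 1L)))
  entry_i <- which(xs >= 0)[1]
  pn_center <- c(cfg$pn_center_frac * L, cfg$pn_offset, 0)
  pn <- region_sphere(pn_center, cfg$pn_radius)

  n_br <- stats::rpois(1, cfg$n_branches_lambda)
  u <- if (cfg$position_dist == "uniform") stats::runif(n_br)
       else stats::rbeta(n_br, 4, 2)
  contact <- stats::runif(n_br) < cfg$p_contact
  multi <- stats::runif(n_br) < cfg$p_multifurcate
  next_id <- n_stem
  truth <- vector("list", n_br)
  contact_zone <- NULL     # coordinates of PN-contact-zone nodes
  for (b in seq_len(n_br)) {
    bp_x <- u[b] * L
    # branch points sit strictly proximal to the stem tip (the growth cone),
    # so the stem itself remains a root-to-leaf path
    bp_i <- entry_i - 1L + which.min(abs(xs[entry_i:(n_stem - 1L)] - bp_x))
    bp <- c(nodes$x[bp_i], 0, 0)
    if (contact[b]) {
      # aim at a random interior point of the PN sphere: distinct branches
      # enter the dendritic territory at distinct spots
      repeat {
        tgt_off <- stats::runif(3, -1, 1) * cfg$pn_radius * 0.6
        if (sum(tgt_off^2) <= (cfg$pn_radius * 0.6)^2) break
      }
      tgt <- pn_center + tgt_off
      dir <- tgt - bp
      dist_c <- sqrt(sum(dir^2))
      dir <- dir / dist_c
      # walk to the target and one step beyond so part of the branch is inside
      n_nodes <- ceiling(dist_c / step) + 1L
    } else {
      ang <- stats::runif(1, -0.3, 0.3)
      dir <- c(sin(ang), -cos(ang), 0)   # away from the PN side (+y)
      n_nodes <- ceiling(stats::runif(1, 8, 16) / step)
    }
    pos <- sweep(outer(seq_len(n_nodes) * step, dir), 2L, bp, `+`)
    ids <- next_id + seq_len(n_nodes)
    nodes <- rbind(nodes, data.frame(id = ids, type = 2L,
                                     x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                     radius = 0.4,
                                     parent = c(nodes$id[bp_i], ids[-n_nodes])))
    next_id <- next_id + n_nodes
    nsec <- 0L
    allpos <- pos
    if (multi[b] && n_nodes >= 2L) {
      mid <- ids[max(1L, n_nodes %/% 2L)]
      mid_pos <- pos[max(1L, n_nodes %/% 2L), ]
      sec <- next_id + 1:3
      sp <- sweep(outer(1:3 * step, c(0, 0, 1)), 2L, mid_pos, `+`)
      nodes <- rbind(nodes, data.frame(id = sec, type = 2L,
                                       x = sp[, 1], y = sp[, 2], z = sp[, 3],
                                       radius = 0.3,
                                       parent = c(mid, sec[-3])))
      next_id <- next_id + 3L
      nsec <- 1L
      allpos <- rbind(allpos, sp)
    }
    if (contact[b]) {
      inside <- region_contains(pn, allpos)
      contact_zone <- rbind(contact_zone, allpos[inside, , drop = FALSE])
    }
    truth[[b]] <- data.frame(branch_point_node = nodes$id[bp_i],
                             child_node = ids[1],
                             normalized_position = nodes$x[bp_i] / L,
                             contacts_pn = contact[b],
                             multifurcated = nsec >= 1L,
                             n_secondary = nsec)
  }
  tree <- neurite_tree(nodes)
  al <- region_box(c(0, -1e6, -1e6), c(1e6, 1e6, 1e6))
  regions <- region_set(al, pn)

  # field over the trace bounding box + margin
  vs <- cfg$voxel_size
  margin <- 5
  lo <- c(min(nodes$x), min(nodes$y), min(nodes$z)) - margin
  hi <- c(max(nodes$x), max(nodes$y), max(nodes$z)) + margin
  d <- pmax(ceiling((hi - lo) / vs), 3L)
  field <- array(cfg$baseline, d)
  if (!is.null(contact_zone) && nrow(contact_zone)) {
    ijk <- floor(sweep(sweep(contact_zone, 2L, lo), 2L, vs, `/`)) + 1L
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(offs^2) <= 1, , drop = FALSE]
    for (i in seq_len(nrow(ijk))) {
      nb <- sweep(offs, 2L, ijk[i, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      field[(nb[, 3] - 1) * d[1] * d[2] + (nb[, 2] - 1) * d[1] + nb[, 1]] <-
        cfg$baseline + cfg$delta
    }
  }
  if (cfg$blur) field <- blur3(field)
  if (cfg$noise_sd > 0)
    field <- field + array(stats::rnorm(prod(d), sd = cfg$noise_sd), d)
  truth <- if (n_br > 0L) do.call(rbind, truth) else
    data.frame(branch_point_node = integer(), child_node = integer(),
               normalized_position = numeric(), contacts_pn = logical(),
               multifurcated = logical(), n_secondary = integer())
  list(tree = tree, regions = regions,
       field = labeled_volume(field, vs, channel = "factin"),
       origin = lo, stem_length = L,
       truth = truth)
}
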