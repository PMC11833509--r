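test_that("stem selection picks the thick limb and reduces to the only path", {
  line <- line_tree(5)
  expect_equal(identify_stem_axon(line), 1:5)
  # Y-tree: shared trunk, one thick and one thin limb of equal length
  y <- neurite_tree(data.frame(
    id = 1:4, x = c(0, 10, 20, 20), y = c(0, 0, 10, -10), z = 0,
    radius = c(1, 1, 1.0, 0.3), parent = c(-1L, 1L, 2L, 2L)))
  expect_equal(identify_stem_axon(y), c(1L, 2L, 3L))
  expect_error(identify_stem_axon(line_tree(1)), "single-node")
})

test_that("stem selection equals exhaustive path enumeration on random trees", {
  set.seed(51)
  for (rep_i in 1:40) {
    tr <- random_tree(sample(5:50, 1))
    expect_equal(identify_stem_axon(tr), stem_oracle(tr))
  }
})

test_that("entry/end location accumulates arc length from the lobe boundary", {
  # 7 nodes at 10 um spacing; region starts at x = 15: nodes 3..7 inside
  tr <- line_tree(7, spacing = 10)
  rs <- region_set(region_box(c(15, -10, -10), c(1e3, 10, 10)))
  ann <- locate_entry_and_end(tr, identify_stem_axon(tr), rs)
  expect_equal(ann$entry_node, 3L)
  expect_equal(ann$end_node, 7L)
  expect_equal(ann$stem_length, 40)

  # stem entirely inside: entry = root, end = tip, full length
  rs_all <- region_set(region_box(c(-1, -1, -1), c(1e3, 1, 1)))
  ann2 <- locate_entry_and_end(tr, 1:7, rs_all)
  expect_equal(ann2$entry_node, 1L)
  expect_equal(ann2$stem_length, 60)

  # region touching only the tip: entry = end, zero length
  rs_tip <- region_set(region_box(c(59, -1, -1), c(61, 1, 1)))
  ann3 <- locate_entry_and_end(tr, 1:7, rs_tip)
  expect_equal(ann3$entry_node, ann3$end_node)
  expect_equal(ann3$stem_length, 0)

  rs_out <- region_set(region_box(c(100, -1, -1), c(110, 1, 1)))
  expect_error(locate_entry_and_end(tr, 1:7, rs_out), "no stem node")
})

test_that("stage classification partitions the length axis at 100 and 170 um", {
  expect_equal(classify_stage(c(0, 99.9, 100, 135, 170, 170.1, 250)),
               c(1L, 1L, 2L, 2L, 2L, 3L, 3L))
  # piecewise-constant oracle over a random sweep
  set.seed(52)
  len <- runif(200, 0, 300)
  oracle <- ifelse(len < 100, 1L, ifelse(len <= 170, 2L, 3L))
  expect_equal(classify_stage(len), oracle)
})

test_that("primary branch extraction normalizes positions and flags contacts and multifurcation", {
  # stem 0..100 along x (11 nodes); one collateral at x = 50 whose subtree
  # bifurcates; another proximal to the entry point
  stem_n <- 11L
  nodes <- data.frame(
    id = 1:16,
    x = c(seq(0, 100, by = 10),  50, 50, 50,  10, 10),
    y = c(rep(0, stem_n),        5, 10, 10,   -5, -10),
    z = c(rep(0, stem_n),        0,  2, -2,    0, 0),
    radius = c(rep(1, stem_n), rep(0.4, 5)),
    parent = c(-1L, 1:10,  6L, 12L, 12L,  2L, 15L))
  tr <- neurite_tree(nodes)
  # entry region starts at x = 20 -> entry node id 3, end id 11, length 80
  rs <- region_set(region_box(c(20, -50, -50), c(500, 50, 50)),
                   pn_dendrites = region_points(matrix(c(50, 10, 2), 1), eps = 1),
                   midline = list(point = c(65, 0, 0), normal = c(1, 0, 0)))
  ann <- locate_entry_and_end(tr, identify_stem_axon(tr), rs)
  expect_equal(ann$stem_length, 80)
  rec <- extract_primary_branches(tr, ann, rs)
  # the branch proximal to entry (at x = 10) is excluded and logged
  expect_equal(nrow(rec), 1L)
  expect_equal(nrow(attr(rec, "excluded")), 1L)
  expect_equal(rec$branch_point_node, 6L)
  expect_equal(rec$normalized_position, (50 - 20) / 80)
  expect_true(rec$contacts_pn)          # node 13 is within eps of the cloud
  expect_true(rec$multifurcated)        # node 12 bifurcates
  expect_equal(rec$n_secondary, 1L)
  expect_equal(rec$side, "ipsilateral") # branch point at x = 50 < midline 65
})

test_that("contact and multifurcation calls match exhaustive subtree scans on random trees", {
  set.seed(53)
  for (rep_i in 1:20) {
    tr <- random_tree(sample(10:40, 1), span = 60)
    stem <- identify_stem_axon(tr)
    rs <- region_set(region_box(c(-1e3, -1e3, -1e3), c(1e3, 1e3, 1e3)),
                     pn_dendrites = region_points(
                       matrix(runif(15, 0, 60), ncol = 3), eps = 2))
    ann <- locate_entry_and_end(tr, stem, rs)
    if (ann$stem_length <= 0) next
    rec <- extract_primary_branches(tr, ann, rs)
    # oracle: walk every stem node's off-stem children by hand
    on_stem <- seq_len(nrow(tr$nodes)) %in% stem
    for (r in seq_len(nrow(rec))) {
      ch <- match(rec$child_node[r], tr$nodes$id)
      sub <- integer(); stack <- ch
      while (length(stack)) {
        v <- stack[1]; stack <- stack[-1]
        sub <- c(sub, v)
        kids <- which(tr$parent_idx == v)
        stack <- c(stack, kids)
      }
      pts <- node_coords(tr, sub)
      d2 <- outer(rowSums(pts^2), rowSums(rs$pn_dendrites$points^2), `+`) -
        2 * pts %*% t(rs$pn_dendrites$points)
      expect_equal(rec$contacts_pn[r], any(d2 <= 4 + 1e-9))
      n_sec <- sum(pmax(0L, tabulate(tr$parent_idx[tr$parent_idx %in% sub],
                                     nbins = nrow(tr$nodes))[sub] - 1L))
      expect_equal(rec$n_secondary[r], n_sec)
      expect_equal(rec$multifurcated[r], n_sec >= 1L)
    }
    expect_true(all(rec$normalized_position >= 0 &
                      rec$normalized_position <= 1))
  }
})

test_that("contact calls are invariant to node re-indexing and joint rigid motion", {
  sim <- gen_axon_with_field(axon_sim_config(seed = 61, noise_sd = 0))
  m1 <- axon_morphometry(sim$tree, sim$regions)
  # re-index nodes (relabel ids, same geometry)
  nd <- sim$tree$nodes
  set.seed(62)
  perm <- sample(nrow(nd))
  map <- integer(nrow(nd)); map[perm] <- seq_len(nrow(nd))
  nd2 <- nd[perm, ]
  nd2$id <- seq_len(nrow(nd))
  nr <- nd2$parent != -1L
  nd2$parent[nr] <- map[nd2$parent[nr]]
  m2 <- axon_morphometry(neurite_tree(nd2), sim$regions)
  expect_equal(sort(m2$records$normalized_position),
               sort(m1$records$normalized_position))
  expect_equal(sum(m2$records$contacts_pn), sum(m1$records$contacts_pn))

  # rigid translation applied jointly to tree and regions
  shift <- c(12, -7, 4)
  nd3 <- nd
  nd3[, c("x", "y", "z")] <- sweep(as.matrix(nd[, c("x", "y", "z")]), 2,
                                   shift, `+`)
  al <- sim$regions$antennal_lobe
  rs3 <- region_set(region_box(al$lower + shift, al$upper + shift),
                    region_sphere(sim$regions$pn_dendrites$center + shift,
                                  sim$regions$pn_dendrites$radius))
  m3 <- axon_morphometry(neurite_tree(nd3), rs3)
  expect_equal(m3$records$contacts_pn, m1$records$contacts_pn)
  expect_equal(m3$stem$stem_length, m1$stem$stem_length)
})

test_that("branch statistics compute densities, fractions and a mass-conserving histogram", {
  # 10 primaries on a 100 um stem -> density 0.1 per um
  rec <- data.frame(branch_point_node = 1:10, child_node = 11:20,
                    normalized_position = seq(0.025, 0.925, by = 0.1),
                    order = "primary",
                    contacts_pn = rep(c(TRUE, FALSE), 5),
                    multifurcated = c(rep(TRUE, 4), rep(FALSE, 6)),
                    n_secondary = c(2L, 1L, 1L, 3L, rep(0L, 6)),
                    side = "ipsilateral")
  class(rec) <- c("branch_records", "data.frame")
  ann <- structure(list(stem_length = 100), class = "stem_annotation")
  s <- branch_statistics(rec, ann, bins = 20L)
  expect_equal(s$branch_density, 0.1)
  expect_equal(s$total_branches, 10L)
  expect_equal(s$contacting_fraction, 0.5)
  expect_equal(s$multifurcated_contacting_fraction,
               mean(rec$contacts_pn[rec$multifurcated]))
  expect_equal(s$n_secondary_contacting,
               sum(rec$n_secondary[rec$contacts_pn]))
  expect_equal(sum(s$position_histogram), 10L)
  # brute-force binning oracle
  br <- seq(0, 1, length.out = 21)
  oracle <- vapply(1:20, function(b) {
    lo <- br[b]; hi <- br[b + 1]
    sum(if (b == 1) rec$normalized_position >= lo &
          rec$normalized_position <= hi
        else rec$normalized_position > lo & rec$normalized_position <= hi)
  }, 1L)
  expect_equal(as.integer(s$position_histogram), oracle)

  empty <- rec[0, ]
  s0 <- branch_statistics(empty, ann)
  expect_equal(s0$branch_density, 0)
  expect_true(is.na(s0$contacting_fraction))
})

test_that("group comparisons reproduce textbook statistics and flag planted shifts", {
  # two identical groups: all corrected pairwise p-values ~ 1
  v <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  res <- compare_groups(v, g, "anova_tukey")
  expect_true(all(res$pairwise$p_adj > 0.99))
  expect_false(is.na(res$normality_p))
  expect_false(is.na(res$variance_p))

  # 2x2 chi-squared equals the closed form n(ad-bc)^2 / row/col products
  counts <- rbind(a = c(50, 50), b = c(90, 10))
  res2 <- compare_groups(counts, test = "chi2_bonferroni")
  chi_hand <- 200 * (50 * 10 - 50 * 90)^2 / (100 * 100 * 140 * 60)
  expect_equal(res2$statistic, chi_hand, tolerance = 1e-12)

  # planted mean shift in one of three groups is flagged after correction
  set.seed(54)
  vals <- c(rnorm(15), rnorm(15), rnorm(15, 3))
  grp <- rep(c("g1", "g2", "g3"), each = 15)
  res3 <- compare_groups(vals, grp, "anova_tukey")
  hit <- res3$pairwise[with(res3$pairwise, (group1 == "g3" | group2 == "g3")), ]
  expect_true(all(hit$p_adj < 0.05))
  same <- res3$pairwise[with(res3$pairwise, group1 != "g3" & group2 != "g3"), ]
  expect_true(all(same$p_adj > 0.05))

  res4 <- compare_groups(vals, grp, "kruskal_bonferroni")
  expect_lt(res4$p_value, 0.01)
  expect_error(compare_groups(c(1, 2), c("a", "b"), "anova_tukey"), "n < 2")
})
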