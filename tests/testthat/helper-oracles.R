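# Independent brute-force oracles and fixture builders used across tests.

# BH step-up by the definition: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(pmin(ps[i:n] * n / (i:n), 1))
  out <- numeric(n)
  out[o] <- q
  out
}

# OLS by the normal equations, independently of the package's fitting path
ols_oracle <- function(y, X) {
  b <- solve(t(X) %*% X) %*% t(X) %*% y
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  list(b = unname(drop(b)), s2 = sum(res^2) / df, df = df)
}

# connected components by an explicit queue-based flood fill
floodfill_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      ci <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        nb <- ci + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1) * d[1] * d[2] + (nb[2] - 1) * d[1] + nb[1]
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# triple-loop voxel intersection counts
overlap_oracle <- function(a, b) {
  d <- dim(a)
  n_int <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (a[i, j, k] && b[i, j, k]) n_int <- n_int + 1L
  n_int
}

# exhaustive stem selection: every root-to-leaf path via igraph simple paths
stem_oracle <- function(tree) {
  g <- igraph::graph_from_edgelist(
    cbind(tree$parent_idx[-tree$root], seq_len(nrow(tree$nodes))[-tree$root]),
    directed = TRUE)
  leaves <- tree_leaves(tree)
  best <- NULL
  best_key <- NULL
  for (lf in leaves) {
    p <- as.integer(igraph::all_simple_paths(g, tree$root, lf)[[1]])
    seg <- tree$edge_length[p[-1]]
    rad <- (tree$nodes$radius[p[-1]] + tree$nodes$radius[p[-length(p)]]) / 2
    len <- sum(seg)
    score <- if (len > 0) sum(seg * rad) / len else mean(tree$nodes$radius[p])
    key <- list(score, len, as.character(tree$nodes$id[lf]))
    if (is.null(best) ||
        key[[1]] > best_key[[1]] ||
        (key[[1]] == best_key[[1]] && key[[2]] > best_key[[2]]) ||
        (key[[1]] == best_key[[1]] && key[[2]] == best_key[[2]] &&
         key[[3]] < best_key[[3]])) {
      best <- p
      best_key <- key
    }
  }
  best
}

# random rooted tree with n nodes: each node's parent drawn among earlier nodes
random_tree <- function(n, radius_range = c(0.2, 1.5), span = 50) {
  id <- seq_len(n)
  parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  neurite_tree(data.frame(
    id = id,
    x = runif(n, 0, span), y = runif(n, 0, span), z = runif(n, 0, span),
    radius = runif(n, radius_range[1], radius_range[2]),
    parent = parent))
}

# straight-line tree along +x with given spacing
line_tree <- function(n, spacing = 10, radius = 1) {
  neurite_tree(data.frame(
    id = seq_len(n), x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
    radius = radius, parent = c(-1L, seq_len(n - 1L))))
}

# minimal balanced 2/2/2 six-plex design used throughout
design6 <- function() {
  tmt_design(c("126", "127", "128", "129", "130", "131"),
             c("TRT", "TRT", "SR", "SR", "NC", "NC"))
}

# protein_quant table from a values matrix (log2-ratio mode rows)
quant_from_matrix <- function(vals, peptides = NULL, ids = NULL) {
  n <- nrow(vals)
  d <- design6()
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  tab <- data.frame(protein_id = ids, gene_symbol = tolower(ids),
                    unique_peptides = if (is.null(peptides)) rep(5L, n)
                                      else peptides,
                    stringsAsFactors = FALSE)
  for (j in 1:6) tab[[d$channel[j]]] <- vals[, j]
  protein_quant(tab, d)
}

# per-node mean within a voxel-space sphere, by explicit offset enumeration
sphere_sample_oracle <- function(field_arr, center_vox, r) {
  d <- dim(field_arr)
  vals <- c()
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx^2 + dy^2 + dz^2 > r^2) next
    v <- center_vox + c(dx, dy, dz)
    if (any(v < 1) || any(v > d)) next
    vals <- c(vals, field_arr[v[1], v[2], v[3]])
  }
  mean(vals)
}
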