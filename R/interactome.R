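#' Three-step bait-anchored ratiometric interactome filter
#'
#' Reduces a fitted TMT table to the bait's intracellular interactome in
#' three nested steps: (1) keep proteins identified by at least
#' `min_peptides` unique peptides; (2) keep proteins whose bait/NC fold
#' change is at least the bait protein's own (removing endogenously
#' biotinylated and endogenous-peroxidase contaminants that are also high
#' in the negative control); (3) keep proteins with a strictly positive
#' bait/spatial-reference fold change (removing generic membrane-proximal
#' background).
#'
#' @name interactome_filter
NULL

#' Step 1: minimum unique-peptide filter
#'
#' @param tab data.frame with a `unique_peptides` column (a `tmt_fit`
#'   table or `protein_quant`).
#' @param k minimum unique-peptide count (default 2).
#' @return the retained subset.
#' @export
filter_min_unique_peptides <- function(tab, k = 2L) {
  tab[tab$unique_peptides >= k, , drop = FALSE]
}

#' Step 2: bait-anchored fold-change filter
#'
#' Retains proteins whose bait/NC log2 fold change is greater than or equal
#' to the bait protein's own (inclusive), so the bait always retains itself.
#'
#' @param tab data.frame with `protein_id`, `fc_nc` (and optionally
#'   `gene_symbol`) columns.
#' @param bait_id bait protein identifier.
#' @param match_gene_symbol if TRUE and `bait_id` is not found among
#'   `protein_id`, fall back to a unique `gene_symbol` match.
#' @return the retained subset; the bait row is always included.
#' @export
bait_anchor_filter <- function(tab, bait_id, match_gene_symbol = FALSE) {
  i <- match(bait_id, tab$protein_id)
  if (is.na(i) && match_gene_symbol && "gene_symbol" %in% names(tab)) {
    hits <- which(tab$gene_symbol == bait_id)
    if (length(hits) == 1L) i <- hits
    else if (length(hits) > 1L)
      stop("bait gene symbol '", bait_id, "' matches multiple proteins")
  }
  if (is.na(i))
    stop("bait '", bait_id, "' not found in the fitted table")
  tab[tab$fc_nc >= tab$fc_nc[i], , drop = FALSE]
}

#' Step 3: spatial-reference ratiometric filter
#'
#' Retains proteins with bait/SR log2 fold change strictly greater than 0.
#'
#' @param tab data.frame with an `fc_sr` column.
#' @return the retained subset.
#' @export
sr_ratiometric_filter <- function(tab) {
  tab[tab$fc_sr > 0, , drop = FALSE]
}

#' Rank interactome candidates by bait/SR fold change
#'
#' Descending sort by `fc_sr`; ties broken by smaller `q_sr`, then
#' lexicographic `protein_id`.  Returns the top `k` with a `rank` column.
#'
#' @param tab the step-3 interactome table.
#' @param k shortlist size (default 37).
#' @return the ranked shortlist (all rows, with a warning, if
#'   `k > nrow(tab)`).
#' @export
rank_candidates <- function(tab, k = 37L) {
  q <- if ("q_sr" %in% names(tab)) tab$q_sr else rep(0, nrow(tab))
  ord <- order(-tab$fc_sr, q, tab$protein_id)
  out <- tab[ord, , drop = FALSE]
  if (k > nrow(out)) {
    warning("requested top ", k, " of only ", nrow(out), " candidates")
    k <- nrow(out)
  }
  out <- out[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Run the full three-step interactome filter
#'
#' @param fit a [tmt_fit()] object.
#' @param bait_id bait protein identifier (see [bait_anchor_filter()]).
#' @param min_peptides minimum unique peptides for step 1.
#' @param top_k shortlist size for [rank_candidates()].
#' @param match_gene_symbol passed to [bait_anchor_filter()].
#' @return list of class `interactome` with elements `trace` (a
#'   `filter_trace`: counts after each step, bait id and fold change),
#'   `step1`, `step2`, `interactome` (step-3 table), `shortlist`.
#' @examples
#' sim <- gen_tmt_dataset(tmt_sim_config(n_proteins = 300, n_interactors = 15,
#'                                       n_membrane = 30, n_endo_biotin = 15,
#'                                       seed = 1))
#' fit <- tmt_fit(sim$quant, mode = "precomputed")
#' res <- run_interactome(fit, bait_id = "BAIT")
#' res$trace
#' @export
run_interactome <- function(fit, bait_id, min_peptides = 2L, top_k = 37L,
                            match_gene_symbol = FALSE) {
  stopifnot(inherits(fit, "tmt_fit"))
  tab <- fit$table
  s1 <- filter_min_unique_peptides(tab, min_peptides)
  s2 <- bait_anchor_filter(s1, bait_id, match_gene_symbol)
  s3 <- sr_ratiometric_filter(s2)
  sl <- rank_candidates(s3, min(top_k, max(nrow(s3), 1L)))
  bait_row <- match(bait_id, tab$protein_id)
  if (is.na(bait_row) && match_gene_symbol)
    bait_row <- match(bait_id, tab$gene_symbol)
  trace <- structure(list(n_detected = nrow(tab),
                          n_step1 = nrow(s1),
                          n_step2 = nrow(s2),
                          n_step3 = nrow(s3),
                          bait_id = bait_id,
                          bait_fc_nc = tab$fc_nc[bait_row]),
                     class = "filter_trace")
  stopifnot(trace$n_detected >= trace$n_step1,
            trace$n_step1 >= trace$n_step2,
            trace$n_step2 >= trace$n_step3)
  structure(list(trace = trace, step1 = s1, step2 = s2,
                 interactome = s3, shortlist = sl),
            class = "interactome")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("Ratiometric filter trace\n")
  cat(sprintf("  detected: %d\n  step 1 (unique peptides): %d\n",
              x$n_detected, x$n_step1))
  cat(sprintf("  step 2 (fc_nc >= bait's %.3f): %d\n", x$bait_fc_nc, x$n_step2))
  cat(sprintf("  step 3 (fc_sr > 0): %d\n", x$n_step3))
  invisible(x)
}

#' @export
print.interactome <- function(x, ...) {
  print(x$trace)
  cat(sprintf("  shortlist: top %d by fc_sr\n", nrow(x$shortlist)))
  invisible(x)
}

#' Write interactome filter outputs
#'
#' Emits the filter trace (JSON), the full statistics table, the step-3
#' interactome and the ranked shortlist (TSV) into a directory.
#'
#' @param res a [run_interactome()] result.
#' @param fit the [tmt_fit()] it came from.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_interactome <- function(res, fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trace = file.path(dir, "filter_trace.json"),
             stats = file.path(dir, "protein_stats.tsv"),
             interactome = file.path(dir, "interactome.tsv"),
             shortlist = file.path(dir, "shortlist.tsv"))
  jsonlite::write_json(unclass(res$trace), paths["trace"], auto_unbox = TRUE,
                       digits = NA)
  write_tmt_stats(fit, paths["stats"])
  utils::write.table(res$interactome, paths["interactome"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$shortlist, paths["shortlist"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
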