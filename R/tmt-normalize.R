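#' Convert reporter intensities to log2 TMT ratios
#'
#' Relative protein abundance in an isobaric-tag experiment is a ratio, not
#' an intensity: each protein's channel values are referenced against that
#' protein's own median intensity across the channels, and log2-transformed.
#' A per-channel median-centering across proteins is then applied to remove
#' channel loading differences.  Tables that already carry log2 ratios pass
#' through unchanged (`mode = "precomputed"`).
#'
#' Proteins with any non-positive intensity in raw mode are rejected (their
#' ids and the reason are recorded in the `rejected` attribute); proteins
#' with all channels missing are dropped and counted.
#'
#' @param quant a `protein_quant` table (see [protein_quant()]).
#' @param mode `"raw_intensity"` (transform) or `"precomputed"` (identity).
#' @return a `protein_quant` table in log2-ratio mode, with attributes
#'   `rejected` (data.frame of protein_id + reason) and `n_dropped_missing`.
#' @export
normalize_log2_ratios <- function(quant, mode = c("raw_intensity", "precomputed")) {
  mode <- match.arg(mode)
  design <- attr(quant, "design")
  if (mode == "precomputed") {
    attr(quant, "rejected") <- data.frame(protein_id = character(),
                                          reason = character())
    attr(quant, "n_dropped_missing") <- 0L
    attr(quant, "log2_mode") <- TRUE
    return(quant)
  }
  vals <- quant_values(quant)
  all_missing <- apply(vals, 1L, function(v) all(is.na(v)))
  n_dropped <- sum(all_missing)
  quant <- quant[!all_missing, , drop = FALSE]
  vals <- vals[!all_missing, , drop = FALSE]

  nonpos <- apply(vals, 1L, function(v) any(v <= 0, na.rm = TRUE))
  rejected <- data.frame(protein_id = rownames(vals)[nonpos],
                         reason = rep("nonpositive intensity", sum(nonpos)),
                         stringsAsFactors = FALSE)
  quant <- quant[!nonpos, , drop = FALSE]
  vals <- vals[!nonpos, , drop = FALSE]

  med <- apply(vals, 1L, stats::median, na.rm = TRUE)
  lr <- log2(vals / med)
  # channel centering: subtract per-channel median across proteins
  lr <- sweep(lr, 2L, apply(lr, 2L, stats::median, na.rm = TRUE))
  for (j in seq_along(design$channel)) quant[[design$channel[j]]] <- lr[, j]
  class(quant) <- c("protein_quant", "data.frame")
  attr(quant, "design") <- design
  attr(quant, "rejected") <- rejected
  attr(quant, "n_dropped_missing") <- n_dropped
  attr(quant, "log2_mode") <- TRUE
  quant
}
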