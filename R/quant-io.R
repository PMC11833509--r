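#' Read a protein quantification table
#'
#' Reads a TSV/CSV table of protein-level TMT quantifications.  Required
#' columns (renameable through `col_map`): a protein identifier, a gene
#' symbol, a unique-peptide count, and one value column per design channel.
#'
#' @param path path to a tab- or comma-separated table (delimiter inferred
#'   from the extension, `.csv` = comma, otherwise tab).
#' @param design a [tmt_design()] object; channel value columns must match
#'   `design$channel` (after `col_map` renaming).
#' @param col_map optional named character vector mapping standard names
#'   (`protein_id`, `gene_symbol`, `unique_peptides`, and channel labels)
#'   to the column names actually present in the file.
#' @return A `protein_quant` data.frame with columns `protein_id`,
#'   `gene_symbol`, `unique_peptides`, then one numeric column per channel.
#' @export
read_protein_quant <- function(path, design, col_map = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(tab))
      if (is.na(j)) stop("mapped column not found in table: ", col_map[[std]])
      names(tab)[j] <- std
    }
  }
  protein_quant(tab, design)
}

#' Validate and class a protein quantification table
#'
#' @param tab data.frame with columns `protein_id`, `gene_symbol`,
#'   `unique_peptides`, and one numeric column per design channel.
#' @param design a [tmt_design()] object.
#' @return the validated data.frame, classed `protein_quant`.
#' @export
protein_quant <- function(tab, design) {
  need <- c("protein_id", "gene_symbol", "unique_peptides", design$channel)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[, need]
  tab$protein_id <- as.character(tab$protein_id)
  tab$gene_symbol <- as.character(tab$gene_symbol)
  tab$unique_peptides <- as.integer(tab$unique_peptides)
  if (any(tab$unique_peptides < 0, na.rm = TRUE))
    stop("unique_peptides must be non-negative")
  if (anyDuplicated(tab$protein_id))
    stop("duplicated protein_id values")
  for (ch in design$channel) tab[[ch]] <- as.numeric(tab[[ch]])
  class(tab) <- c("protein_quant", "data.frame")
  attr(tab, "design") <- design
  tab
}

#' Channel value matrix of a protein_quant table
#' @param quant a `protein_quant` data.frame.
#' @return numeric matrix, proteins x channels, rownames = protein_id.
#' @export
quant_values <- function(quant) {
  design <- attr(quant, "design")
  m <- as.matrix(quant[, design$channel, drop = FALSE])
  rownames(m) <- quant$protein_id
  m
}
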