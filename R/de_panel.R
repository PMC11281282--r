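#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values, with
#' monotonicity enforcement and capping at 1 (the standard BH procedure, as
#' implemented by [stats::p.adjust()]). Inputs outside \[0, 1\] are an error.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance filter for differential-expression tables
#'
#' Applies the fold-change and adjusted-p thresholds used to call
#' significantly altered genes: a row is kept iff `|log2fc| > lfcAbsMin`
#' (strict; the default 0.5 corresponds to a ~1.4-fold change in either
#' direction) and `padj <= padjMax` (non-strict), and - when a panel is
#' given - its symbol belongs to the panel. Rows are returned sorted by
#' log2 fold change, descending.
#'
#' @param rows data.frame with columns `symbol`, `log2fc`, `padj` (e.g. from
#'   [simulateDeTable()] or [readDeTable()]); symbols must be unique.
#' @param panel optional character vector of gene symbols, or the name of a
#'   shipped panel (see [genePanels()]).
#' @param lfcAbsMin minimum absolute log2 fold change (exclusive).
#' @param padjMax maximum adjusted p-value (inclusive).
#' @return the retained rows, sorted by `log2fc` descending.
#' @export
filterSignificant <- function(rows, panel = NULL, lfcAbsMin = 0.5,
                              padjMax = 0.05) {
  need <- c("symbol", "log2fc", "padj")
  if (!all(need %in% names(rows)))
    stop("'rows' must have columns ", paste(need, collapse = ", "))
  if (lfcAbsMin <= 0 || padjMax <= 0)
    stop("thresholds must be > 0")
  if (anyDuplicated(rows$symbol))
    stop("duplicate gene symbols in input: ",
         paste(unique(rows$symbol[duplicated(rows$symbol)]), collapse = ", "))
  if (!is.null(panel)) {
    if (length(panel) == 1L && panel %in% names(genePanels()))
      panel <- genePanels()[[panel]]
    rows <- rows[rows$symbol %in% panel, , drop = FALSE]
  }
  keep <- abs(rows$log2fc) > lfcAbsMin & rows$padj <= padjMax
  out <- rows[keep, , drop = FALSE]
  out <- out[order(out$log2fc, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a log2 fold change to a linear fold change
#'
#' @param log2fc numeric log2 fold change(s).
#' @return `2^log2fc`; e.g. 0.5 gives ~1.4, 2.63 gives ~6.2 (a roughly
#'   six-fold change).
#' @examples
#' log2fcToFold(c(0, 0.5, 2.63))
#' @export
log2fcToFold <- function(log2fc) {
  stopifnot(all(is.finite(log2fc)))
  2^log2fc
}

#' Curated gene panels
#'
#' Symbol lists of the four curated panels shipped with the package: ECM
#' proteins, cancer-associated fibroblast (CAF) markers, immune checkpoints,
#' and T-cell/immune-cytokine markers.
#'
#' @return named list of character vectors (`ECM`, `CAF`,
#'   `immune_checkpoint`, `T_cell`).
#' @export
genePanels <- function() {
  tab <- examplePanelDeTable()
  split(tab$symbol, tab$panel)[c("ECM", "CAF", "immune_checkpoint",
                                 "T_cell")]
}

#' Example panel differential-expression table
#'
#' The curated ECM / CAF / immune-checkpoint / T-cell panel with log2 fold
#' changes between noninvasive and invasive stage IA lung adenocarcinoma
#' (GEO accession GSE166720, differential expression as computed by GEO2R),
#' shipped as a plain-text fixture. 39 genes; positive log2fc means higher
#' expression in the invasive group.
#'
#' @return data.frame with columns `panel`, `description`, `symbol`,
#'   `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
examplePanelDeTable <- function() {
  path <- system.file("extdata", "gse166720_panel_de.tsv",
                      package = "shgfiber", mustWork = TRUE)
  readDeTable(path)
}

#' Read / write a differential-expression table
#'
#' Tab-separated tables with at least the columns `symbol`, `log2fc`,
#' `pvalue`, `padj` (extra columns such as `panel`, `description`, `gene_id`
#' are carried through).
#'
#' @param path file path.
#' @param rows data.frame to write.
#' @return `readDeTable` returns a data.frame; `writeDeTable` returns the
#'   path invisibly.
#' @export
readDeTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "log2fc", "pvalue", "padj")
  if (!all(need %in% names(tab)))
    stop("DE table must have columns ", paste(need, collapse = ", "))
  tab
}

#' @rdname readDeTable
#' @export
writeDeTable <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
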