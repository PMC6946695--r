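#' Two-condition omics data container
#'
#' Per-gene expression fold-changes with FDR and per-metabolite abundance
#' ratios for a perturbed/reference condition pair (e.g. stationary vs
#' exponential phase, or sand vs liquid).
#'
#' @param genes data.frame with columns `gene_id`, `log2fc` (log2
#'   perturbed/reference), `fdr`.
#' @param metabolites data.frame with columns `metabolite_id`, `ratio`
#'   (perturbed/reference, > 0), `significant` (logical).
#' @return object of class `omics_data`.
#' @export
omics_data <- function(genes = NULL, metabolites = NULL) {
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), log2fc = numeric(),
                        fdr = numeric())
  if (is.null(metabolites))
    metabolites <- data.frame(metabolite_id = character(), ratio = numeric(),
                              significant = logical())
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(genes)),
            all(c("metabolite_id", "ratio", "significant") %in%
                  names(metabolites)))
  if (any(metabolites$ratio <= 0))
    stop("metabolite abundance ratios must be positive")
  if (any(genes$fdr < 0 | genes$fdr > 1))
    stop("FDR values must lie in [0, 1]")
  structure(list(genes = genes, metabolites = metabolites),
            class = "omics_data")
}

#' @exportS3Method base::print
print.omics_data <- function(x, ...) {
  cat("<omics_data> ", nrow(x$genes), " gene records, ",
      nrow(x$metabolites), " metabolite records\n", sep = "")
  invisible(x)
}

#' Read/write omics tables
#'
#' Gene table columns: `gene_id`, `log2fc`, `fdr`. Metabolite table
#' columns: `metabolite_id`, `ratio`, `significant`.
#'
#' @param genes_path,metabolites_path TSV paths (either may be `NULL`).
#' @export
read_omics_tsv <- function(genes_path = NULL, metabolites_path = NULL) {
  g <- if (!is.null(genes_path))
    read.delim(genes_path, stringsAsFactors = FALSE) else NULL
  m <- if (!is.null(metabolites_path))
    read.delim(metabolites_path, stringsAsFactors = FALSE) else NULL
  if (!is.null(m)) m$significant <- as.logical(m$significant)
  omics_data(g, m)
}

#' @rdname read_omics_tsv
#' @param omics an [omics_data()].
#' @export
write_omics_tsv <- function(omics, genes_path = NULL,
                            metabolites_path = NULL) {
  if (!is.null(genes_path))
    write.table(omics$genes, genes_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  if (!is.null(metabolites_path))
    write.table(omics$metabolites, metabolites_path, sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(omics)
}
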