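#' Genes-by-cells expression matrix with cell metadata
#'
#' The shared container for calibration, correlation diagnostics and
#' matrix-mode simulation. Genes are rows, cells are columns; metadata is
#' keyed by cell id and aligned to the columns.
#'
#' @param counts Numeric genes x cells matrix, non-negative. Row names are
#'   used as gene ids if \code{gene_ids} is missing.
#' @param cell_metadata Data frame with columns \code{cell_id},
#'   \code{individual_id} and optionally \code{group} and \code{cell_type},
#'   one row per column of \code{counts}.
#' @param gene_ids Optional character vector of gene identifiers.
#' @return An object of class \code{"multigene_matrix"} with elements
#'   \code{counts}, \code{gene_ids}, \code{cell_metadata}.
#' @export
multigene_matrix <- function(counts, cell_metadata, gene_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("expression matrix contains negative entries")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(counts)
    if (is.null(gene_ids))
      gene_ids <- if (nrow(counts)) paste0("gene", seq_len(nrow(counts)))
                  else character(0)
  }
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length does not match the number of rows")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  cell_metadata <- as.data.frame(cell_metadata)
  req <- c("cell_id", "individual_id")
  if (!all(req %in% names(cell_metadata)))
    stop("cell_metadata needs columns: ", paste(req, collapse = ", "))
  if (nrow(cell_metadata) != ncol(counts))
    stop("metadata rows (", nrow(cell_metadata),
         ") do not match matrix columns (", ncol(counts), ")")
  if (anyDuplicated(cell_metadata$cell_id)) stop("duplicate cell ids")
  cell_metadata$cell_id <- as.character(cell_metadata$cell_id)
  cell_metadata$individual_id <- as.character(cell_metadata$individual_id)
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_metadata$cell_id
  structure(list(counts = counts, gene_ids = gene_ids,
                 cell_metadata = cell_metadata),
            class = "multigene_matrix")
}

#' @export
print.multigene_matrix <- function(x, ...) {
  md <- x$cell_metadata
  cat(sprintf("multigene_matrix: %d genes x %d cells, %d individuals\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(md$individual_id))))
  if (!is.null(md$group))
    cat("  groups: ", paste(names(table(md$group)), table(md$group),
                            sep = "=", collapse = ", "), "\n")
  if (!is.null(md$cell_type))
    cat("  cell types:", length(unique(md$cell_type)), "\n")
  invisible(x)
}

#' @export
dim.multigene_matrix <- function(x) dim(x$counts)

# Subset a multigene_matrix by gene and/or cell index (internal).
subset_matrix <- function(x, genes = NULL, cells = NULL) {
  counts <- x$counts
  md <- x$cell_metadata
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(cells)) {
    counts <- counts[, cells, drop = FALSE]
    md <- md[cells, , drop = FALSE]
  }
  multigene_matrix(counts, md)
}
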