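# Readers and writers: genes-as-rows CSV/TSV or MatrixMarket matrices with
# a cell-metadata sidecar, tidy report tables, and run manifests.

#' Read a genes-by-cells expression matrix with cell metadata
#'
#' Accepts a delimited file (genes as rows, header row of cell ids, first
#' column gene ids) or a MatrixMarket \code{.mtx} file with
#' \code{<stem>_genes.tsv} / \code{<stem>_cells.tsv} sidecars (one id per
#' line). Metadata rows are aligned to the matrix columns by cell id;
#' cells without metadata are an error naming the offenders.
#'
#' @param path Matrix file (\code{.csv}, \code{.tsv}/\code{.txt} or
#'   \code{.mtx}).
#' @param metadata_path TSV with columns \code{cell_id},
#'   \code{individual_id}, optional \code{group}, \code{cell_type}.
#' @return A [multigene_matrix()].
#' @export
read_expression_matrix <- function(path, metadata_path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    counts <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    gene_ids <- readLines(paste0(stem, "_genes.tsv"))
    cell_ids <- readLines(paste0(stem, "_cells.tsv"))
    if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
      stop("sidecar id files do not match matrix dimensions")
    rownames(counts) <- gene_ids
    colnames(counts) <- cell_ids
  } else {
    sep <- if (ext == "csv") "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             row.names = 1, check.names = FALSE,
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab)
  }
  if (any(counts < 0)) stop("matrix contains negative values")

  md <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("cell_id", "individual_id") %in% names(md)))
    stop("metadata needs cell_id and individual_id columns")
  missing <- setdiff(colnames(counts), md$cell_id)
  if (length(missing))
    stop("cells missing from metadata: ",
         paste(utils::head(missing, 10), collapse = ", "))
  md <- md[match(colnames(counts), md$cell_id), , drop = FALSE]
  multigene_matrix(counts, md)
}

#' Write a multigene matrix (and truth, if present) to disk
#'
#' Writes the matrix as TSV (genes as rows), the metadata as TSV, and the
#' simulation truth table (if attached) as TSV.
#'
#' @param matrix A [multigene_matrix()].
#' @param stem Output path stem; files \code{<stem>_matrix.tsv},
#'   \code{<stem>_metadata.tsv} and optionally \code{<stem>_truth.tsv}
#'   are written.
#' @return Character vector of written paths, invisibly.
#' @export
write_expression_matrix <- function(matrix, stem) {
  stopifnot(inherits(matrix, "multigene_matrix"))
  paths <- paste0(stem, c("_matrix.tsv", "_metadata.tsv"))
  utils::write.table(matrix$counts, paths[1], sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(matrix$cell_metadata, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- attr(matrix, "truth")
  if (!is.null(truth)) {
    p <- paste0(stem, "_truth.tsv")
    utils::write.table(truth, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a tidy report table
#'
#' @param table Data frame.
#' @param path Output path.
#' @param format \code{"tsv"} (default) or \code{"json"}. Round-trips
#'   parse-equal.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' @param path Output JSON path.
#' @param seed Master seed used.
#' @param settings Named list of run settings (grid, methods, ...).
#' @param params Optional [calibration_params()]; stored flat.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, seed, settings = list(), params = NULL) {
  manifest <- list(
    package = "scdesim",
    version = as.character(utils::packageVersion("scdesim")),
    seed = seed, settings = settings)
  if (!is.null(params)) manifest$calibration <- unclass(params)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a packaged synthetic fixture
#'
#' Deterministic stand-ins for reference data, small enough for tests:
#' \code{"hierarchical"} simulates from the packaged default calibration
#' (inter-individual variance present), \code{"iid"} collapses the
#' hierarchy (\code{f1 = 0}, negative control) and
#' \code{"two-group-signal"} spikes known fold changes into half the
#' genes.
#'
#' @param kind \code{"hierarchical"}, \code{"iid"} or
#'   \code{"two-group-signal"}.
#' @param seed Integer seed; fixed seed gives a byte-identical fixture.
#' @param n_genes,n_per_group,expected_cells Fixture dimensions (defaults
#'   200 genes, 10 individuals per group, 100 expected cells).
#' @return A [multigene_matrix()] with a \code{truth} attribute.
#' @export
generate_fixture <- function(kind = c("hierarchical", "iid",
                                      "two-group-signal"),
                             seed = 1L, n_genes = 200, n_per_group = 10,
                             expected_cells = 100) {
  kind <- match.arg(kind)
  params <- calibration_default()
  if (kind == "iid") {
    params$f1_intercept <- 0
    params$f1_slope <- 0
  }
  design <- design_spec(n_per_group = n_per_group,
                        cell_count_model = "POISSON",
                        expected_cells = expected_cells)
  fcs <- NULL
  if (kind == "two-group-signal") {
    fcs <- rep(1, n_genes)
    fcs[seq_len(n_genes %/% 2)] <- rep(c(1.5, 2, 3), length.out = n_genes %/% 2)
  }
  simulate_matrix(params, design, n_genes = n_genes,
                  fold_changes = fcs, seed = seed)
}
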