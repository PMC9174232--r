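#' Expression matrix container
#'
#' A light container for a gene-by-cell nonnegative expression matrix
#' (FPKM/RPKM or normalised counts) with optional per-cell metadata.
#' Most functions in the package accept either an `sc_expr` object or a bare
#' numeric matrix with gene row names and cell column names.
#'
#' @param values numeric matrix, genes in rows, cells in columns; row and
#'   column names must be unique and non-empty; entries must be nonnegative.
#' @param cell_meta optional data.frame keyed by `cell_id` (or with row names
#'   equal to the cell ids) carrying condition, genotype and optionally
#'   cell-type labels.
#' @return an object of class `sc_expr`: a list with elements `values` and
#'   `cell_meta`.
#' @export
sc_expr <- function(values, cell_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x cells)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and cell column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell ids in expression matrix")
  if (any(values < 0))
    stop("expression values must be nonnegative")
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if (!is.null(cell_meta$cell_id)) {
      rownames(cell_meta) <- cell_meta$cell_id
    }
    missing <- setdiff(colnames(values), rownames(cell_meta))
    if (length(missing))
      stop("cell_meta does not cover all cells (missing e.g. ",
           missing[1L], ")")
    cell_meta <- cell_meta[colnames(values), , drop = FALSE]
  }
  structure(list(values = values, cell_meta = cell_meta),
            class = "sc_expr")
}

#' @export
print.sc_expr <- function(x, ...) {
  cat("sc_expr: ", nrow(x$values), " genes x ", ncol(x$values), " cells\n",
      sep = "")
  if (!is.null(x$cell_meta))
    cat("cell metadata: ", paste(colnames(x$cell_meta), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
dim.sc_expr <- function(x) dim(x$values)

# Accept sc_expr or bare matrix everywhere.
expr_values <- function(x) {
  if (inherits(x, "sc_expr")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an 'sc_expr' object or a numeric matrix")
}

expr_meta <- function(x) if (inherits(x, "sc_expr")) x$cell_meta else NULL

# Rebuild an object of the same flavour as the input after subsetting.
expr_like <- function(x, values, cells = colnames(values)) {
  if (inherits(x, "sc_expr")) {
    meta <- x$cell_meta
    if (!is.null(meta)) meta <- meta[cells, , drop = FALSE]
    sc_expr(values, meta)
  } else values
}
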