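#' Construct a validated expression matrix
#'
#' The substrate of all transcriptome stages: a cells x genes matrix of
#' non-negative RPKM values together with one experimental group label per
#' cell (see [timecourse_groups()]).
#'
#' @param values Numeric matrix, cells in rows and genes in columns, with
#'   row and column names giving the cell and gene identifiers.
#' @param cell_groups Character or factor, one group label per cell, each a
#'   member of `timecourse_groups()`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `cell_groups` (a factor with the six group
#'   levels in temporal order).
#' @export
expression_matrix <- function(values, cell_groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (cells x genes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry cell ids as rownames and gene ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("expression values must not contain NA")
  if (any(values < 0)) stop("expression values must be non-negative (RPKM)")
  if (length(cell_groups) != nrow(values))
    stop("`cell_groups` length (", length(cell_groups),
         ") does not match the number of cells (", nrow(values), ")")
  cg <- as.character(cell_groups)
  bad <- setdiff(unique(cg), timecourse_groups())
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  structure(
    list(values = values,
         cell_groups = factor(cg, levels = timecourse_groups())),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "cells x", ncol(x$values), "genes\n")
  cat("groups:", paste(sprintf("%s=%d", levels(x$cell_groups),
                               tabulate(x$cell_groups, nbins = nlevels(x$cell_groups))),
                       collapse = " "), "\n")
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by cells
#'
#' @param x An `ExpressionMatrix`.
#' @param cells Logical, integer or character index into the cells.
#' @return A new `ExpressionMatrix` containing only the selected cells.
#' @export
subset_cells <- function(x, cells) {
  expression_matrix(x$values[cells, , drop = FALSE],
                    as.character(x$cell_groups)[
                      if (is.character(cells)) match(cells, cell_ids(x)) else cells])
}

# Indices of cells belonging to the post-TAC groups.
tac_cell_idx <- function(x) which(as.character(x$cell_groups) %in% tac_groups())
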