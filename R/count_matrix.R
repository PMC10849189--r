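#' Cell-by-gene count matrix with group metadata
#'
#' Container for a scCRISPR-seq expression matrix (cells in rows, genes in
#' columns), tagged as control (non-targeting gRNAs) or perturbation group,
#' optionally carrying the cell-to-gRNA and gRNA-to-target assignments.
#'
#' @param values numeric matrix, cells x genes, finite and non-negative.
#' @param cell_ids,gene_ids character vectors; default to the dimnames of
#'   `values`. Must be free of duplicates.
#' @param group_label `"control"` or `"perturbation"`.
#' @param grna_assignment optional named character vector mapping cell id to
#'   gRNA id; every name must be a cell id of this matrix.
#' @param target_assignment optional named character vector mapping gRNA id
#'   to target gene.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(values, cell_ids = rownames(values),
                         gene_ids = colnames(values),
                         group_label = c("control", "perturbation"),
                         grna_assignment = NULL, target_assignment = NULL) {
  group_label <- match.arg(group_label)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    .stop2("cell_ids/gene_ids lengths do not match the matrix dimensions")
  if (anyDuplicated(cell_ids)) .stop2("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) .stop2("duplicate gene_ids")
  if (!all(is.finite(values))) .stop2("values must be finite")
  if (any(values < 0)) .stop2("values must be non-negative")
  dimnames(values) <- list(cell_ids, gene_ids)
  if (!is.null(grna_assignment)) {
    grna_assignment <- vapply(grna_assignment, as.character, "")
    missing_cells <- setdiff(names(grna_assignment), cell_ids)
    if (length(missing_cells))
      .stop2("grna_assignment refers to unknown cells: ",
             paste(head(missing_cells, 5L), collapse = ", "))
  }
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 group_label = group_label,
                 grna_assignment = grna_assignment,
                 target_assignment = target_assignment),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes (%s group)\n",
              nrow(x$values), ncol(x$values), x$group_label))
  if (!is.null(x$grna_assignment))
    cat(sprintf("  gRNA assignment for %d cells (%d gRNAs)\n",
                length(x$grna_assignment),
                length(unique(x$grna_assignment))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a dense cell-by-gene matrix from CSV/TSV
#'
#' First column holds cell ids, remaining columns one gene each (header row
#' gives gene ids). The separator is inferred by [data.table::fread].
#'
#' @param path file path.
#' @inheritParams count_matrix
#' @param ... passed on to [count_matrix()].
#' @return a [count_matrix].
#' @export
read_counts_csv <- function(path, group_label = "control", ...) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) .stop2("expected a cell-id column plus gene columns: ", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  count_matrix(m, group_label = group_label, ...)
}

#' Write a count matrix as CSV (cells in rows)
#' @param x a [count_matrix].
#' @param path output file.
#' @export
write_counts_csv <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  dt <- data.table::data.table(cell_id = x$cell_ids)
  dt <- cbind(dt, data.table::as.data.table(x$values))
  data.table::fwrite(dt, path, sep = ",")
  invisible(path)
}

#' Read a sparse matrix-market matrix with 10x-style sidecars
#'
#' Expects the triplet layout used by 10x Genomics exports: a matrix-market
#' file with genes in rows and cells in columns, plus `barcodes.tsv` (cell
#' ids) and `features.tsv` (gene ids in the first column). The matrix is
#' transposed to cells x genes on load.
#'
#' @param mtx path to the `.mtx` file, or a directory containing
#'   `matrix.mtx`, `barcodes.tsv` and `features.tsv`.
#' @param barcodes,features optional explicit sidecar paths.
#' @inheritParams read_counts_csv
#' @return a [count_matrix].
#' @export
read_counts_mtx <- function(mtx, barcodes = NULL, features = NULL,
                            group_label = "control", ...) {
  if (dir.exists(mtx)) {
    barcodes <- barcodes %||% file.path(mtx, "barcodes.tsv")
    features <- features %||% file.path(mtx, "features.tsv")
    mtx <- file.path(mtx, "matrix.mtx")
  }
  if (is.null(barcodes) || is.null(features))
    .stop2("barcodes/features sidecar paths are required")
  m <- Matrix::readMM(mtx)
  cells <- read.table(barcodes, sep = "\t", header = FALSE,
                      colClasses = "character")[[1L]]
  genes <- read.table(features, sep = "\t", header = FALSE,
                      colClasses = "character")[[1L]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    .stop2("matrix dimensions do not match the sidecar files")
  dense <- as.matrix(Matrix::t(m))
  rownames(dense) <- cells; colnames(dense) <- genes
  count_matrix(dense, group_label = group_label, ...)
}

#' Write a count matrix in matrix-market triplet form with sidecars
#' @param x a [count_matrix].
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `barcodes.tsv`, `features.tsv` in the genes x cells orientation.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(x$values), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(x$gene_ids, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a cell-to-gRNA assignment table
#'
#' Tab-separated file with columns `cell_id`, `grna_id`, `target`.
#'
#' @param path file path.
#' @return list with `grna_assignment` (cell id -> gRNA id) and
#'   `target_assignment` (gRNA id -> target gene).
#' @export
read_grna_assignment <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  need <- c("cell_id", "grna_id", "target")
  if (!all(need %in% names(dt)))
    .stop2("assignment table must have columns: ", paste(need, collapse = ", "))
  ta <- unique(dt[, c("grna_id", "target")])
  if (anyDuplicated(ta$grna_id))
    .stop2("a gRNA maps to several targets in ", path)
  list(grna_assignment = setNames(dt$grna_id, dt$cell_id),
       target_assignment = setNames(ta$target, ta$grna_id))
}

#' Read gene sets (one per line: name, tab, comma-separated gene symbols)
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) .stop2("malformed gene-set line(s): ", which(bad)[1L])
  setNames(lapply(parts, function(p) {
    unique(trimws(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]))
  }), vapply(parts, `[[`, "", 1L))
}

#' Split a perturbation matrix into per-gRNA or per-target groups
#'
#' @param x a perturbation [count_matrix] whose `grna_assignment` covers the
#'   cells to keep (unassigned cells are dropped).
#' @param group_by pool cells by `"target"` gene (all gRNAs against one gene
#'   form one perturbation group) or keep each `"grna"` separate.
#' @return named list of [count_matrix] objects.
#' @export
split_by_group <- function(x, group_by = c("target", "grna")) {
  stopifnot(inherits(x, "count_matrix"))
  group_by <- match.arg(group_by)
  if (is.null(x$grna_assignment))
    .stop2("no gRNA assignment available; supply one to group perturbation cells")
  cells <- intersect(x$cell_ids, names(x$grna_assignment))
  key <- x$grna_assignment[cells]
  if (group_by == "target") {
    if (is.null(x$target_assignment))
      .stop2("group_by = \"target\" requires a gRNA-to-target assignment")
    unknown <- setdiff(unique(key), names(x$target_assignment))
    if (length(unknown))
      .stop2("gRNAs without target annotation: ",
             paste(head(unknown, 5L), collapse = ", "))
    key <- x$target_assignment[key]
  }
  lapply(split(cells, key), function(cc) {
    count_matrix(x$values[cc, , drop = FALSE], group_label = "perturbation",
                 grna_assignment = x$grna_assignment[cc],
                 target_assignment = x$target_assignment)
  })
}
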