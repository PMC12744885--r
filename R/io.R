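## On-disk exchange formats: bulk TSV tables, Matrix-Market single-cell
## directories, ImageJ-compatible text images, and partition TSVs.

#' Read a bulk expression table from TSV
#'
#' Reads a tab-separated expression table as distributed by expression
#' compendia (one header row, first column = labels) into the internal
#' genes x samples orientation.  Atlas downloads typically list samples as
#' rows and genes as columns, which is the default orientation.
#'
#' @param path path to a TSV file with a header row.
#' @param orientation `"samples_as_rows"` (default; header = gene ids,
#'   first column = sample labels) or `"genes_as_rows"` (header = sample
#'   labels, first column = gene ids).
#' @return A genes x samples numeric matrix with gene row names and sample
#'   column names, all values finite and nonnegative.
#' @details Non-numeric body cells raise an error naming the offending row
#'   and column; duplicated gene ids (e.g. per-probeset multiplicity) are an
#'   error listing the ids, never silently aggregated.  Row and column
#'   order of the source file is preserved.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "gA\t1\t2", "gB\t3\t4"), tf)
#' readBulkTable(tf, orientation = "genes_as_rows")
#' @export
readBulkTable <- function(path,
                          orientation = c("samples_as_rows",
                                          "genes_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("expected a label column plus numeric columns")
  labels <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]], labels[bad[1L, 1L]],
                 colnames(body)[bad[1L, 2L]]))
  if (anyNA(num)) stop("missing values are not allowed in bulk tables")
  dimnames(num) <- list(labels, colnames(body))
  tab <- if (orientation == "samples_as_rows") t(num) else num
  assertBulkTable(tab, "parsed table")
  tab
}

#' Write a bulk expression table to TSV
#'
#' Inverse of [readBulkTable()]: emits a header row plus one label column,
#' in the requested orientation.
#'
#' @param table genes x samples numeric matrix.
#' @param path output file path.
#' @inheritParams readBulkTable
#' @return Invisibly, `path`.
#' @export
writeBulkTable <- function(table, path,
                           orientation = c("samples_as_rows",
                                           "genes_as_rows")) {
  orientation <- match.arg(orientation)
  assertBulkTable(table)
  out <- if (orientation == "samples_as_rows") t(table) else table
  df <- data.frame(label = rownames(out), out, check.names = FALSE)
  names(df)[1L] <- if (orientation == "samples_as_rows") "sample" else "gene"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sparse single-cell counts from a Matrix-Market directory
#'
#' Expects the conventional sparse-counts layout: `matrix.mtx` (genes x
#' cells, Matrix-Market coordinate format), `features.tsv` (gene ids, one
#' per matrix row), `barcodes.tsv` (cell ids, one per matrix column) and
#' `annotations.tsv` (header `cell_id<TAB>group`).  Counts are returned in
#' the internal cells x genes orientation.
#'
#' @param dir directory containing the four files.
#' @param permissive if `TRUE`, cells absent from `annotations.tsv` are
#'   assigned group `"unannotated"` instead of raising an error.
#' @return A \linkS4class{SingleCellCounts}.
#' @examples
#' sim <- simulateSingleCell(nGroups = 2, cellsPerGroup = 50, nGenes = 30,
#'                           cooccGroups = "group1", seed = 7)
#' d <- tempfile(); writeSparseCounts(sim$counts, d)
#' sc <- readSparseCounts(d)
#' identical(scCounts(sc), scCounts(sim$counts))
#' @export
readSparseCounts <- function(dir, permissive = FALSE) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "annotations.tsv")
  paths <- file.path(dir, need)
  if (!all(file.exists(paths)))
    stop("missing file(s): ", paste(need[!file.exists(paths)], collapse = ", "))
  m <- as(Matrix::readMM(paths[1L]), "CsparseMatrix")
  genes <- readLines(paths[2L])
  cells <- readLines(paths[3L])
  if (nrow(m) != length(genes))
    stop(sprintf("matrix has %d rows but features.tsv lists %d genes",
                 nrow(m), length(genes)))
  if (ncol(m) != length(cells))
    stop(sprintf("matrix has %d columns but barcodes.tsv lists %d cells",
                 ncol(m), length(cells)))
  ann <- read.delim(paths[4L], header = TRUE, sep = "\t",
                    colClasses = "character")
  if (!all(c("cell_id", "group") %in% names(ann)))
    stop("annotations.tsv must have columns 'cell_id' and 'group'")
  if (anyDuplicated(ann$cell_id))
    stop("duplicate cell_id in annotations.tsv")
  groups <- setNames(ann$group, ann$cell_id)[cells]
  if (anyNA(groups)) {
    if (!permissive)
      stop(sprintf("%d cell(s) lack an annotation row (e.g. '%s'); ",
                   sum(is.na(groups)), cells[which(is.na(groups))[1L]]),
           "use permissive = TRUE to label them 'unannotated'")
    groups[is.na(groups)] <- "unannotated"
  }
  dimnames(m) <- list(genes, cells)
  SingleCellCounts(t(m), setNames(as.character(groups), cells))
}

#' Write sparse single-cell counts to a Matrix-Market directory
#'
#' Inverse of [readSparseCounts()]; writes `matrix.mtx` in genes x cells
#' orientation plus the three label files.
#'
#' @param sc a \linkS4class{SingleCellCounts}.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeSparseCounts <- function(sc, dir) {
  stopifnot(is(sc, "SingleCellCounts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(t(scCounts(sc)), file.path(dir, "matrix.mtx"))
  writeLines(geneIDs(sc), file.path(dir, "features.tsv"))
  writeLines(cellIDs(sc), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(cell_id = cellIDs(sc),
                         group = as.character(cellGroups(sc))),
              file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a brightness-coded matrix as an ImageJ text image
#'
#' Writes a matrix of values in [0, 1] as plain whitespace-delimited numeric
#' rows, one matrix row per line, no header: the dialect ImageJ/Fiji's
#' File > Import > "Text Image..." command accepts.  Values are printed with
#' up to 6 significant digits, trailing zeros trimmed.
#'
#' @param matrix numeric matrix with all entries finite and in [0, 1]
#'   (normalise first, e.g. with [maxNormalize()]).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeTextImage(rbind(c(0, 1), c(0.5, 0.25)), tf)
#' readLines(tf)
#' @export
writeTextImage <- function(matrix, path) {
  if (!is.matrix(matrix) || !is.numeric(matrix) || length(matrix) == 0L)
    stop("'matrix' must be a non-empty numeric matrix")
  if (any(!is.finite(matrix)))
    stop("all entries must be finite")
  if (any(matrix < 0) || any(matrix > 1))
    stop("entries outside [0, 1]; normalise the matrix first")
  lines <- apply(matrix, 1L, function(row)
    paste(formatCompact(row), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write module partitions as TSV
#'
#' A partition file has a header and three columns: `group`, `gene_id`,
#' `module_label`, with `"unassigned"` as the reserved label for genes not
#' in any module.  A gene appearing twice within one group is an error.
#'
#' @param path file path.
#' @param partition a \linkS4class{ModulePartition}.
#' @param minModuleSize size floor recorded on the object when reading.
#' @return `readPartition()`: a \linkS4class{ModulePartition};
#'   `writePartition()`: invisibly, `path`.
#' @export
readPartition <- function(path, minModuleSize = 10L) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character")
  if (!all(c("group", "gene_id", "module_label") %in% names(df)))
    stop("partition file needs columns group, gene_id, module_label")
  dup <- duplicated(df[c("group", "gene_id")])
  if (any(dup))
    stop("duplicate (group, gene) row(s): ",
         paste(unique(sprintf("(%s, %s)", df$group[dup], df$gene_id[dup])),
               collapse = ", "))
  groups <- unique(df$group)
  assignments <- lapply(groups, function(g) {
    sub <- df[df$group == g, ]
    setNames(sub$module_label, sub$gene_id)
  })
  names(assignments) <- groups
  ModulePartition(assignments, minModuleSize)
}

#' @rdname readPartition
#' @export
writePartition <- function(partition, path) {
  stopifnot(is(partition, "ModulePartition"))
  rows <- do.call(rbind, lapply(partitionGroups(partition), function(g) {
    a <- moduleAssignments(partition)[[g]]
    data.frame(group = g, gene_id = names(a), module_label = unname(a))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
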