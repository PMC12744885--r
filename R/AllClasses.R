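## Central S4 containers.  Orientation conventions used throughout:
##   - bulk tables:      genes x samples   (plain numeric matrix, dimnames set)
##   - single-cell:      cells x genes     (sparse dgCMatrix)
##   - metacell/normalised matrices: (meta)cells x genes (dense matrix)

#' Sparse single-cell counts with cell-type annotation
#'
#' Cells x genes nonnegative integer counts stored as a
#' \linkS4class{dgCMatrix}, plus one group (cell-type) label per cell.
#'
#' @slot counts cells x genes sparse matrix of nonnegative integers with
#'   unique row (cell) and column (gene) names.
#' @slot groups factor of cell-type labels, one per cell, named by cell id.
#'
#' @seealso [SingleCellCounts()] for the validating constructor,
#'   [readSparseCounts()] / [writeSparseCounts()] for on-disk exchange.
#' @exportClass SingleCellCounts
setClass("SingleCellCounts",
         slots = c(counts = "dgCMatrix", groups = "factor"))

setValidity("SingleCellCounts", function(object) {
  m <- object@counts
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have cell (row) and gene (column) names")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate cell ids")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate gene ids")
  }
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x))))
    msg <- c(msg, "counts must be nonnegative integers")
  if (length(object@groups) != nrow(m))
    msg <- c(msg, "need exactly one group label per cell")
  else if (!identical(names(object@groups), rownames(m)))
    msg <- c(msg, "group labels must be named by cell id, in matrix order")
  if (anyNA(object@groups)) msg <- c(msg, "group labels must not be NA")
  if (length(msg)) msg else TRUE
})

#' Construct a SingleCellCounts object
#'
#' @param counts cells x genes matrix (coerced to sparse) of nonnegative
#'   integer counts; row and column names required.
#' @param groups character or factor of cell-type labels, one per cell,
#'   either named by cell id or in row order.
#' @return A validated \linkS4class{SingleCellCounts} object.
#' @examples
#' m <- Matrix::Matrix(matrix(rpois(12, 1), 4, 3,
#'        dimnames = list(paste0("c", 1:4), paste0("g", 1:3))), sparse = TRUE)
#' sc <- SingleCellCounts(m, rep(c("typeA", "typeB"), each = 2))
#' cellGroups(sc)
#' @export
SingleCellCounts <- function(counts, groups) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(names(groups))) {
    stopifnot(length(groups) == nrow(counts))
    groups <- setNames(groups, rownames(counts))
  }
  groups <- groups[rownames(counts)]
  new("SingleCellCounts", counts = counts,
      groups = as.factor(setNames(as.character(groups), rownames(counts))))
}

#' Metacells: aggregated neighbourhoods of cells
#'
#' A set of metacells built per annotated group: each metacell is the average
#' of the raw counts of exactly \code{k} transcriptionally neighbouring
#' cells, with the pairwise overlap of member lists within a group capped at
#' \code{max_shared} cells.
#'
#' @slot expression metacells x genes matrix of mean raw counts.
#' @slot members named list: metacell id -> character vector of member cell
#'   ids (length \code{k}).
#' @slot groupOf named character: metacell id -> group label.
#' @slot params list with elements \code{k}, \code{maxShared}, \code{seed},
#'   \code{skippedGroups}.
#' @seealso [buildMetacells()], [normalizeMetacells()]
#' @exportClass MetacellSet
setClass("MetacellSet",
         slots = c(expression = "matrix", members = "list",
                   groupOf = "character", params = "list"))

setValidity("MetacellSet", function(object) {
  msg <- character()
  ids <- rownames(object@expression)
  if (!identical(names(object@members), ids) ||
      !identical(names(object@groupOf), ids))
    msg <- c(msg, "members and groupOf must be named by metacell id, in order")
  k <- object@params$k
  if (!is.null(k) && length(object@members) &&
      !all(lengths(object@members) == k))
    msg <- c(msg, sprintf("every metacell must have exactly k = %d members", k))
  if (length(msg)) msg else TRUE
})

#' Per-group gene -> module assignments
#'
#' For each cell-type group, a mapping from every analysed gene to a module
#' label; \code{"unassigned"} is reserved for genes not placed in any module
#' of at least \code{minModuleSize} genes.
#'
#' @slot assignments named list: group -> named character vector
#'   (gene id -> module label).
#' @slot minModuleSize integer, the smallest size a detected cluster may
#'   have and still receive a module label.
#' @seealso [detectModules()], [readPartition()], [writePartition()]
#' @exportClass ModulePartition
setClass("ModulePartition",
         slots = c(assignments = "list", minModuleSize = "integer"))

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (is.null(names(object@assignments)) ||
      anyDuplicated(names(object@assignments)))
    msg <- c(msg, "assignments must be a list uniquely named by group")
  for (g in names(object@assignments)) {
    a <- object@assignments[[g]]
    if (!is.character(a) || is.null(names(a)) || anyDuplicated(names(a)))
      msg <- c(msg, sprintf(
        "group '%s': assignments must be a character vector uniquely named by gene", g))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ModulePartition
#'
#' @param assignments named list of named character vectors, one per group:
#'   gene id -> module label ("unassigned" for unmodularised genes).
#' @param minModuleSize integer(1), recorded provenance of the size floor.
#' @return A validated \linkS4class{ModulePartition}.
#' @export
ModulePartition <- function(assignments, minModuleSize = 10L) {
  new("ModulePartition", assignments = assignments,
      minModuleSize = as.integer(minModuleSize))
}

#' Weighted gene network (adjacency or topological overlap)
#'
#' Symmetric genes x genes weight matrix with values in [0, 1] and unit
#' diagonal; \code{kind} records whether the weights are a soft-threshold
#' adjacency or its topological overlap transform, and \code{power} the soft
#' power used to build the underlying adjacency.
#'
#' @slot weights symmetric numeric matrix in [0, 1], unit diagonal, with
#'   identical row and column gene names.
#' @slot kind "adjacency" or "TOM".
#' @slot power integer soft-threshold exponent (provenance).
#' @seealso [softAdjacency()], [tomSimilarity()]
#' @exportClass GeneNetwork
setClass("GeneNetwork",
         slots = c(weights = "matrix", kind = "character", power = "integer"))

setValidity("GeneNetwork", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w) || !identical(rownames(w), colnames(w)))
    msg <- c(msg, "weights must be square with matching gene names")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10, check.attributes = FALSE)))
    msg <- c(msg, "weights must be symmetric")
  if (any(w < -1e-12) || any(w > 1 + 1e-12))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (nrow(w) && max(abs(diag(w) - 1)) > 1e-12)
    msg <- c(msg, "diagonal must be 1")
  if (!object@kind %in% c("adjacency", "TOM"))
    msg <- c(msg, "kind must be 'adjacency' or 'TOM'")
  if (length(msg)) msg else TRUE
})

#' Reduced-dimensional cell coordinates
#'
#' Principal-component scores used as the space in which metacell
#' neighbourhoods are found.
#'
#' @slot coords cells x components score matrix.
#' @slot varExplained fraction of variance per retained component,
#'   non-increasing.
#' @seealso [reduceDims()]
#' @exportClass ReducedSpace
setClass("ReducedSpace",
         slots = c(coords = "matrix", varExplained = "numeric"))

setValidity("ReducedSpace", function(object) {
  msg <- character()
  if (ncol(object@coords) != length(object@varExplained))
    msg <- c(msg, "one varExplained entry per component required")
  if (is.unsorted(rev(object@varExplained), strictly = FALSE))
    msg <- c(msg, "components must be ordered by decreasing explained variance")
  if (length(msg)) msg else TRUE
})

#' Result of the module co-assignment permutation test
#'
#' @slot candidate the candidate gene the empirical statistic refers to.
#' @slot sEmp empirical co-assignment count: number of groups in which the
#'   candidate shares its module with both anchors.
#' @slot nGroups number of groups whose partition has a module containing
#'   both anchors (the test's denominator, T).
#' @slot B number of Monte Carlo replicates.
#' @slot nExceed number of replicates with null statistic >= sEmp.
#' @slot pMC Monte Carlo p-value, floored at 1/B (see \code{pFloor}).
#' @slot pFloor TRUE when no replicate reached sEmp, i.e. the p-value is
#'   reported as "< 1/B".
#' @slot pExact exact Poisson-binomial tail probability (NA when not
#'   computed).
#' @slot nullCounts integer histogram of the null statistic, named by value.
#' @slot seed RNG seed used for the replicates.
#' @seealso [permutationTest()], [exactTail()]
#' @exportClass CoocResult
setClass("CoocResult",
         slots = c(candidate = "character", sEmp = "integer",
                   nGroups = "integer", B = "integer", nExceed = "integer",
                   pMC = "numeric", pFloor = "logical", pExact = "numeric",
                   nullCounts = "integer", seed = "integer"))

setValidity("CoocResult", function(object) {
  msg <- character()
  if (object@sEmp < 0L || object@sEmp > object@nGroups)
    msg <- c(msg, "sEmp must lie in [0, nGroups]")
  if (!is.na(object@pMC) && (object@pMC <= 0 || object@pMC > 1))
    msg <- c(msg, "pMC must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
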