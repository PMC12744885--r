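#' Accessors for coexscreen classes
#'
#' Small generic layer over the S4 containers: raw counts and cell-type
#' labels of a \linkS4class{SingleCellCounts}; member lists, group labels
#' and aggregated expression of a \linkS4class{MetacellSet}; per-group
#' assignments of a \linkS4class{ModulePartition}; weight matrix of a
#' \linkS4class{GeneNetwork}; coordinates of a \linkS4class{ReducedSpace}.
#'
#' @param object one of the package's S4 objects.
#' @return The slot content named by the accessor (see Details of each
#'   class).
#' @name accessors
#' @examples
#' sim <- simulateSingleCell(nGroups = 2, cellsPerGroup = 60, nGenes = 40,
#'                           cooccGroups = "group1", seed = 1)
#' dim(scCounts(sim$counts))
#' table(cellGroups(sim$counts))
NULL

#' @rdname accessors
#' @export
setGeneric("scCounts", function(object) standardGeneric("scCounts"))
#' @rdname accessors
#' @export
setMethod("scCounts", "SingleCellCounts", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("cellGroups", function(object) standardGeneric("cellGroups"))
#' @rdname accessors
#' @export
setMethod("cellGroups", "SingleCellCounts", function(object) object@groups)

#' @rdname accessors
#' @export
setGeneric("cellIDs", function(object) standardGeneric("cellIDs"))
#' @rdname accessors
#' @export
setMethod("cellIDs", "SingleCellCounts",
          function(object) rownames(object@counts))

#' @rdname accessors
#' @export
setGeneric("geneIDs", function(object) standardGeneric("geneIDs"))
#' @rdname accessors
#' @export
setMethod("geneIDs", "SingleCellCounts",
          function(object) colnames(object@counts))
#' @rdname accessors
#' @export
setMethod("geneIDs", "MetacellSet",
          function(object) colnames(object@expression))

#' @rdname accessors
#' @export
setGeneric("metacellMembers", function(object)
  standardGeneric("metacellMembers"))
#' @rdname accessors
#' @export
setMethod("metacellMembers", "MetacellSet", function(object) object@members)

#' @rdname accessors
#' @export
setGeneric("metacellGroups", function(object)
  standardGeneric("metacellGroups"))
#' @rdname accessors
#' @export
setMethod("metacellGroups", "MetacellSet", function(object) object@groupOf)

#' @rdname accessors
#' @export
setGeneric("metacellExpression", function(object)
  standardGeneric("metacellExpression"))
#' @rdname accessors
#' @export
setMethod("metacellExpression", "MetacellSet",
          function(object) object@expression)

#' @rdname accessors
#' @export
setGeneric("moduleAssignments", function(object)
  standardGeneric("moduleAssignments"))
#' @rdname accessors
#' @export
setMethod("moduleAssignments", "ModulePartition",
          function(object) object@assignments)

#' @rdname accessors
#' @export
setGeneric("partitionGroups", function(object)
  standardGeneric("partitionGroups"))
#' @rdname accessors
#' @export
setMethod("partitionGroups", "ModulePartition",
          function(object) names(object@assignments))

#' @rdname accessors
#' @export
setGeneric("networkWeights", function(object)
  standardGeneric("networkWeights"))
#' @rdname accessors
#' @export
setMethod("networkWeights", "GeneNetwork", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("spaceCoords", function(object) standardGeneric("spaceCoords"))
#' @rdname accessors
#' @export
setMethod("spaceCoords", "ReducedSpace", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("varExplained", function(object) standardGeneric("varExplained"))
#' @rdname accessors
#' @export
setMethod("varExplained", "ReducedSpace",
          function(object) object@varExplained)

#' @rdname accessors
#' @export
setGeneric("pvalueMC", function(object) standardGeneric("pvalueMC"))
#' @rdname accessors
#' @export
setMethod("pvalueMC", "CoocResult", function(object) object@pMC)

#' @rdname accessors
#' @export
setGeneric("pvalueExact", function(object) standardGeneric("pvalueExact"))
#' @rdname accessors
#' @export
setMethod("pvalueExact", "CoocResult", function(object) object@pExact)

#' @rdname accessors
#' @export
setGeneric("coocCounts", function(object) standardGeneric("coocCounts"))
#' @rdname accessors
#' @export
setMethod("coocCounts", "CoocResult",
          function(object) c(matched = object@sEmp, total = object@nGroups))

setMethod("show", "SingleCellCounts", function(object) {
  cat(sprintf("SingleCellCounts: %d cells x %d genes, %d nonzeros\n",
              nrow(object@counts), ncol(object@counts),
              length(object@counts@x)))
  tab <- table(object@groups)
  cat(sprintf("  %d groups: %s\n", length(tab),
              paste(sprintf("%s (%d)", head(names(tab), 5), head(tab, 5)),
                    collapse = ", ")))
})

setMethod("show", "MetacellSet", function(object) {
  cat(sprintf("MetacellSet: %d metacells x %d genes (k = %s, max_shared = %s)\n",
              nrow(object@expression), ncol(object@expression),
              object@params$k, object@params$maxShared))
  tab <- table(object@groupOf)
  cat(sprintf("  per group: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf("ModulePartition over %d groups (min module size %d)\n",
              length(object@assignments), object@minModuleSize))
  for (g in head(names(object@assignments), 8)) {
    a <- object@assignments[[g]]
    cat(sprintf("  %s: %d genes, %d modules\n", g, length(a),
                length(setdiff(unique(a), "unassigned"))))
  }
})

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork (%s): %d genes, soft power %d\n",
              object@kind, nrow(object@weights), object@power))
})

setMethod("show", "CoocResult", function(object) {
  p <- if (isTRUE(object@pFloor)) sprintf("< %g", 1 / object@B)
       else sprintf("= %g", object@pMC)
  cat(sprintf("CoocResult for '%s': matched %d of %d anchor-module groups\n",
              object@candidate, object@sEmp, object@nGroups))
  cat(sprintf("  Monte Carlo p %s (B = %d, seed = %d); exact p = %g\n",
              p, object@B, object@seed, object@pExact))
})
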