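## KNN metacell construction.  Within each annotated group, seed cells are
## drawn without replacement; each seed's k-nearest neighbourhood (Euclidean
## in the reduced space, self included) is accepted as a metacell iff its
## overlap with every previously accepted metacell of that group is at most
## maxShared cells.  Aggregation averages raw counts; library-size
## renormalisation happens afterwards, so mean and sum aggregation are
## equivalent.

#' Build metacells per annotated group
#'
#' @param reduced a \linkS4class{ReducedSpace} whose rows are the cells of
#'   `sc` (same ids, same order not required).
#' @param sc a \linkS4class{SingleCellCounts} (QC-filtered).
#' @param k metacell size: number of member cells (default 25).
#' @param maxShared maximum number of cells two metacells of the same group
#'   may share (default 10; must be < k).
#' @param targetPerGroup acceptance cap per group; default
#'   `floor(group_size / (k - maxShared))`, a feasibility-motivated bound.
#' @param maxAttempts maximum seed cells tried per group; default
#'   `5 * group_size` (attempts also stop when seeds are exhausted).
#' @param seed integer RNG seed; output is deterministic given inputs and
#'   seed.
#' @return A \linkS4class{MetacellSet}.  Groups with fewer than `k` cells
#'   are skipped with a warning and listed in `params$skippedGroups`.
#' @examples
#' sim <- simulateSingleCell(nGroups = 2, cellsPerGroup = 80, nGenes = 60,
#'                           cooccGroups = "group1", seed = 5)
#' norm <- normalizeLog1p(sim$counts)
#' red <- reduceDims(scaleGenes(norm), nComponents = 10)
#' buildMetacells(red, sim$counts, k = 10, maxShared = 4, seed = 1)
#' @export
buildMetacells <- function(reduced, sc, k = 25L, maxShared = 10L,
                           targetPerGroup = NULL, maxAttempts = NULL,
                           seed = 1L) {
  stopifnot(is(reduced, "ReducedSpace"), is(sc, "SingleCellCounts"))
  if (!(k > maxShared && maxShared >= 0L))
    stop("need k > maxShared >= 0")
  coords <- spaceCoords(reduced)
  if (!setequal(rownames(coords), cellIDs(sc)))
    stop("reduced space and counts must cover the same cells")
  coords <- coords[cellIDs(sc), , drop = FALSE]
  counts <- scCounts(sc)
  groups <- cellGroups(sc)
  groupLevels <- sort(unique(as.character(groups)))

  members <- list(); groupOf <- character(); skipped <- character()
  withSeed(seed, {
    for (g in groupLevels) {
      cells <- cellIDs(sc)[groups == g]
      n <- length(cells)
      if (n < k) {
        warning(sprintf("group '%s' has %d cells (< k = %d); skipped",
                        g, n, k))
        skipped <- c(skipped, g)
        next
      }
      target <- if (is.null(targetPerGroup))
        max(1L, n %/% (k - maxShared)) else targetPerGroup
      attempts <- if (is.null(maxAttempts)) 5L * n else maxAttempts
      seedOrder <- sample(cells)
      accepted <- list()
      tried <- 0L
      for (s in seedOrder) {
        if (length(accepted) >= target || tried >= attempts) break
        tried <- tried + 1L
        d2 <- rowSums(sweep(coords[cells, , drop = FALSE], 2L,
                            coords[s, ], `-`)^2)
        nb <- cells[order(d2, cells)[seq_len(k)]]
        ok <- all(vapply(accepted, function(a)
          length(intersect(a, nb)) <= maxShared, logical(1)))
        if (ok) accepted[[length(accepted) + 1L]] <- nb
      }
      if (length(accepted)) {
        ids <- sprintf("%s_mc%03d", g, seq_along(accepted))
        names(accepted) <- ids
        members <- c(members, accepted)
        groupOf <- c(groupOf, setNames(rep(g, length(ids)), ids))
      }
    }
  })
  if (!length(members))
    stop("no metacells could be built; check k against group sizes")
  expr <- do.call(rbind, lapply(members, function(m)
    Matrix::colMeans(counts[m, , drop = FALSE])))
  rownames(expr) <- names(members)
  new("MetacellSet", expression = expr, members = members,
      groupOf = groupOf,
      params = list(k = as.integer(k), maxShared = as.integer(maxShared),
                    seed = as.integer(seed), skippedGroups = skipped))
}

#' Normalise metacell expression
#'
#' Library-size normalisation of the aggregated metacell matrix to `scale`
#' total, followed by natural-log `log1p` — the same transform as
#' [normalizeLog1p()] applied to metacells.
#'
#' @param mc a \linkS4class{MetacellSet}.
#' @param scale library-size target (default 10000).
#' @return A metacells x genes matrix of log-normalised expression.
#' @export
normalizeMetacells <- function(mc, scale = 10000) {
  stopifnot(is(mc, "MetacellSet"), scale > 0)
  expr <- metacellExpression(mc)
  totals <- rowSums(expr)
  if (any(totals == 0)) stop("metacell(s) with zero total aggregated count")
  log1p(expr * (scale / totals))
}

#' Pearson correlation between two genes over metacells
#'
#' @param expr metacells x genes normalised matrix (from
#'   [normalizeMetacells()]).
#' @param mc the \linkS4class{MetacellSet} the matrix came from (supplies
#'   group labels for `byGroup = TRUE`).
#' @param g1,g2 gene ids.
#' @param byGroup if `TRUE`, one correlation per group; groups with fewer
#'   than 3 metacells or a constant vector report `NA` rather than a
#'   number.
#' @return A single correlation, or a named numeric vector (one entry per
#'   group) when `byGroup = TRUE`.
#' @export
metacellCorrelation <- function(expr, mc, g1, g2, byGroup = FALSE) {
  stopifnot(is.matrix(expr))
  miss <- setdiff(c(g1, g2), colnames(expr))
  if (length(miss)) stop("gene(s) not in matrix: ",
                         paste(miss, collapse = ", "))
  if (!byGroup) {
    if (g1 == g2) return(1)
    return(pearsonR(expr[, g1], expr[, g2]))
  }
  stopifnot(is(mc, "MetacellSet"))
  groups <- metacellGroups(mc)[rownames(expr)]
  vapply(sort(unique(groups)), function(g) {
    i <- which(groups == g)
    x <- expr[i, g1]; y <- expr[i, g2]
    if (length(i) < 3L || sd(x) == 0 || sd(y) == 0) NA_real_
    else if (g1 == g2) 1 else pearsonR(x, y)
  }, numeric(1))
}

#' Ordinary least-squares line
#'
#' Fits `y = slope * x + intercept` minimising vertical residuals — the
#' regression line drawn through metacell co-expression scatter plots.
#'
#' @param x,y numeric vectors of equal length >= 2; `x` non-constant.
#' @return Named numeric `c(slope, intercept)`.
#' @examples
#' olsLine(c(0, 1, 2, 3), c(1, 1, 3, 3))  # slope 0.8, intercept 0.8
#' @export
olsLine <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (sd(x) == 0) stop("x is constant; line undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}
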