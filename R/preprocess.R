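## Single-cell preprocessing: QC on detected-gene counts, library-size
## log-normalisation, highly-variable-gene selection, per-gene scaling and
## PCA.  Every stage is deterministic; the pipeline order is
## qcFilter -> normalizeLog1p -> selectHVG -> scaleGenes -> reduceDims,
## with prevalenceFilter defining the gene universe for the network stage.

#' Filter cells by number of detected genes
#'
#' Retains cells whose number of detected genes (nonzero counts) lies in
#' `[minGenes, maxGenes]`, both bounds inclusive.  Genes are untouched.
#' `maxGenes` has no default: the sensible ceiling depends on the tissue
#' and platform (doublet-rich tissues need a tighter bound).
#'
#' @param sc a \linkS4class{SingleCellCounts}.
#' @param minGenes minimum detected genes per cell (default 200).
#' @param maxGenes maximum detected genes per cell (required;
#'   `> minGenes`).
#' @return A \linkS4class{SingleCellCounts} with the retained cells.
#' @examples
#' sim <- simulateSingleCell(nGroups = 2, cellsPerGroup = 60, nGenes = 50,
#'                           cooccGroups = "group1", seed = 2)
#' qcFilter(sim$counts, minGenes = 10, maxGenes = 50)
#' @export
qcFilter <- function(sc, minGenes = 200L, maxGenes) {
  stopifnot(is(sc, "SingleCellCounts"))
  if (missing(maxGenes)) stop("'maxGenes' is required (tissue-dependent)")
  if (!(minGenes < maxGenes)) stop("need minGenes < maxGenes")
  detected <- Matrix::rowSums(scCounts(sc) > 0)
  keep <- detected >= minGenes & detected <= maxGenes
  if (!any(keep))
    stop("QC removed every cell; review minGenes/maxGenes against the ",
         "detected-gene distribution")
  SingleCellCounts(scCounts(sc)[keep, , drop = FALSE],
                   cellGroups(sc)[keep])
}

#' Library-size log-normalisation
#'
#' Scales each cell's counts to a common library size and log-transforms:
#' `log(1 + scale * count / cell_total)`, natural log.  A zero entry stays
#' exactly zero, and the normalised profile of a cell is invariant to
#' multiplying all its counts by a constant.
#'
#' @param sc a \linkS4class{SingleCellCounts}; every cell must have total
#'   count > 0 (run [qcFilter()] first).
#' @param scale library-size target (default 10000).
#' @return A dense cells x genes matrix of log-normalised expression, with
#'   attributes `scaleFactor` and `logBase` (`"e"`).
#' @export
normalizeLog1p <- function(sc, scale = 10000) {
  stopifnot(is(sc, "SingleCellCounts"), scale > 0)
  counts <- scCounts(sc)
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    stop("cell(s) with zero total count (e.g. '",
         rownames(counts)[which(totals == 0)[1L]],
         "'); remove them with qcFilter() first")
  norm <- as.matrix(log1p(counts * (scale / totals)))
  attr(norm, "scaleFactor") <- scale
  attr(norm, "logBase") <- "e"
  norm
}

#' Select highly variable genes
#'
#' Ranks genes by a variance statistic on the log-normalised matrix and
#' returns the top `n`.  The default statistic standardises each gene's
#' variance by a mean-variance trend fitted with a running median over
#' genes ordered by mean expression, so that highly expressed genes do not
#' dominate purely through their scale; `method = "plain"` ranks by raw
#' variance instead.  Deterministic; ties are broken alphabetically by
#' gene id.
#'
#' @param norm cells x genes log-normalised matrix (from
#'   [normalizeLog1p()]).
#' @param n number of genes to select (default 2000, capped at the number
#'   of genes available).
#' @param method `"trend"` (default) or `"plain"`.
#' @return Character vector of `n` gene ids.
#' @export
selectHVG <- function(norm, n = 2000L, method = c("trend", "plain")) {
  method <- match.arg(method)
  stopifnot(is.matrix(norm))
  if (n > ncol(norm)) stop("n exceeds the number of genes")
  mu <- colMeans(norm)
  v <- apply(norm, 2L, var)
  stat <- if (method == "plain") v else {
    ord <- order(mu, colnames(norm))
    win <- min(ncol(norm), max(31L, 2L * (ncol(norm) %/% 40L) + 1L))
    if (win %% 2L == 0L) win <- win - 1L
    win <- max(win, 1L)
    trend <- numeric(length(v))
    trend[ord] <- runmed(v[ord], k = win, endrule = "median")
    ifelse(trend > 0, v / trend, v)
  }
  sel <- order(-stat, colnames(norm))[seq_len(n)]
  colnames(norm)[sel]
}

#' Filter genes by expression prevalence
#'
#' Returns the genes detected (count > 0) in at least `minFrac` of cells;
#' the bound is inclusive.  This defines the gene universe entering the
#' co-expression network stage.
#'
#' @param sc a \linkS4class{SingleCellCounts}.
#' @param minFrac minimum fraction of cells with nonzero count
#'   (default 0.05).
#' @return Character vector of gene ids, in input gene order.
#' @export
prevalenceFilter <- function(sc, minFrac = 0.05) {
  stopifnot(is(sc, "SingleCellCounts"), minFrac > 0, minFrac <= 1)
  frac <- Matrix::colMeans(scCounts(sc) > 0)
  geneIDs(sc)[frac >= minFrac]
}

#' Z-score genes with clipping
#'
#' Centres and scales each selected gene over cells and clips the result to
#' `[-clip, clip]`; a constant gene becomes an all-zero column rather than
#' an error.  The finite clip guards the subsequent PCA against outlier
#' cells.
#'
#' @param norm cells x genes log-normalised matrix.
#' @param hvg gene ids to keep (subset of `colnames(norm)`).
#' @param clip absolute bound on the z-scores (default 10).
#' @return A cells x `length(hvg)` matrix of clipped z-scores.
#' @export
scaleGenes <- function(norm, hvg = colnames(norm), clip = 10) {
  stopifnot(is.matrix(norm), clip > 0)
  if (!all(hvg %in% colnames(norm))) stop("hvg must be a subset of genes")
  x <- norm[, hvg, drop = FALSE]
  sds <- apply(x, 2L, sd)
  x <- sweep(x, 2L, colMeans(x))
  x <- sweep(x, 2L, ifelse(sds > 0, sds, 1), `/`)
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  x
}

#' Principal components of the scaled matrix
#'
#' Standard PCA of the cells x genes scaled matrix, retaining the top
#' `nComponents` score vectors.  For determinism the sign of each component
#' is fixed so that its largest-magnitude gene loading is positive.
#'
#' @param scaled cells x genes matrix from [scaleGenes()].
#' @param nComponents number of components to retain (default 50; must not
#'   exceed `min(dim(scaled))`).
#' @return A \linkS4class{ReducedSpace} with cell scores and the fraction
#'   of variance explained per component.
#' @export
reduceDims <- function(scaled, nComponents = 50L) {
  stopifnot(is.matrix(scaled))
  if (nComponents > min(dim(scaled)))
    stop("nComponents exceeds min(cells, genes)")
  p <- prcomp(scaled, center = TRUE, scale. = FALSE, rank. = nComponents)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(p$x, 2L, flip, `*`)
  rownames(scores) <- rownames(scaled)
  ve <- p$sdev^2 / sum(p$sdev^2)
  new("ReducedSpace", coords = scores,
      varExplained = ve[seq_len(nComponents)])
}
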