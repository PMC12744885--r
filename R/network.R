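## Weighted co-expression networks per cell-type group: signed soft-threshold
## adjacency, scale-free topology fit for automatic soft-power selection,
## topological overlap, average-linkage module detection with a static tree
## cut, and module eigengenes with eigengene connectivity (kME).

#' Signed soft-threshold adjacency from metacell expression
#'
#' Computes the signed weighted adjacency
#' `a_ij = ((1 + r_ij) / 2) ^ power` with `r` the Pearson correlation of
#' gene pairs over metacells, diagonal set to 1.  With a signed network,
#' anti-correlated genes get weights near 0 rather than being conflated
#' with positively correlated ones.
#'
#' @param expr metacells x genes normalised matrix; no constant gene
#'   columns (pre-filter them — their correlations are undefined).
#' @param power integer soft-threshold exponent, >= 1.
#' @param mode `"signed"` (default) or `"unsigned"`
#'   (`a_ij = |r_ij| ^ power`).
#' @return A \linkS4class{GeneNetwork} of kind `"adjacency"`.
#' @export
softAdjacency <- function(expr, power, mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr), power >= 1)
  sds <- apply(expr, 2L, sd)
  if (any(sds == 0))
    stop("constant gene(s) have undefined correlations: ",
         paste(head(colnames(expr)[sds == 0], 5), collapse = ", "),
         "; filter them before building the network")
  r <- cor(expr)
  a <- if (mode == "signed") ((1 + r) / 2)^power else abs(r)^power
  a <- (a + t(a)) / 2
  a[a > 1] <- 1; a[a < 0] <- 0
  diag(a) <- 1
  new("GeneNetwork", weights = a, kind = "adjacency",
      power = as.integer(power))
}

#' Scale-free topology fit of an adjacency network
#'
#' Measures how closely the network's connectivity distribution follows a
#' power law: connectivities `k_i` (row sums minus the diagonal) are binned
#' on the log10 scale, and `log10(frequency)` is regressed on
#' `log10(mean k)` per bin.  Returns the signed R-squared of that fit —
#' negated when the slope is positive, so that only declining (scale-free
#' like) distributions score high.
#'
#' @param network a \linkS4class{GeneNetwork} of kind `"adjacency"` with at
#'   least 20 genes.
#' @param nBins number of equal-width log-scale connectivity bins
#'   (default 10; empty bins are dropped).
#' @return Signed R-squared in [-1, 1]; 0 with a warning when the fit is
#'   undefined (all connectivities equal, or fewer than 2 occupied bins).
#' @export
scaleFreeFit <- function(network, nBins = 10L) {
  stopifnot(is(network, "GeneNetwork"), network@kind == "adjacency")
  w <- networkWeights(network)
  if (nrow(w) < 20L) stop("need at least 20 genes for a meaningful fit")
  k <- rowSums(w) - 1
  k <- k[k > 0]
  if (length(unique(signif(k, 12))) < 2L) {
    warning("all connectivities equal; scale-free fit undefined")
    return(0)
  }
  bins <- cut(log10(k), breaks = nBins)
  freq <- tabulate(bins, nbins = nBins)
  meanK <- vapply(seq_len(nBins), function(b)
    mean(k[as.integer(bins) == b]), numeric(1))
  keep <- freq > 0
  if (sum(keep) < 2L) {
    warning("fewer than 2 occupied connectivity bins; fit undefined")
    return(0)
  }
  x <- log10(meanK[keep]); y <- log10(freq[keep])
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[["x"]]
  if (slope > 0) -r2 else r2
}

#' Select the soft power by scale-free topology fit
#'
#' Scans the candidate powers in increasing order and returns the lowest
#' whose signed scale-free fit reaches `targetFit` (default 0.8).  When no
#' power reaches the target, the fixed `fallbackPower` is returned with a
#' warning — the field's convention for networks whose connectivity
#' distribution never looks scale-free (small gene sets, planted-block
#' simulations).  Selecting instead the power with the maximal fit is
#' unstable there: the argmax of an R-squared estimated from a handful of
#' connectivity bins is driven by noise, and statistically identical
#' datasets would get wildly different powers.
#'
#' @param expr metacells x genes normalised matrix (>= 20 genes, >= 10
#'   metacells).
#' @param powers integer vector of candidate powers (default 1:30).
#' @param targetFit required signed R-squared (default 0.8).
#' @param fallbackPower power used when no candidate reaches `targetFit`
#'   (default 12, the customary signed-network default).
#' @param mode passed to [softAdjacency()].
#' @return The selected power (integer), with the per-power fits attached
#'   as attribute `"fits"`.
#' @export
pickSoftPower <- function(expr, powers = 1:30, targetFit = 0.8,
                          fallbackPower = 12L, mode = "signed") {
  stopifnot(is.matrix(expr), length(powers) >= 1L)
  if (nrow(expr) < 10L) stop("need at least 10 metacells")
  if (ncol(expr) < 20L) stop("need at least 20 genes")
  powers <- as.integer(powers)
  fits <- vapply(powers, function(p)
    suppressWarnings(scaleFreeFit(softAdjacency(expr, p, mode))),
    numeric(1))
  names(fits) <- powers
  hit <- which(fits >= targetFit)
  sel <- if (length(hit)) powers[hit[1L]] else {
    warning(sprintf(
      "no power reached a scale-free fit of %.2f (best %.3f); using fallback power %d",
      targetFit, max(fits), fallbackPower))
    as.integer(fallbackPower)
  }
  structure(sel, fits = fits)
}

#' Topological overlap matrix
#'
#' Transforms an adjacency into the topological overlap similarity
#' `w_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` (k = row sums excluding the diagonal), diagonal 1.  Two genes
#' get a high overlap when they are strongly connected to each other
#' and share the same neighbourhood, which smooths out unreliable
#' individual correlations before clustering.
#'
#' @param adj a \linkS4class{GeneNetwork} of kind `"adjacency"`.
#' @return A \linkS4class{GeneNetwork} of kind `"TOM"`.
#' @export
tomSimilarity <- function(adj) {
  stopifnot(is(adj, "GeneNetwork"), adj@kind == "adjacency")
  a <- networkWeights(adj)
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  w <- num / den
  w <- (w + t(w)) / 2
  w[w > 1] <- 1; w[w < 0] <- 0
  diag(w) <- 1
  new("GeneNetwork", weights = w, kind = "TOM", power = adj@power)
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at a single static height.  Clusters of at least `minModuleSize`
#' genes become modules, labelled `"M1"`, `"M2"`, ... ordered by
#' decreasing size (ties: lexicographically smallest member first); all
#' other genes get the reserved label `"unassigned"`.
#'
#' By default the cut height is set relative to the network itself, at
#' 98 percent of the median off-diagonal dissimilarity.  Because the scale
#' of topological overlap values depends strongly on the soft power, no
#' single a-priori height separates modules from background across powers;
#' what is stable is that unrelated gene pairs concentrate tightly at the
#' top of the dissimilarity range while co-expressed blocks sit far below
#' it.  Requiring clusters to form distinctly below the typical unrelated
#' pair (the 0.98 factor) admits every genuine module while chance
#' correlations produce only small clusters that fall under
#' `minModuleSize` and end up unassigned.  Pass a numeric `cutHeight` to
#' override.
#'
#' @param tom a \linkS4class{GeneNetwork} of kind `"TOM"`.
#' @param minModuleSize smallest cluster size that becomes a module
#'   (default 10).
#' @param cutHeight static cut height on the `1 - TOM` dendrogram, or
#'   `NULL` (default) for the median-dissimilarity rule described above.
#' @return Named character vector: gene id -> module label (one group's
#'   partition; assemble several groups into a
#'   \linkS4class{ModulePartition}).
#' @export
detectModules <- function(tom, minModuleSize = 10L, cutHeight = NULL) {
  stopifnot(is(tom, "GeneNetwork"), tom@kind == "TOM")
  w <- networkWeights(tom)
  genes <- rownames(w)
  tree <- hclust(as.dist(1 - w), method = "average")
  if (is.null(cutHeight))
    cutHeight <- 0.98 * median((1 - w)[upper.tri(w)])
  cl <- cutree(tree, h = cutHeight)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= minModuleSize]
  ## deterministic labels: by size desc, then smallest member gene id
  firstMember <- vapply(big, function(b)
    min(genes[cl == as.integer(b)]), character(1))
  big <- big[order(-as.integer(sizes[big]), firstMember)]
  labels <- setNames(rep("unassigned", length(genes)), genes)
  for (i in seq_along(big))
    labels[cl == as.integer(big[i])] <- paste0("M", i)
  labels
}

#' Module eigengene and eigengene connectivity (kME)
#'
#' The module eigengene is the first principal component of the module's
#' gene-standardised expression over metacells, scaled to unit norm and
#' sign-oriented to correlate positively with the module's mean expression.
#' kME is each gene's Pearson correlation with the eigengene — a
#' connectivity measure usable for any gene, member or not.
#'
#' @param expr metacells x genes normalised matrix (>= 3 metacells).
#' @param moduleGenes ids of the module's member genes (>= 2, subset of
#'   `colnames(expr)`).
#' @return A list with `eigengene` (unit-norm numeric vector over
#'   metacells) and `kME` (named vector: correlation of every gene in
#'   `expr` with the eigengene; `NA` for constant genes).
#' @export
moduleEigengene <- function(expr, moduleGenes) {
  stopifnot(is.matrix(expr), length(moduleGenes) >= 2L, nrow(expr) >= 3L)
  if (!all(moduleGenes %in% colnames(expr)))
    stop("moduleGenes must be a subset of the matrix genes")
  sub <- expr[, moduleGenes, drop = FALSE]
  sds <- apply(sub, 2L, sd)
  if (all(sds == 0)) stop("degenerate module: all member genes constant")
  sub <- sub[, sds > 0, drop = FALSE]
  z <- scale(sub)
  eg <- prcomp(z, center = FALSE, scale. = FALSE, rank. = 1L)$x[, 1L]
  if (cor(eg, rowMeans(sub)) < 0) eg <- -eg
  eg <- eg / sqrt(sum(eg^2))
  kME <- apply(expr, 2L, function(col)
    if (sd(col) == 0) NA_real_ else cor(col, eg))
  list(eigengene = eg, kME = kME)
}
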