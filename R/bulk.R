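## The bulk-compendium screen: brightness normalisation, Pearson ranking of
## candidates against a reference gene, peak-timing ordering, and the
## presence tally used to ask in how many samples a candidate accompanies
## the reference.

#' Normalise each gene row to its maximum
#'
#' Divides every gene row by its row maximum, the brightness-coding used to
#' display expression tables as images: values land in [0, 1] with exactly
#' one 1 per non-zero row.  All-zero rows are left unchanged.  The operation
#' is idempotent.
#'
#' @param table genes x samples numeric matrix (nonnegative, finite).
#' @return A matrix of the same shape with rows scaled to max 1.
#' @examples
#' m <- rbind(gA = c(2, 4, 8), gB = c(0, 0, 0))
#' colnames(m) <- c("s1", "s2", "s3")
#' maxNormalize(m)
#' @export
maxNormalize <- function(table) {
  assertBulkTable(table)
  mx <- apply(table, 1L, max)
  scale <- ifelse(mx > 0, mx, 1)
  table / scale
}

#' Sample Pearson correlation with strict degenerate handling
#'
#' Plain sample Pearson correlation, but a constant vector is an explicit
#' error rather than a silent `NA` or zero: in a screen, an undefined
#' correlation must surface, not rank.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The correlation, in [-1, 1].
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: constant vector")
  r <- cor(x, y)
  min(1, max(-1, r))
}

#' Rank candidate genes by correlation with a reference gene
#'
#' Computes the Pearson correlation of every candidate's expression profile
#' with the reference gene's, across samples, and sorts in descending order
#' of r.  Correlations are computed on the raw table; Pearson r is invariant
#' to the per-gene max-normalisation used for display, so this equals
#' correlating brightness-coded rows.  Candidates with a constant profile
#' get `r = NA` and rank last.  Ties (and NAs among themselves) are broken
#' alphabetically by gene id.
#'
#' @param table genes x samples numeric matrix.
#' @param reference reference gene id (must be non-constant).
#' @param candidates character vector of candidate gene ids.
#' @param dataset optional dataset label recorded on the result.
#' @return A data.frame with columns `gene`, `r`, `rank`, ordered by
#'   descending r; attributes `reference` and `dataset`.
#' @examples
#' sim <- simulateBulk(seed = 1)
#' head(rankCandidates(sim$table, "Col4a1", sim$truth$candidates), 3)
#' @export
rankCandidates <- function(table, reference, candidates, dataset = NA_character_) {
  assertBulkTable(table)
  assertGenesPresent(table, c(reference, candidates))
  ref <- table[reference, ]
  r <- vapply(candidates, function(g) {
    row <- table[g, ]
    if (sd(row) == 0) NA_real_ else pearsonR(ref, row)
  }, numeric(1))
  ord <- order(-r, candidates, na.last = TRUE)
  out <- data.frame(gene = candidates[ord], r = unname(r[ord]),
                    rank = seq_along(candidates), row.names = NULL)
  attr(out, "reference") <- reference
  attr(out, "dataset") <- dataset
  out
}

#' Order genes by the timing of their expression peak
#'
#' Sorts gene ids by the sample index at which each row attains its maximum
#' (earlier peaks first); for a row with several equal maxima the first is
#' taken.  Genes peaking at the same sample keep their input order (stable
#' sort).
#'
#' @param table genes x samples numeric matrix, columns in temporal order.
#' @return Character vector of gene ids, earliest peak first.
#' @export
sortByPeak <- function(table) {
  assertBulkTable(table)
  peak <- apply(table, 1L, which.max)
  rownames(table)[order(peak)]
}

#' Count samples where a gene accompanies the expressed reference
#'
#' After max-normalising both rows, counts the samples in which the
#' reference is "visibly" expressed (normalised value > `threshold`) and,
#' among those, the samples in which the query gene is also above
#' `threshold` — the tally behind statements like "expression was visible
#' in the samples expressing the reference, apart from n exceptions".
#'
#' @param table genes x samples numeric matrix.
#' @param reference,gene gene ids.
#' @param threshold visibility cutoff on the max-normalised scale
#'   (default 0.05, i.e. 5 percent of the gene's own maximum).
#' @return Integer vector `c(n_ref_expressed, n_both)`.
#' @export
coexpressionPresence <- function(table, reference, gene, threshold = 0.05) {
  assertBulkTable(table)
  assertGenesPresent(table, c(reference, gene))
  stopifnot(threshold >= 0)
  norm <- maxNormalize(table[unique(c(reference, gene)), , drop = FALSE])
  refOn <- norm[reference, ] > threshold
  c(n_ref_expressed = sum(refOn),
    n_both = sum(refOn & norm[gene, ] > threshold))
}
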