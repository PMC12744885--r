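## End-to-end screens.  Each stage reads and writes only the package's
## exchange types, so the screens are thin orchestration: they wire the
## stages together, persist every intermediate as TSV when an output
## directory is given, and record a JSON manifest with every seed and
## parameter needed to reproduce the outputs.

#' Run the bulk correlation screen
#'
#' Ranks all candidates against the reference gene and emits the ranking
#' plus a brightness-coded text image of the max-normalised expression of
#' the reference and candidates (rows in ranking order).
#'
#' @param table genes x samples bulk matrix, or a path to a TSV readable by
#'   [readBulkTable()].
#' @param reference reference gene id.
#' @param candidates character vector of candidate gene ids.
#' @param outDir output directory (created); `NULL` for no files.
#' @param dataset label recorded in the ranking and manifest.
#' @param orientation passed to [readBulkTable()] when `table` is a path.
#' @return Invisibly, a list with `ranking` (data.frame) and `image`
#'   (the brightness matrix).
#' @examples
#' sim <- simulateBulk(seed = 1)
#' res <- runBulkScreen(sim$table, sim$truth$referenceGene,
#'                      sim$truth$candidates)
#' head(res$ranking, 3)
#' @export
runBulkScreen <- function(table, reference, candidates, outDir = NULL,
                          dataset = NA_character_,
                          orientation = "samples_as_rows") {
  if (is.character(table) && length(table) == 1L)
    table <- readBulkTable(table, orientation)
  ranking <- rankCandidates(table, reference, candidates, dataset)
  img <- maxNormalize(table[c(reference, ranking$gene), , drop = FALSE])
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(ranking, file.path(outDir, "ranking.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeTextImage(img, file.path(outDir, "brightness.txt"))
    writeManifest(file.path(outDir, "manifest.json"),
                  list(screen = "bulk", reference = reference,
                       candidates = candidates, dataset = dataset,
                       n_genes = nrow(table), n_samples = ncol(table)))
  }
  invisible(list(ranking = ranking, image = img))
}

#' Run the single-cell co-expression screen
#'
#' The full single-cell arm: QC -> log-normalisation -> HVG selection ->
#' scaling -> PCA -> per-group metacells -> per-group co-expression
#' networks and module detection -> co-assignment permutation test.  The
#' gene universe for the networks is the prevalence filter intersected with
#' the HVGs; genes constant within a group's metacells are dropped from
#' that group's network.  Groups skipped (too few cells, too few metacells
#' or too few network genes) are recorded in the manifest.
#'
#' @param sc a \linkS4class{SingleCellCounts}, or a directory readable by
#'   [readSparseCounts()].
#' @param anchors character(2): the anchor gene pair.
#' @param candidate the candidate of interest.
#' @param candidates the candidate panel for the permutation null
#'   (defaults to `candidate` alone).
#' @param minGenes,maxGenes QC bounds on detected genes per cell
#'   ([qcFilter()]).
#' @param hvgN number of highly variable genes (capped at the gene count).
#' @param pcs number of principal components.
#' @param minFrac prevalence threshold ([prevalenceFilter()]).
#' @param k,maxShared,targetPerGroup metacell parameters
#'   ([buildMetacells()]).
#' @param powers,targetFit soft-power scan ([pickSoftPower()]).
#' @param minModuleSize,cutHeight module detection ([detectModules()]).
#' @param B permutation replicates.
#' @param seed master seed; stage seeds are derived from it.
#' @param outDir output directory (created); `NULL` for no files.
#' @return Invisibly, a list: `partition` (\linkS4class{ModulePartition}),
#'   `cooc` (\linkS4class{CoocResult} or `NULL` when the anchors were never
#'   co-assigned), `correlations` (data.frame of per-group anchor/candidate
#'   metacell correlations), `metacells`, `powers` (chosen soft power per
#'   group), `skipped` (named list of skipped groups per stage).
#' @examples
#' sim <- simulateSingleCell(nGroups = 2, cellsPerGroup = 150, nGenes = 80,
#'                           cooccGroups = "group1", seed = 11)
#' res <- runScScreen(sim$counts, anchors = c("Col4a1", "vkg"),
#'                    candidate = "PH4aEFB", minGenes = 10, maxGenes = 80,
#'                    k = 15, maxShared = 6, B = 500, seed = 1)
#' res$cooc
#' @export
runScScreen <- function(sc, anchors, candidate, candidates = candidate,
                        minGenes = 200L, maxGenes, hvgN = 2000L, pcs = 50L,
                        minFrac = 0.05, k = 25L, maxShared = 10L,
                        targetPerGroup = NULL, powers = 1:30,
                        targetFit = 0.8, minModuleSize = 10L,
                        cutHeight = NULL, B = 10000L, seed = 1L,
                        outDir = NULL) {
  if (is.character(sc) && length(sc) == 1L) sc <- readSparseCounts(sc)
  stopifnot(is(sc, "SingleCellCounts"), length(anchors) == 2L)

  kept <- qcFilter(sc, minGenes, maxGenes)
  norm <- normalizeLog1p(kept)
  hvg <- selectHVG(norm, min(hvgN, ncol(norm)))
  scaled <- scaleGenes(norm, hvg)
  red <- reduceDims(scaled, min(pcs, min(dim(scaled))))
  mc <- withCallingHandlers(
    buildMetacells(red, kept, k, maxShared, targetPerGroup,
                   seed = deriveSeed(seed, 1L)),
    warning = function(w) invokeRestart("muffleWarning"))
  mcExpr <- normalizeMetacells(mc)

  universe <- intersect(prevalenceFilter(kept, minFrac), hvg)
  groups <- sort(unique(metacellGroups(mc)))
  assignments <- list(); chosenPower <- integer(); smallGroups <- character()
  for (g in groups) {
    rows <- names(metacellGroups(mc))[metacellGroups(mc) == g]
    ge <- mcExpr[rows, universe, drop = FALSE]
    ge <- ge[, apply(ge, 2L, sd) > 0, drop = FALSE]
    if (nrow(ge) < 10L || ncol(ge) < 20L) {
      smallGroups <- c(smallGroups, g)
      next
    }
    p <- suppressWarnings(pickSoftPower(ge, powers, targetFit))
    tom <- tomSimilarity(softAdjacency(ge, p))
    assignments[[g]] <- detectModules(tom, minModuleSize, cutHeight)
    chosenPower[g] <- as.integer(p)
  }
  if (!length(assignments))
    stop("no group yielded a co-expression network; check group sizes")
  partition <- ModulePartition(assignments, minModuleSize)

  cooc <- tryCatch(
    permutationTest(partition, candidate, candidates, anchors[1L],
                    anchors[2L], B = B, seed = deriveSeed(seed, 2L)),
    error = function(e) {
      if (grepl("never co-assigned", conditionMessage(e))) NULL else stop(e)
    })

  corrRows <- do.call(rbind, lapply(c(
    list(c(anchors[1L], anchors[2L]), c(anchors[1L], candidate))),
    function(pair) {
      rg <- metacellCorrelation(mcExpr, mc, pair[1L], pair[2L],
                                byGroup = TRUE)
      data.frame(gene1 = pair[1L], gene2 = pair[2L],
                 group = names(rg), r = unname(rg))
    }))
  overall <- data.frame(
    gene1 = anchors[1L],
    gene2 = c(anchors[2L], candidate),
    group = "(all)",
    r = c(metacellCorrelation(mcExpr, mc, anchors[1L], anchors[2L]),
          metacellCorrelation(mcExpr, mc, anchors[1L], candidate)))
  correlations <- rbind(overall, corrRows)

  skipped <- list(metacells = mc@params$skippedGroups,
                  network = smallGroups)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writePartition(partition, file.path(outDir, "partition.tsv"))
    write.table(correlations, file.path(outDir, "correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cooc)) {
      pTxt <- if (cooc@pFloor) sprintf("< %g", 1 / cooc@B)
              else sprintf("%g", cooc@pMC)
      write.table(data.frame(candidate = candidate,
                             matched = cooc@sEmp, total = cooc@nGroups,
                             p = pTxt, p_exact = cooc@pExact),
                  file.path(outDir, "cooccurrence.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    writeManifest(file.path(outDir, "manifest.json"), list(
      screen = "single-cell", anchors = anchors, candidate = candidate,
      candidates = candidates, minGenes = minGenes, maxGenes = maxGenes,
      hvgN = hvgN, pcs = pcs, minFrac = minFrac, k = k,
      maxShared = maxShared, targetFit = targetFit,
      minModuleSize = minModuleSize, cutHeight = cutHeight, B = B,
      seed = seed, metacellSeed = deriveSeed(seed, 1L),
      permutationSeed = deriveSeed(seed, 2L), softPowers = chosenPower,
      skippedGroups = skipped))
  }
  invisible(list(partition = partition, cooc = cooc,
                 correlations = correlations, metacells = mc,
                 powers = chosenPower, skipped = skipped))
}

## Derive a stage seed from the master seed, kept inside 32-bit range.
deriveSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + stage * 7919) %% 2147483647)
}

writeManifest <- function(path, fields) {
  fields$package_version <- as.character(utils::packageVersion("coexscreen"))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}
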