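## Synthetic data with planted ground truth.  These generators define the
## study conditions under which the pipeline is validated: a bulk panel in
## which a reference gene, its obligate partner and one true candidate share
## a latent sample profile among independent decoys, and a single-cell
## dataset in which an anchor gene pair and a candidate are planted into
## co-expression modules in a configurable subset of cell types.

#' Simulate a bulk expression panel with one planted co-regulated trio
#'
#' Emulates the structure of a candidate-gene correlation screen over an
#' expression atlas: a reference gene, a partner gene (the near-identical
#' co-promoter pair, e.g. the two collagen IV subunits) and one true
#' candidate all follow a single latent log-normal sample profile plus
#' independent log-normal noise, while `nDecoys` decoy candidates follow
#' independent profiles of the same magnitude.
#'
#' @param nSamples number of samples (tissues/conditions), >= 3.
#' @param nDecoys number of decoy candidate genes (default 25, one short of
#'   a 26-gene candidate panel whose remaining member is the true one).
#' @param referenceGene,partnerGene,trueCandidate gene ids for the planted
#'   trio.
#' @param sharedProfileSd sd of the latent log-profile shared by the trio
#'   (and, independently, of each decoy's own profile), log scale.
#' @param noiseSd sd of the independent log-normal noise on the partner-free
#'   members of the trio and on the decoys.
#' @param partnerNoiseSd noise sd of the partner gene; small by default so
#'   the partner tracks the reference nearly identically, mimicking two
#'   subunit genes under a shared promoter.
#' @param seed integer RNG seed; the output is a deterministic function of
#'   the arguments.
#' @return A list with `table` (genes x samples matrix: reference, partner,
#'   candidate, then decoys) and `truth` (list with the planted role of each
#'   gene and the generative parameters).
#' @examples
#' sim <- simulateBulk(seed = 1)
#' rk <- rankCandidates(sim$table, sim$truth$referenceGene,
#'                      sim$truth$candidates)
#' head(rk, 3)
#' @export
simulateBulk <- function(nSamples = 25L, nDecoys = 25L,
                         referenceGene = "Col4a1", partnerGene = "vkg",
                         trueCandidate = "PH4aEFB",
                         sharedProfileSd = 1, noiseSd = 0.3,
                         partnerNoiseSd = 0.05, seed = 1L) {
  stopifnot(nSamples >= 3L, nDecoys >= 1L, sharedProfileSd > 0, noiseSd > 0,
            partnerNoiseSd > 0)
  genes <- c(referenceGene, partnerGene, trueCandidate,
             sprintf("decoy%02d", seq_len(nDecoys)))
  if (anyDuplicated(genes)) stop("gene ids must be distinct")
  samples <- sprintf("sample%02d", seq_len(nSamples))
  tab <- withSeed(seed, {
    shared <- rnorm(nSamples, 0, sharedProfileSd)
    geneScale <- rlnorm(length(genes), meanlog = 2, sdlog = 0.5)
    rows <- list(
      exp(shared + rnorm(nSamples, 0, noiseSd)),
      exp(shared + rnorm(nSamples, 0, partnerNoiseSd)),
      exp(shared + rnorm(nSamples, 0, noiseSd)))
    decoys <- lapply(seq_len(nDecoys), function(i)
      exp(rnorm(nSamples, 0, sharedProfileSd) + rnorm(nSamples, 0, noiseSd)))
    m <- do.call(rbind, c(rows, decoys)) * geneScale
    dimnames(m) <- list(genes, samples)
    m
  })
  truth <- list(referenceGene = referenceGene, partnerGene = partnerGene,
                trueCandidate = trueCandidate,
                candidates = c(trueCandidate,
                               sprintf("decoy%02d", seq_len(nDecoys))),
                sharedProfileSd = sharedProfileSd, noiseSd = noiseSd,
                partnerNoiseSd = partnerNoiseSd, seed = as.integer(seed))
  list(table = tab, truth = truth)
}

#' Simulate single-cell counts with planted co-expression modules
#'
#' Generates sparse overdispersed counts structured into cell-type groups.
#' Within each group, genes are organised into `nModulesPerGroup` planted
#' modules of `moduleSize` genes; each module has a per-cell latent activity
#' `z ~ Normal(0, moduleEffect)` and member-gene expected expression is the
#' gene's baseline scaled by `exp(z)`.  Counts are negative binomial
#' (gamma-Poisson) around library-size-scaled means, with library sizes
#' log-normal; sparsity arises from low means, with no explicit
#' zero-inflation.  The anchor pair always occupies module `"M1"` of every
#' group; the candidate joins that module in exactly `cooccGroups` and a
#' different module (`"M2"`) elsewhere, so the planted co-assignment count
#' equals `length(cooccGroups)`.
#'
#' @param nGroups number of cell-type groups.
#' @param cellsPerGroup cells per group.
#' @param nGenes total genes (>= `nModulesPerGroup * moduleSize`).
#' @param nModulesPerGroup planted modules per group (>= 2).
#' @param moduleSize genes per planted module (>= 3).
#' @param anchorPair character(2), the anchor gene ids.
#' @param candidate candidate gene id.
#' @param cooccGroups group labels in which the candidate is planted into
#'   the anchor module; must be a subset of the generated group labels
#'   `"group1"..."groupN"`.
#' @param libsizeMean mean library size (expected total counts per cell).
#' @param libsizeSdLog log-sd of the log-normal library sizes.
#' @param nbDispersion negative binomial dispersion (Var = mu + disp mu^2).
#' @param moduleEffect sd of the per-cell module activity on the log scale;
#'   0 switches all co-expression off (null data).
#' @param baselineSdLog log-sd of the per-gene baseline abundances.
#' @param seed integer RNG seed.
#' @return A list with `counts` (a \linkS4class{SingleCellCounts}) and
#'   `truth` (list: `modules` = per-group gene -> module map with
#'   `"unassigned"` for background genes, `sTrue`, `anchorPair`,
#'   `candidate`, `cooccGroups`, and the generative parameters).
#' @examples
#' sim <- simulateSingleCell(nGroups = 2, cellsPerGroup = 80, nGenes = 60,
#'                           cooccGroups = "group1", seed = 3)
#' sim$truth$sTrue
#' sim$counts
#' @export
simulateSingleCell <- function(nGroups = 8L, cellsPerGroup = 500L,
                               nGenes = 300L, nModulesPerGroup = 3L,
                               moduleSize = 10L,
                               anchorPair = c("Col4a1", "vkg"),
                               candidate = "PH4aEFB",
                               cooccGroups = paste0("group", 1:5),
                               libsizeMean = 2000, libsizeSdLog = 0.3,
                               nbDispersion = 1, moduleEffect = 1,
                               baselineSdLog = 0.5, seed = 1L) {
  stopifnot(nGroups >= 1L, cellsPerGroup >= 1L, moduleSize >= 3L,
            nModulesPerGroup >= 2L, nbDispersion > 0, libsizeMean > 0,
            length(anchorPair) == 2L)
  if (nModulesPerGroup * moduleSize > nGenes)
    stop("module assignments exceed the number of genes: need at least ",
         nModulesPerGroup * moduleSize, " genes")
  groups <- paste0("group", seq_len(nGroups))
  if (!all(cooccGroups %in% groups))
    stop("cooccGroups must be a subset of ",
         paste(groups, collapse = ", "))
  special <- c(anchorPair, candidate)
  if (anyDuplicated(special)) stop("anchor and candidate ids must differ")
  nBackground <- nGenes - 3L
  genes <- c(special, sprintf("gene%03d", seq_len(nBackground)))
  pool <- genes[-(1:3)]

  out <- withSeed(seed, {
    baseline <- setNames(rlnorm(nGenes, meanlog = 0, sdlog = baselineSdLog),
                         genes)
    moduleMap <- list()   # group -> gene -> module label
    counts <- vector("list", nGroups)
    cellNames <- vector("list", nGroups)
    for (gi in seq_len(nGroups)) {
      g <- groups[gi]
      candidateInAnchor <- g %in% cooccGroups
      ## per-group module membership: anchors (+ candidate) in M1,
      ## candidate in M2 when not co-occurring, fillers sampled from the
      ## background pool (one module per gene at most)
      nFill1 <- moduleSize - 2L - as.integer(candidateInAnchor)
      nFill2 <- moduleSize - as.integer(!candidateInAnchor)
      nFillOther <- (nModulesPerGroup - 2L) * moduleSize
      fillers <- sample(pool, nFill1 + nFill2 + nFillOther)
      cursor <- 0L
      takeFillers <- function(n) {
        out <- fillers[cursor + seq_len(n)]
        cursor <<- cursor + n
        out
      }
      members <- vector("list", nModulesPerGroup)
      members[[1L]] <- c(anchorPair, if (candidateInAnchor) candidate,
                         takeFillers(nFill1))
      members[[2L]] <- c(if (!candidateInAnchor) candidate,
                         takeFillers(nFill2))
      if (nModulesPerGroup > 2L)
        for (m in 3:nModulesPerGroup)
          members[[m]] <- takeFillers(moduleSize)
      map <- setNames(rep("unassigned", nGenes), genes)
      for (m in seq_len(nModulesPerGroup))
        map[members[[m]]] <- paste0("M", m)
      moduleMap[[g]] <- map

      ## latent module activities per cell, then NB counts
      memberOf <- setNames(rep(NA_integer_, nGenes), genes)
      for (m in seq_len(nModulesPerGroup))
        memberOf[members[[m]]] <- m
      z <- matrix(rnorm(cellsPerGroup * nModulesPerGroup, 0, moduleEffect),
                  cellsPerGroup, nModulesPerGroup)
      logAct <- matrix(0, cellsPerGroup, nGenes)
      inMod <- !is.na(memberOf)
      logAct[, inMod] <- z[, memberOf[inMod], drop = FALSE]
      rate <- sweep(exp(logAct), 2L, baseline, `*`)
      lib <- rlnorm(cellsPerGroup,
                    meanlog = log(libsizeMean) - libsizeSdLog^2 / 2,
                    sdlog = libsizeSdLog)
      mu <- rate / rowSums(rate) * lib
      cts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / nbDispersion),
                    cellsPerGroup, nGenes)
      counts[[gi]] <- cts
      cellNames[[gi]] <- sprintf("%s_cell%04d", g, seq_len(cellsPerGroup))
    }
    m <- do.call(rbind, counts)
    dimnames(m) <- list(unlist(cellNames), genes)
    list(m = m, moduleMap = moduleMap)
  })

  groupsVec <- setNames(rep(groups, each = cellsPerGroup), rownames(out$m))
  sc <- SingleCellCounts(Matrix::Matrix(out$m, sparse = TRUE), groupsVec)
  truth <- list(modules = out$moduleMap, sTrue = length(cooccGroups),
                anchorPair = anchorPair, candidate = candidate,
                cooccGroups = cooccGroups, moduleEffect = moduleEffect,
                nbDispersion = nbDispersion, libsizeMean = libsizeMean,
                seed = as.integer(seed))
  list(counts = sc, truth = truth)
}
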