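# Fixture builders and independent oracles shared across test files.
# Everything is generated in code under fixed seeds; no stored data.

# --- partitions ------------------------------------------------------------

# Random per-group module partition over a shared gene universe in which the
# anchors are co-assigned in every group and a fixed candidate panel is
# analysed everywhere (so the Poisson-binomial oracle applies exactly).
randomPartition <- function(seed, anchors = c("A1", "A2"),
                            candidates = paste0("cand", 1:5)) {
  withr::with_seed(seed, {
    nGroups <- sample(3:12, 1)
    assignments <- lapply(seq_len(nGroups), function(g) {
      nGenes <- sample(15:40, 1)
      fillers <- sprintf("g%02d_f%02d", g, seq_len(nGenes - 2 -
                                                     length(candidates)))
      genes <- c(anchors, candidates, fillers)
      nMods <- sample(2:5, 1)
      labels <- paste0("M", seq_len(nMods))
      lab <- sample(c(labels, "unassigned"), length(genes), replace = TRUE)
      names(lab) <- genes
      lab[anchors] <- labels[1]          # anchors co-assigned, never unassigned
      lab
    })
    names(assignments) <- paste0("type", seq_len(nGroups))
    ModulePartition(assignments)
  })
}

# --- oracles ---------------------------------------------------------------

# Poisson-binomial upper tail by full 2^T enumeration.
enumTail <- function(q, sEmp) {
  if (sEmp <= 0) return(1)
  t <- length(q)
  total <- 0
  for (mask in 0:(2^t - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(t)]
    if (sum(bits) >= sEmp)
      total <- total + prod(ifelse(bits == 1, q, 1 - q))
  }
  total
}

# Naive triple-loop topological overlap (the defining formula, no algebra).
tomNaive <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  w <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    w[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(w) <- dimnames(a)
  w
}

# Random valid adjacency network on n genes.
randomAdjacency <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
    new("GeneNetwork", weights = a, kind = "adjacency", power = 1L)
  })
}

# Adjusted Rand index between a detected partition and the planted truth,
# restricted to the genes planted into modules (background genes have no
# meaningful planted grouping).
plantedARI <- function(detected, truthMap) {
  planted <- intersect(names(truthMap)[truthMap != "unassigned"],
                       names(detected))
  mclust::adjustedRandIndex(detected[planted], truthMap[planted])
}

# --- small single-cell fixture for metacell tests --------------------------

# Cells scattered in a low-dimensional space with arbitrary counts; enough
# structure for neighbourhoods, no planted modules.
metacellFixture <- function(seed, nGroups = 2, cellsPerGroup = 120,
                            nGenes = 40, dims = 5) {
  withr::with_seed(seed, {
    n <- nGroups * cellsPerGroup
    ids <- sprintf("c%04d", seq_len(n))
    coords <- matrix(rnorm(n * dims), n, dims,
                     dimnames = list(ids, paste0("PC", seq_len(dims))))
    counts <- matrix(rpois(n * nGenes, 5), n, nGenes,
                     dimnames = list(ids, sprintf("g%02d", seq_len(nGenes))))
    sc <- SingleCellCounts(Matrix::Matrix(counts, sparse = TRUE),
                           rep(paste0("grp", seq_len(nGroups)),
                               each = cellsPerGroup))
    red <- new("ReducedSpace", coords = coords,
               varExplained = rev(sort(runif(dims))))
    list(sc = sc, red = red)
  })
}

# Memoised default-condition screen run shared by acceptance checks.
.runCache <- new.env(parent = emptyenv())
defaultScreenRun <- function(seed = 1L) {
  key <- paste0("run", seed)
  if (is.null(.runCache[[key]])) {
    sim <- simulateSingleCell(seed = seed)
    res <- suppressWarnings(runScScreen(
      sim$counts, anchors = c("Col4a1", "vkg"), candidate = "PH4aEFB",
      minGenes = 100, maxGenes = 300, B = 10000, seed = seed))
    .runCache[[key]] <- list(sim = sim, res = res)
  }
  .runCache[[key]]
}
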