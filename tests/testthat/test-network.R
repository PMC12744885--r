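# Adjacency, scale-free fit, soft-power selection, TOM, module detection,
# eigengenes.

test_that("signed adjacency matches its closed form", {
  # three exactly collinear/anti-collinear/orthogonal genes
  x <- c(1, 2, 3, 4, 5, 6)
  expr <- cbind(gA = x, gB = 2 * x + 1, gC = -x,
                gD = c(1, -1, 1, -1, 1, -1))
  rownames(expr) <- paste0("m", 1:6)
  adj <- softAdjacency(expr, power = 6)
  w <- networkWeights(adj)
  expect_equal(w["gA", "gB"], 1)           # r = 1
  expect_equal(w["gA", "gC"], 0)           # r = -1 -> ((1-1)/2)^p = 0
  rAD <- cor(expr[, "gA"], expr[, "gD"])
  expect_equal(w["gA", "gD"], ((1 + rAD) / 2)^6)
  expect_equal(diag(w), setNames(rep(1, 4), colnames(expr)))

  exprC <- cbind(expr, gE = rep(2, 6))
  expect_error(softAdjacency(exprC, 6), "constant")

  # r = 0 at power 6 gives 0.5^6
  ortho <- cbind(gA = c(1, -1, 1, -1), gB = c(1, 1, -1, -1))
  rownames(ortho) <- paste0("m", 1:4)
  expect_equal(networkWeights(softAdjacency(ortho, 6))["gA", "gB"], 0.5^6)
})

test_that("adjacency and TOM keep symmetry and [0, 1] range on random input", {
  for (s in 1:25) {
    net <- randomAdjacency(15, s)
    tom <- tomSimilarity(net)
    for (x in list(networkWeights(net), networkWeights(tom))) {
      expect_equal(x, t(x))
      expect_true(all(x >= 0 & x <= 1))
      expect_equal(unname(diag(x)), rep(1, 15))
    }
  }
})

test_that("TOM equals the naive triple-loop oracle", {
  # 3-node all-ones network: omega = (1 + 1) / (2 + 1 - 1) = 1
  ones <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  net1 <- new("GeneNetwork", weights = ones, kind = "adjacency", power = 1L)
  expect_equal(unname(networkWeights(tomSimilarity(net1))),
               matrix(1, 3, 3))

  # no edge, no shared neighbours -> omega = 0
  iso <- diag(3); dimnames(iso) <- dimnames(ones)
  net0 <- new("GeneNetwork", weights = iso, kind = "adjacency", power = 1L)
  expect_equal(networkWeights(tomSimilarity(net0))["g1", "g2"], 0)

  for (s in 1:5) {
    n <- c(8, 13, 21, 27, 30)[s]
    net <- randomAdjacency(n, 100 + s)
    expect_equal(networkWeights(tomSimilarity(net)),
                 tomNaive(networkWeights(net)), tolerance = 1e-10)
  }
})

test_that("scale-free fit scores power laws high and degenerates to zero", {
  # rank-1 weighted network with geometric connectivity classes:
  # frequency halves whenever connectivity doubles -> log-log linear
  tgt <- rep(c(1, 2, 4, 8, 16, 32), c(32, 16, 8, 4, 2, 1))
  cvec <- tgt / sqrt(sum(tgt))
  cvec <- cvec / max(cvec)          # keep every weight within [0, 1]
  deg <- outer(cvec, cvec)
  diag(deg) <- 1
  dimnames(deg) <- list(paste0("g", seq_along(tgt)),
                        paste0("g", seq_along(tgt)))
  net <- new("GeneNetwork", weights = deg, kind = "adjacency", power = 1L)
  fit <- scaleFreeFit(net)
  expect_gte(fit, 0.8)
  expect_lte(abs(fit), 1)

  flat <- matrix(0.4, 25, 25,
                 dimnames = list(paste0("g", 1:25), paste0("g", 1:25)))
  diag(flat) <- 1
  netFlat <- new("GeneNetwork", weights = flat, kind = "adjacency",
                 power = 1L)
  expect_warning(f0 <- scaleFreeFit(netFlat), "undefined")
  expect_identical(f0, 0)
})

test_that("pickSoftPower equals an exhaustive scan and is lowest-first", {
  fx <- metacellFixture(42, nGroups = 1, cellsPerGroup = 60, nGenes = 40)
  mc <- buildMetacells(fx$red, fx$sc, k = 10, maxShared = 4, seed = 1)
  ex <- normalizeMetacells(mc)
  powers <- 1:12
  sel <- suppressWarnings(pickSoftPower(ex, powers, targetFit = 0.3))
  # independent oracle: direct scan re-deriving every fit
  fits <- vapply(powers, function(p)
    suppressWarnings(scaleFreeFit(softAdjacency(ex, p))), numeric(1))
  hits <- which(fits >= 0.3)
  oracle <- if (length(hits)) powers[hits[1]] else 12L
  expect_identical(as.integer(sel), as.integer(oracle))
  expect_equal(unname(attr(sel, "fits")), fits)
  # every power below the returned one misses the target
  if (as.integer(sel) > 1 && length(hits))
    expect_true(all(fits[seq_len(which(powers == as.integer(sel)) - 1)] < 0.3))
  # unreachable target falls back to the documented fixed power
  expect_warning(fb <- pickSoftPower(ex, powers, targetFit = 0.999,
                                     fallbackPower = 7L),
                 "fallback")
  expect_identical(as.integer(fb), 7L)
})

test_that("detectModules separates perfect blocks and applies the size floor", {
  blockTom <- function(sizes) {
    n <- sum(sizes)
    w <- matrix(0, n, n)
    labels <- rep(seq_along(sizes), sizes)
    for (b in seq_along(sizes)) w[labels == b, labels == b] <- 1
    dimnames(w) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    new("GeneNetwork", weights = w, kind = "TOM", power = 1L)
  }
  two <- detectModules(blockTom(c(12, 12)), minModuleSize = 10)
  expect_identical(sort(unique(two)), c("M1", "M2"))
  expect_identical(unname(table(two)["M1"]), 12L)

  small <- detectModules(blockTom(c(5, 15)), minModuleSize = 10)
  expect_identical(sort(unique(small)), c("M1", "unassigned"))
  expect_identical(sum(small == "unassigned"), 5L)

  # gene order invariance
  tom <- blockTom(c(11, 14))
  perm <- withr::with_seed(5, sample(25))
  w <- networkWeights(tom)[perm, perm]
  permuted <- detectModules(new("GeneNetwork", weights = w, kind = "TOM",
                                power = 1L), minModuleSize = 10)
  base <- detectModules(tom, minModuleSize = 10)
  expect_identical(permuted[names(base)], base)
})

test_that("module eigengene is oriented and kME separates members", {
  run <- defaultScreenRun(1)
  mc <- run$res$metacells
  ex <- normalizeMetacells(mc)
  g <- "group2"
  rows <- names(metacellGroups(mc))[metacellGroups(mc) == g]
  exg <- ex[rows, ]
  truthMap <- run$sim$truth$modules[[g]]
  mod <- names(truthMap)[truthMap == truthMap[["Col4a1"]]]
  eg <- moduleEigengene(exg, mod)
  expect_equal(sum(eg$eigengene^2), 1)
  expect_gte(cor(eg$eigengene, rowMeans(exg[, mod])), 0)
  # members carry higher kME than background genes in >= 95 % of pairs
  outside <- intersect(names(truthMap)[truthMap == "unassigned"],
                       colnames(exg))
  cmp <- outer(eg$kME[mod], eg$kME[outside], `>`)
  expect_gte(mean(cmp), 0.95)

  # a module of identical genes has kME 1 for every member
  same <- cbind(gA = exg[, 1], gB = exg[, 1], gC = exg[, 1])
  egSame <- moduleEigengene(same, c("gA", "gB", "gC"))
  expect_equal(unname(egSame$kME), rep(1, 3), tolerance = 1e-10)

  flat <- matrix(3, 10, 2, dimnames = list(NULL, c("gA", "gB")))
  expect_error(moduleEigengene(flat, c("gA", "gB")), "degenerate")
})
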