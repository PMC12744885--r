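# Metacell construction invariants, aggregation, correlations, OLS.

test_that("metacells satisfy size, overlap and purity invariants", {
  fx <- metacellFixture(31)
  for (s in c(1, 2, 3)) {
    mc <- buildMetacells(fx$red, fx$sc, k = 20, maxShared = 8, seed = s)
    expect_true(all(lengths(metacellMembers(mc)) == 20))
    byGroup <- split(names(metacellGroups(mc)), metacellGroups(mc))
    for (g in names(byGroup)) {
      ids <- byGroup[[g]]
      mem <- metacellMembers(mc)[ids]
      # group purity
      for (m in mem)
        expect_true(all(as.character(cellGroups(fx$sc)[m]) == g))
      # pairwise overlap cap
      if (length(mem) > 1)
        for (i in seq_along(mem)[-1]) for (j in seq_len(i - 1))
          expect_lte(length(intersect(mem[[i]], mem[[j]])), 8)
    }
  }
})

test_that("metacell construction is deterministic and honours maxShared = 0", {
  fx <- metacellFixture(32)
  a <- buildMetacells(fx$red, fx$sc, k = 15, maxShared = 5, seed = 4)
  b <- buildMetacells(fx$red, fx$sc, k = 15, maxShared = 5, seed = 4)
  expect_identical(metacellMembers(a), metacellMembers(b))
  expect_identical(metacellExpression(a), metacellExpression(b))

  disjoint <- buildMetacells(fx$red, fx$sc, k = 15, maxShared = 0, seed = 4)
  mem <- metacellMembers(disjoint)
  expect_identical(anyDuplicated(unlist(mem)), 0L)

  expect_error(buildMetacells(fx$red, fx$sc, k = 10, maxShared = 10), "k >")
})

test_that("groups smaller than k are skipped with a warning", {
  fx <- metacellFixture(33, nGroups = 2, cellsPerGroup = 60)
  # shrink grp1 to 20 cells so only grp2 can host k = 40 neighbourhoods
  keep <- c(cellIDs(fx$sc)[1:20], cellIDs(fx$sc)[61:120])
  sc <- SingleCellCounts(scCounts(fx$sc)[keep, ], cellGroups(fx$sc)[keep])
  red <- new("ReducedSpace", coords = spaceCoords(fx$red)[keep, ],
             varExplained = varExplained(fx$red))
  expect_warning(mc <- buildMetacells(red, sc, k = 40, maxShared = 10,
                                      seed = 1),
                 "skipped")
  expect_identical(mc@params$skippedGroups, "grp1")
  expect_true(all(metacellGroups(mc) == "grp2"))
})

test_that("accepted metacells equal a step-by-step replay of the rule", {
  fx <- metacellFixture(34, nGroups = 1, cellsPerGroup = 60, dims = 3)
  k <- 12; maxShared <- 4; seedVal <- 6
  mc <- buildMetacells(fx$red, fx$sc, k = k, maxShared = maxShared,
                       targetPerGroup = 100, seed = seedVal)
  # independent replay: same seeded draw order, same acceptance rule
  coords <- spaceCoords(fx$red)[cellIDs(fx$sc), ]
  cells <- cellIDs(fx$sc)
  replay <- withr::with_seed(as.integer(seedVal), {
    seedOrder <- sample(cells)
    accepted <- list()
    for (s in seedOrder) {
      if (length(accepted) >= 100) break
      d2 <- colSums((t(coords) - coords[s, ])^2)
      nb <- cells[order(d2, cells)[seq_len(k)]]
      if (all(vapply(accepted, function(a)
        length(intersect(a, nb)) <= maxShared, logical(1))))
        accepted[[length(accepted) + 1]] <- nb
    }
    accepted
  })
  expect_identical(unname(metacellMembers(mc)), replay)
})

test_that("aggregation averages member counts; normalisation reduces noise", {
  fx <- metacellFixture(35, nGroups = 1, cellsPerGroup = 80)
  mc <- buildMetacells(fx$red, fx$sc, k = 10, maxShared = 4, seed = 2)
  cts <- as.matrix(scCounts(fx$sc))
  id1 <- names(metacellMembers(mc))[1]
  expect_equal(metacellExpression(mc)[id1, ],
               colMeans(cts[metacellMembers(mc)[[id1]], ]))

  # a metacell of identical cells normalises like the single cell
  same <- matrix(rep(c(3, 0, 7), each = 5), 5, 3,
                 dimnames = list(paste0("c", 1:5), paste0("g", 1:3)))
  scSame <- SingleCellCounts(Matrix::Matrix(same, sparse = TRUE),
                             rep("t", 5))
  mcSame <- new("MetacellSet",
                expression = rbind(mc1 = colMeans(same)),
                members = list(mc1 = paste0("c", 1:5)),
                groupOf = c(mc1 = "t"),
                params = list(k = 5L, maxShared = 0L, seed = 1L,
                              skippedGroups = character(0)))
  expect_equal(normalizeMetacells(mcSame)["mc1", ],
               normalizeLog1p(scSame)["c1", ])
  expect_equal(unname(normalizeMetacells(mcSame)[, "g2"]), 0)

  # variance shrinks for most genes after aggregation
  norm <- normalizeLog1p(fx$sc)
  mcNorm <- normalizeMetacells(mc)
  vCell <- apply(norm, 2, var)
  vMc <- apply(mcNorm, 2, var)
  expect_gte(mean(vMc < vCell), 0.9)
})

test_that("metacell correlations handle self, per-group NA and missing genes", {
  fx <- metacellFixture(36)
  mc <- buildMetacells(fx$red, fx$sc, k = 15, maxShared = 6, seed = 3)
  ex <- normalizeMetacells(mc)
  expect_equal(metacellCorrelation(ex, mc, "g01", "g01"), 1)
  r <- metacellCorrelation(ex, mc, "g01", "g02", byGroup = TRUE)
  expect_identical(sort(names(r)), sort(unique(metacellGroups(mc))))
  expect_error(metacellCorrelation(ex, mc, "g01", "nope"), "nope")

  exConst <- ex; exConst[, "g02"] <- 5
  rc <- metacellCorrelation(exConst, mc, "g01", "g02", byGroup = TRUE)
  expect_true(all(is.na(rc)))
})

test_that("olsLine matches the normal equations", {
  expect_equal(olsLine(c(1, 2, 3), c(3, 5, 7)),
               c(slope = 2, intercept = 1))
  expect_equal(olsLine(c(0, 1, 2, 3), c(1, 1, 3, 3)),
               c(slope = 0.8, intercept = 0.8))
  withr::with_seed(17, {
    x <- rnorm(30); y <- 2 * x + rnorm(30)
    expect_equal(sign(olsLine(x, y)[["slope"]]), sign(pearsonR(x, y)))
  })
  expect_error(olsLine(c(1, 1, 1), c(1, 2, 3)), "constant")
})
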