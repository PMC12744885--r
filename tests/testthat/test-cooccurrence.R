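# Co-assignment statistic, permutation test, exact Poisson-binomial oracle.

# Fixture with the shape of a per-tissue co-occurrence summary: 8 cell types,
# anchors co-assigned in all 8, candidate matching in 3.
tableStyleFixture <- function() {
  assignments <- lapply(1:8, function(g) {
    fillers <- sprintf("f%02d", 1:16)
    genes <- c("A1", "A2", "cand", fillers)
    lab <- setNames(c("M1", "M1",
                      if (g <= 3) "M1" else "M2",
                      rep(c("M1", "M2", "M3"), length.out = 16)),
                    genes)
    lab
  })
  names(assignments) <- paste0("type", 1:8)
  ModulePartition(assignments)
}

test_that("anchorModules reports per-group labels and the denominator T", {
  part <- ModulePartition(list(
    A = c(A1 = "M1", A2 = "M1", x = "M2"),
    B = c(A1 = "M2", A2 = "M2", x = "M2"),
    C = c(A1 = "M1", A2 = "M3", x = "M2"),
    D = c(A1 = "unassigned", A2 = "unassigned", x = "M2")))
  am <- anchorModules(part, "A1", "A2")
  expect_identical(am, c(A = "M1", B = "M2", C = NA_character_,
                         D = NA_character_))
  expect_identical(sum(!is.na(am)), 2L)
  expect_error(anchorModules(part, "A1", "missing"), "not analysed")
})

test_that("coocCount matches brute force and its fixed points", {
  part <- tableStyleFixture()
  am <- anchorModules(part, "A1", "A2")
  expect_identical(sum(!is.na(am)), 8L)
  expect_identical(coocCount(part, "cand", am), 3L)
  # candidate equal to an anchor matches everywhere
  expect_identical(coocCount(part, "A1", am), 8L)
  # brute force re-count
  brute <- sum(vapply(names(am), function(g) {
    a <- moduleAssignments(part)[[g]]
    !is.na(am[[g]]) && a[["cand"]] == am[[g]]
  }, logical(1)))
  expect_identical(coocCount(part, "cand", am), as.integer(brute))

  partU <- ModulePartition(list(
    A = c(A1 = "M1", A2 = "M1", cand = "unassigned", x = "M1")))
  expect_identical(
    coocCount(partU, "cand", anchorModules(partU, "A1", "A2")), 0L)
})

test_that("exactTail matches hand enumeration and the 2^T oracle", {
  # q = (0.25, 0.5): P(S >= 2) = 0.125, P(S >= 1) = 0.625
  part <- ModulePartition(list(
    g1 = setNames(c("M1", "M1", "M1", "M1", rep("M2", 6)),
                  c("A1", "A2", paste0("x", 1:8))),
    g2 = setNames(c("M1", "M1", "M1", "M1", "M2", "M2"),
                  c("A1", "A2", paste0("y", 1:4)))))
  expect_equal(exactTail(part, "A1", "A2", 2), 0.125)
  expect_equal(exactTail(part, "A1", "A2", 1), 0.625)
  expect_equal(exactTail(part, "A1", "A2", 0), 1)

  # DP equals full enumeration on random partitions
  for (s in 1:20) {
    part <- randomPartition(200 + s)
    am <- anchorModules(part, "A1", "A2")
    q <- vapply(names(am)[!is.na(am)], function(g) {
      a <- moduleAssignments(part)[[g]]
      (sum(a == am[[g]]) - 2) / (length(a) - 2)
    }, numeric(1))
    for (sEmp in 0:length(q))
      expect_equal(exactTail(part, "A1", "A2", sEmp), enumTail(q, sEmp),
                   tolerance = 1e-12)
  }
})

test_that("permutation p-value matches the closed form in a single group", {
  # N = 10 analysed genes, anchor module of size 4: q = (4-2)/(10-2) = 0.25
  part <- ModulePartition(list(
    g1 = setNames(c("M1", "M1", "M1", "M1", rep("M2", 6)),
                  c("A1", "A2", "cand", paste0("x", 1:7)))))
  res <- permutationTest(part, "cand", c("cand", paste0("x", 1:7)),
                         "A1", "A2", B = 10000, seed = 2)
  expect_identical(res@sEmp, 1L)
  expect_equal(res@pExact, 0.25)
  expect_lt(abs(res@pMC - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("permutation test handles fixed points, floors and errors", {
  part <- tableStyleFixture()
  cands <- c("cand", sprintf("f%02d", 1:16))
  # f02 is outside the anchor module everywhere: S_emp = 0, P(S >= 0) = 1
  res0 <- permutationTest(part, "f02", cands, "A1", "A2", B = 500, seed = 1)
  expect_identical(res0@sEmp, 0L)
  expect_equal(res0@pMC, 1)

  # determinism
  a <- permutationTest(part, "cand", cands, "A1", "A2", B = 2000, seed = 9)
  b <- permutationTest(part, "cand", cands, "A1", "A2", B = 2000, seed = 9)
  expect_identical(a@nullCounts, b@nullCounts)
  expect_identical(a@pMC, b@pMC)

  # p is never exactly zero: an unreachable S_emp reports the 1/B floor
  partBig <- ModulePartition(lapply(setNames(nm = paste0("t", 1:10)),
    function(g) setNames(c("M1", "M1", "M1", rep("M2", 37)),
                         c("A1", "A2", "cand", sprintf("%s_x%02d", g, 1:37)))))
  resBig <- permutationTest(partBig, "cand", "cand", "A1", "A2",
                            B = 1000, seed = 3)
  expect_identical(resBig@sEmp, 10L)
  expect_true(resBig@pFloor)
  expect_equal(resBig@pMC, 1 / 1000)

  expect_error(permutationTest(part, "A1", c("A1", "cand"), "A1", "A2"),
               "anchors must not")
  partNone <- ModulePartition(list(
    g1 = c(A1 = "M1", A2 = "M2", cand = "M1", x = "M2")))
  expect_error(permutationTest(partNone, "cand", "cand", "A1", "A2"),
               "never co-assigned")
})

test_that("Monte Carlo agrees with the exact oracle across random partitions", {
  ok <- 0L
  for (s in 1:30) {
    part <- randomPartition(300 + s)
    cands <- paste0("cand", 1:5)
    res <- permutationTest(part, "cand1", cands, "A1", "A2",
                           B = 10000, seed = s)
    tol <- 3 * sqrt(res@pExact * (1 - res@pExact) / 10000)
    if (abs(res@nExceed / res@B - res@pExact) <= tol) ok <- ok + 1L
  }
  expect_gte(ok, 29L)
})

test_that("p-value is monotone non-increasing in the empirical count", {
  part <- randomPartition(77)
  am <- anchorModules(part, "A1", "A2")
  tG <- sum(!is.na(am))
  pv <- vapply(0:tG, function(s) exactTail(part, "A1", "A2", s), numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("the null law does not depend on which candidates are drawn", {
  # candidate-exchangeability: null histograms for disjoint candidate
  # panels agree in distribution (chi-square-free coarse check on means)
  part <- randomPartition(55)
  resA <- permutationTest(part, "cand1", paste0("cand", 1:2), "A1", "A2",
                          B = 20000, seed = 5)
  resB <- permutationTest(part, "cand3", paste0("cand", 3:5), "A1", "A2",
                          B = 20000, seed = 6)
  mA <- sum(as.integer(names(resA@nullCounts)) * resA@nullCounts) / 20000
  mB <- sum(as.integer(names(resB@nullCounts)) * resB@nullCounts) / 20000
  expect_lt(abs(mA - mB), 0.05)
})
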