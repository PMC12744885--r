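## Module co-assignment statistic and its significance.  S counts the
## cell-type groups in which a candidate occupies the same module as both
## anchor genes.  The null holds the anchors (and hence the anchor modules)
## fixed and permutes the module labels of all non-anchor genes within each
## group, preserving module sizes; one candidate is drawn per replicate.
## Because only the drawn candidate's permuted label enters the statistic,
## and the marginal of a uniform permutation at a single position is uniform
## over the label multiset, replicates are realised by drawing that one
## label per group — distributionally identical to materialising the full
## permutation, at a fraction of the cost.  An exact Poisson-binomial
## oracle (exactTail) covers the same null in closed form.

#' Per-group anchor modules
#'
#' For each group of the partition, the module label shared by both anchor
#' genes, or `NA` when they are in different modules, unassigned, or not
#' analysed in that group.
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param a1,a2 the anchor gene ids.
#' @return Named character vector, one entry per group (`NA` = anchors not
#'   co-assigned).  Errors if the anchors are analysed in no group at all.
#' @export
anchorModules <- function(partition, a1, a2) {
  stopifnot(is(partition, "ModulePartition"))
  asg <- moduleAssignments(partition)
  anyAnalysed <- any(vapply(asg, function(a)
    all(c(a1, a2) %in% names(a)), logical(1)))
  if (!anyAnalysed)
    stop(sprintf("anchors '%s'/'%s' are not analysed together in any group",
                 a1, a2))
  vapply(asg, function(a) {
    if (!all(c(a1, a2) %in% names(a))) return(NA_character_)
    if (a[[a1]] != a[[a2]] || a[[a1]] == "unassigned") return(NA_character_)
    a[[a1]]
  }, character(1))
}

#' Empirical co-assignment count
#'
#' The number of groups in which `candidate` carries the anchor module's
#' label.  A candidate absent from a group's analysed genes contributes no
#' match there.
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param candidate candidate gene id.
#' @param anchorsMap result of [anchorModules()].
#' @return Integer count `S`.
#' @export
coocCount <- function(partition, candidate, anchorsMap) {
  stopifnot(is(partition, "ModulePartition"))
  asg <- moduleAssignments(partition)
  s <- 0L
  for (g in names(asg)) {
    lab <- anchorsMap[[g]]
    if (is.na(lab)) next
    a <- asg[[g]]
    if (candidate %in% names(a) && a[[candidate]] == lab) s <- s + 1L
  }
  s
}

#' Monte Carlo permutation test of module co-assignment
#'
#' Tests whether `candidate` shares a module with both anchors in more
#' groups than expected by chance.  Each of the `B` replicates permutes,
#' within every group, the module labels of all non-anchor genes (module
#' sizes preserved, anchors held fixed so the anchor modules are
#' conditioned on), draws one gene uniformly from `candidates`, and records
#' its co-assignment count.  The p-value is the proportion of replicates
#' whose null count reaches the empirical count; when no replicate does,
#' the p-value is reported as `< 1/B` (slot `pFloor`), never 0.
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param candidate the candidate of interest (the empirical statistic is
#'   its count).
#' @param candidates the candidate panel the null draws from; must not
#'   contain the anchors.
#' @param a1,a2 anchor gene ids.
#' @param B number of replicates (default 10000).
#' @param seed integer RNG seed.
#' @param exact if `TRUE` (default) also compute the exact
#'   Poisson-binomial tail via [exactTail()]; set `FALSE` when candidate
#'   eligibility differs across groups, where the closed form does not
#'   apply.
#' @return A \linkS4class{CoocResult}.
#' @examples
#' part <- ModulePartition(list(
#'   g1 = setNames(c("M1", "M1", "M1", "M1", rep("M2", 6)),
#'                 c("A", "B", "cand", paste0("x", 1:7)))))
#' permutationTest(part, "cand", c("cand", paste0("x", 1:7)),
#'                 "A", "B", B = 2000, seed = 1)
#' @export
permutationTest <- function(partition, candidate, candidates, a1, a2,
                            B = 10000L, seed = 1L, exact = TRUE) {
  stopifnot(is(partition, "ModulePartition"), B >= 1L,
            length(candidates) >= 1L)
  if (any(c(a1, a2) %in% candidates))
    stop("anchors must not appear in the candidate panel")
  if (!candidate %in% candidates)
    stop("'candidate' must be one of 'candidates'")
  anchorsMap <- anchorModules(partition, a1, a2)
  tGroups <- sum(!is.na(anchorsMap))
  if (tGroups == 0L)
    stop("anchors never co-assigned: the co-assignment statistic is undefined")
  sEmp <- coocCount(partition, candidate, anchorsMap)

  asg <- moduleAssignments(partition)
  groups <- names(anchorsMap)[!is.na(anchorsMap)]
  ## per relevant group: multiset of non-anchor labels and, per candidate,
  ## whether it was analysed there
  labelPool <- lapply(groups, function(g)
    unname(asg[[g]][setdiff(names(asg[[g]]), c(a1, a2))]))
  eligible <- vapply(groups, function(g)
    candidates %in% names(asg[[g]]), logical(length(candidates)))
  eligible <- matrix(eligible, nrow = length(candidates))  # candidates x groups

  sNull <- withSeed(seed, {
    drawn <- sample.int(length(candidates), B, replace = TRUE)
    s <- integer(B)
    for (j in seq_along(groups)) {
      pool <- labelPool[[j]]
      hit <- pool[sample.int(length(pool), B, replace = TRUE)] ==
        anchorsMap[[groups[j]]]
      s <- s + as.integer(hit & eligible[drawn, j])
    }
    s
  })
  nExceed <- sum(sNull >= sEmp)
  pFloor <- nExceed == 0L
  pMC <- if (pFloor) 1 / B else nExceed / B
  pExact <- if (exact) exactTail(partition, a1, a2, sEmp) else NA_real_
  hist <- tabulate(sNull + 1L, nbins = tGroups + 1L)
  names(hist) <- 0:tGroups
  new("CoocResult", candidate = candidate, sEmp = sEmp,
      nGroups = as.integer(tGroups), B = as.integer(B),
      nExceed = as.integer(nExceed), pMC = pMC, pFloor = pFloor,
      pExact = pExact, nullCounts = hist, seed = as.integer(seed))
}

#' Exact tail probability of the null co-assignment count
#'
#' Under the size-preserving permutation null with anchors held fixed, a
#' random non-anchor gene lands in group g's anchor module with probability
#' `q_g = (m_g - 2) / (N_g - 2)` (`m_g` = anchor module size, `N_g` =
#' analysed genes in g).  The null count over the anchor-module groups is
#' then Poisson-binomial; this computes `P(S >= sEmp)` by dynamic
#' programming over groups.  Assumes the drawn candidate is analysed in
#' every anchor-module group.
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param a1,a2 anchor gene ids.
#' @param sEmp empirical count whose tail probability is wanted.
#' @return `P(S >= sEmp)` in [0, 1]; 1 when `sEmp <= 0`.
#' @examples
#' # two anchor-module groups with q = (0.25, 0.5): P(S >= 2) = 0.125
#' part <- ModulePartition(list(
#'   g1 = setNames(c("M1", "M1", "M1", "M1", rep("M2", 6)),
#'                 c("A", "B", paste0("x", 1:8))),
#'   g2 = setNames(c("M1", "M1", "M1", "M1", "M2", "M2"),
#'                 c("A", "B", paste0("y", 1:4)))))
#' exactTail(part, "A", "B", 2)
#' @export
exactTail <- function(partition, a1, a2, sEmp) {
  stopifnot(is(partition, "ModulePartition"))
  anchorsMap <- anchorModules(partition, a1, a2)
  asg <- moduleAssignments(partition)
  groups <- names(anchorsMap)[!is.na(anchorsMap)]
  if (!length(groups))
    stop("anchors never co-assigned: tail undefined")
  q <- vapply(groups, function(g) {
    a <- asg[[g]]
    n <- length(a)
    if (n <= 2L) stop(sprintf("group '%s' has too few analysed genes", g))
    m <- sum(a == anchorsMap[[g]])
    (m - 2) / (n - 2)
  }, numeric(1))
  if (sEmp <= 0L) return(1)
  ## Poisson-binomial pmf by DP over groups
  pmf <- 1
  for (qi in q) pmf <- c(pmf * (1 - qi), 0) + c(0, pmf * qi)
  sum(pmf[(sEmp + 1L):length(pmf)])
}
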