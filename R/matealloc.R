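## Mate allocation among selected parents: minimize the contribution-
## weighted coancestry sum C.M with C_ij = cd_i * H_ij * cs_j, at most
## kappaD matings per dam, at least kappaS per sire and a per-pair cap
## (1 in binary mode, sigmaD in integer mode). The constraint matrix is a
## transportation structure (totally unimodular), so the continuous
## relaxation -- solved here as a min-cost flow -- has integral optima.

#' Construct a mate-allocation problem
#'
#' @param cd,cs positive dam and sire contributions (named vectors).
#' @param H dam-by-sire genomic coancestry block.
#' @param kappaD maximum matings per dam (default 3).
#' @param kappaS minimum matings per sire (default 0, which prunes sires
#'   with unhelpful coancestry; values >= 1 are supported but can be
#'   restrictive when contributions are tiny).
#' @param sigmaD per-pair cap in integer mode (default `kappaD`).
#' @param mode `"binary"` (each pair mated at most once) or `"integer"`.
#' @return A [MatingProblem-class].
#' @export
MatingProblem <- function(cd, cs, H, kappaD = 3L, kappaS = 0L,
                          sigmaD = kappaD, mode = c("binary", "integer")) {
  mode <- match.arg(mode)
  H <- as.matrix(H)
  if (nrow(H) != length(cd) || ncol(H) != length(cs))
    stop("H must be length(cd) x length(cs)")
  new("MatingProblem", cd = unname(as.numeric(cd)), cs = unname(as.numeric(cs)),
      H = H, kappaD = as.integer(kappaD), kappaS = as.integer(kappaS),
      sigmaD = as.integer(sigmaD), mode = mode)
}

setMethod("show", "MatingProblem", function(object) {
  cat("MatingProblem:", length(object@cd), "dams x", length(object@cs),
      "sires,", object@mode, "mode, kappaD =", object@kappaD,
      "kappaS =", object@kappaS, "\n")
})

setMethod("show", "MatingPlan", function(object) {
  cat("MatingPlan (", object@solver, "): ", object@nMatings, " matings, ",
      "objective ", format(object@objective, digits = 6), "\n", sep = "")
  used <- which(object@M > 0, arr.ind = TRUE)
  cat("  dams used:", length(unique(used[, 1L])),
      " sires used:", length(unique(used[, 2L])), "\n")
})

pairCap <- function(p) if (p@mode == "binary") 1L else p@sigmaD

makePlan <- function(M, C, solver) {
  M <- round(M)
  new("MatingPlan", M = M, objective = sum(C * M),
      nMatings = as.integer(sum(M)), solver = solver)
}

#' Linearized mating cost matrix
#'
#' \eqn{C_{ij} = c_{d,i} H_{ij} c_{s,j}}: because contributions and
#' coancestries are constants at this stage, the quadratic-looking objective
#' \eqn{c_d^\top (H \odot M) c_s} is linear in the mating counts M.
#'
#' @param p a [MatingProblem-class].
#' @return nd x ns numeric cost matrix (dimnames from H).
#' @export
buildCostMatrix <- function(p) {
  stopifnot(is(p, "MatingProblem"))
  C <- outer(p@cd, p@cs) * p@H
  dimnames(C) <- dimnames(p@H)
  C
}

#' Closed-form mate allocation for kappaS = 0
#'
#' With no minimum-mating constraint on sires the rows of the program
#' decouple: each dam independently fills her `kappaD` matings with the
#' most negative cost entries (up to `cap` per pair), never allocating to
#' nonnegative costs. Ties go to the lowest sire index. This is provably
#' optimal for the decoupled rows.
#'
#' @param C cost matrix.
#' @param kappaD maximum matings per dam.
#' @param cap per-pair cap.
#' @return A [MatingPlan-class].
#' @export
solveMatingGreedy <- function(C, kappaD, cap = 1L) {
  C <- as.matrix(C)
  M <- matrix(0L, nrow(C), ncol(C), dimnames = dimnames(C))
  for (i in seq_len(nrow(C))) {
    remaining <- kappaD
    for (j in order(C[i, ], seq_len(ncol(C)))) {
      if (remaining == 0L || C[i, j] >= 0) break
      take <- min(cap, remaining)
      M[i, j] <- take
      remaining <- remaining - take
    }
  }
  makePlan(M, C, "greedy")
}

## ---- min-cost-flow LP relaxation -------------------------------------

## Successive-shortest-path min-cost flow on the transportation graph
## source -> dam (cap kappaD - sum(lower)) -> sire (cap upper - lower,
## cost C) -> sink (a "required" arc of capacity r_j at cost -BIG forcing
## column minima, plus a free arc). Augments along Bellman-Ford shortest
## paths while they have negative cost; integral capacities give an
## integral optimal flow, which by total unimodularity is also the LP
## relaxation optimum.
relaxMating <- function(C, kappaD, kappaS, lower, upper) {
  nd <- nrow(C); ns <- ncol(C)
  rowUsed <- rowSums(lower)
  if (any(rowUsed > kappaD)) return(list(feasible = FALSE))
  if (any(lower > upper)) return(list(feasible = FALSE))
  req <- pmax(0, kappaS - colSums(lower))
  baseCost <- sum(C * lower)
  BIG <- max(abs(C), 1) + 1

  S <- 1L; Dn <- 1L + seq_len(nd); Sn <- 1L + nd + seq_len(ns)
  Tn <- 2L + nd + ns
  nNode <- Tn
  ## arc arrays; paired forward/backward at 2k-1 / 2k
  from <- to <- integer(0); cap <- cost <- numeric(0)
  addArc <- function(u, v, cp, cs) {
    from <<- c(from, u, v); to <<- c(to, v, u)
    cap <<- c(cap, cp, 0); cost <<- c(cost, cs, -cs)
  }
  for (i in seq_len(nd)) addArc(S, Dn[i], kappaD - rowUsed[i], 0)
  pairArc <- matrix(0L, nd, ns)
  for (i in seq_len(nd)) for (j in seq_len(ns)) {
    addArc(Dn[i], Sn[j], upper[i, j] - lower[i, j], C[i, j])
    pairArc[i, j] <- length(cap) - 1L
  }
  reqArc <- integer(ns)
  for (j in seq_len(ns)) {
    addArc(Sn[j], Tn, req[j], -BIG)
    reqArc[j] <- length(cap) - 1L
    addArc(Sn[j], Tn, nd * max(upper[, j]), 0)
  }
  nArc <- length(cap)

  repeat {
    ## Bellman-Ford shortest path S -> Tn on the residual graph,
    ## vectorized over arcs (Jacobi-style simultaneous relaxation)
    dist <- rep(Inf, nNode); dist[S] <- 0
    prevArc <- integer(nNode)
    act <- which(cap > 1e-9)
    for (pass in seq_len(nNode)) {
      cand <- dist[from[act]] + cost[act]
      ok <- is.finite(cand) & cand < dist[to[act]] - 1e-12
      if (!any(ok)) break
      sub <- act[ok]
      o <- order(to[sub], dist[from[sub]] + cost[sub])
      sel <- sub[o][!duplicated(to[sub][o])]
      dist[to[sel]] <- dist[from[sel]] + cost[sel]
      prevArc[to[sel]] <- sel
    }
    if (!is.finite(dist[Tn]) || dist[Tn] >= -1e-9) break
    ## bottleneck along the path
    bn <- Inf; v <- Tn
    while (v != S) { a <- prevArc[v]; bn <- min(bn, cap[a]); v <- from[a] }
    v <- Tn
    while (v != S) {
      a <- prevArc[v]
      cap[a] <- cap[a] - bn
      mate <- if (a %% 2L == 1L) a + 1L else a - 1L
      cap[mate] <- cap[mate] + bn
      v <- from[a]
    }
  }

  if (any(cap[reqArc] > 1e-9)) return(list(feasible = FALSE))
  flow <- matrix(0, nd, ns)
  for (i in seq_len(nd)) for (j in seq_len(ns)) {
    a <- pairArc[i, j]
    flow[i, j] <- (upper[i, j] - lower[i, j]) - cap[a]
  }
  M <- lower + flow
  list(feasible = TRUE, M = M, value = baseCost + sum(C * flow))
}

#' Continuous relaxation of a mate-allocation problem
#'
#' Solves the LP relaxation (0 <= M <= cap, row sums <= kappaD, column sums
#' >= kappaS) exactly via min-cost flow. Because the constraint matrix is
#' totally unimodular the returned optimum is integral and its value equals
#' the integer optimum.
#'
#' @param p a [MatingProblem-class].
#' @return list with `value` (relaxation optimum) and `M` (an optimal,
#'   integral allocation), or `feasible = FALSE`.
#' @export
solveMatingRelaxation <- function(p) {
  stopifnot(is(p, "MatingProblem"))
  C <- buildCostMatrix(p)
  cap <- pairCap(p)
  relaxMating(C, p@kappaD, p@kappaS,
              matrix(0L, nrow(C), ncol(C)),
              matrix(as.integer(cap), nrow(C), ncol(C)))
}

checkMatingFeasible <- function(p) {
  nd <- length(p@cd); ns <- length(p@cs); cap <- pairCap(p)
  if (p@kappaS * ns > p@kappaD * nd)
    stop("infeasible mating constraints: total sire minimum kappaS*ns = ",
         p@kappaS * ns, " exceeds total dam capacity kappaD*nd = ",
         p@kappaD * nd)
  if (p@kappaS > nd * cap)
    stop("infeasible mating constraints: a sire needs kappaS = ", p@kappaS,
         " matings but at most nd*cap = ", nd * cap, " are possible")
  invisible(TRUE)
}

#' Exact mate allocation by branch-and-bound
#'
#' Depth-first branch-and-bound over the entries of M. Each node's lower
#' bound is the continuous relaxation under the node's entry bounds, solved
#' by [solveMatingRelaxation()]'s min-cost-flow routine; nodes whose bound
#' cannot improve on the incumbent are pruned, and fractional relaxation
#' solutions are branched on the most fractional entry (lowest dam, then
#' sire, index on ties). With this transportation structure the relaxation
#' comes back integral, so the search typically certifies optimality at the
#' root node.
#'
#' @param p a [MatingProblem-class].
#' @param nodeLimit branch-and-bound node cap (default 1e6).
#' @return A [MatingPlan-class] with the certified optimal plan.
#' @export
solveMatingBnB <- function(p, nodeLimit = 1e6) {
  stopifnot(is(p, "MatingProblem"))
  checkMatingFeasible(p)
  C <- buildCostMatrix(p)
  nd <- nrow(C); ns <- ncol(C); cap <- pairCap(p)
  best <- list(value = Inf, M = NULL)
  nodes <- 0L

  recurse <- function(lower, upper) {
    nodes <<- nodes + 1L
    if (nodes > nodeLimit) stop("search limit: branch-and-bound node cap exceeded")
    rel <- relaxMating(C, p@kappaD, p@kappaS, lower, upper)
    if (!rel$feasible) return(invisible(NULL))
    if (rel$value >= best$value - 1e-12) return(invisible(NULL))
    frac <- abs(rel$M - round(rel$M))
    if (max(frac) <= 1e-9) {
      best <<- list(value = rel$value, M = round(rel$M))
      return(invisible(NULL))
    }
    ## branch on the most fractional entry (lowest indices on ties)
    k <- which(frac == max(frac))[1L]
    i <- row(C)[k]; j <- col(C)[k]
    f <- floor(rel$M[i, j])
    upF <- upper; upF[i, j] <- f
    recurse(lower, upF)
    loC <- lower; loC[i, j] <- f + 1
    recurse(loC, upper)
  }

  recurse(matrix(0L, nd, ns), matrix(as.integer(cap), nd, ns))
  if (is.null(best$M))
    stop("infeasible mating constraints: no allocation satisfies the ",
         "row/column aggregates")
  M <- best$M
  dimnames(M) <- dimnames(p@H)
  makePlan(M, C, "bnb")
}

#' Exhaustive mate-allocation oracle
#'
#' Enumerates every feasible mating matrix (all entries in `0:cap`) and
#' returns the minimum-objective plan, preferring the lexicographically
#' smallest matrix (row-major entry order) on objective ties. Intended as a
#' test oracle for tiny instances.
#'
#' @param p a [MatingProblem-class].
#' @return A [MatingPlan-class].
#' @export
enumerateMatings <- function(p) {
  stopifnot(is(p, "MatingProblem"))
  C <- buildCostMatrix(p)
  nd <- nrow(C); ns <- ncol(C); cap <- pairCap(p)
  nCells <- nd * ns
  total <- (cap + 1)^nCells
  if (total > 1e7) stop("instance too large for exhaustive enumeration")
  best <- list(value = Inf, M = NULL)
  e <- integer(nCells)                       # row-major entries
  Crm <- as.numeric(t(C))                    # row-major costs
  repeat {
    M <- matrix(e, nd, ns, byrow = TRUE)
    if (all(rowSums(M) <= p@kappaD) && all(colSums(M) >= p@kappaS)) {
      val <- sum(Crm * e)
      if (val < best$value - 1e-12) best <- list(value = val, M = M)
    }
    ## mixed-radix increment, last cell fastest: visits matrices in
    ## lexicographic (row-major) order, so ties keep the smallest
    k <- nCells
    while (k >= 1L && e[k] == cap) { e[k] <- 0L; k <- k - 1L }
    if (k < 1L) break
    e[k] <- e[k] + 1L
  }
  if (is.null(best$M)) stop("infeasible mating constraints")
  M <- best$M
  dimnames(M) <- dimnames(p@H)
  makePlan(M, C, "exhaustive")
}
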