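## Evaluation statistics for mating plans (future coancestry theta_f and
## genetic gain delta_u) and the truncation-selection / random-mating
## baseline schemes.

#' Future coancestry of a mating plan
#'
#' The mating-count-weighted mean coancestry of the mated dam-sire pairs:
#' \eqn{\theta_f = \sum_{ij} M_{ij} H_{ij} / \sum_{ij} M_{ij}}. Only
#' dam-by-sire coancestries enter; self- and within-sex terms do not.
#'
#' @param plan a [MatingPlan-class].
#' @param H dam-by-sire coancestry block matching the plan's dimensions.
#' @return scalar \eqn{\theta_f} (dimensionless).
#' @export
futureCoancestry <- function(plan, H) {
  stopifnot(is(plan, "MatingPlan"))
  H <- as.matrix(H)
  if (!all(dim(plan@M) == dim(H))) stop("plan and H dimensions differ")
  if (plan@nMatings < 1L) stop("no matings in plan")
  sum(plan@M * H) / plan@nMatings
}

#' Genetic gain of a mating plan
#'
#' \eqn{\Delta\hat u = E(\hat u_{sel}) - E(\hat u_{pop})}, where the
#' selected mean is the mating-count-weighted mean of parental midpoints
#' (each mating contributes \eqn{(\hat u_{dam} + \hat u_{sire})/2}) and the
#' population mean is the unweighted mean over all candidates.
#'
#' @param plan a [MatingPlan-class].
#' @param damEbv,sireEbv breeding values of the plan's dams (rows) and
#'   sires (columns).
#' @param popEbv breeding values of the entire breeding population.
#' @return scalar gain in trait units.
#' @export
geneticGain <- function(plan, damEbv, sireEbv, popEbv) {
  stopifnot(is(plan, "MatingPlan"))
  if (length(damEbv) != nrow(plan@M) || length(sireEbv) != ncol(plan@M))
    stop("breeding-value vectors do not match plan dimensions")
  if (plan@nMatings < 1L) stop("no matings in plan")
  selMean <- sum(plan@M * outer(damEbv, sireEbv, "+")) / (2 * plan@nMatings)
  selMean - mean(popEbv)
}

#' Random mating plan among selected parents
#'
#' Dams are filled in order with up to `kappaD` matings each until
#' `nMatings` total; every mating's sire is drawn uniformly with
#' replacement. Deterministic given the seed.
#'
#' @param damIds,sireIds identifiers of the selected parents.
#' @param kappaD maximum matings per dam.
#' @param nMatings total matings to place.
#' @param seed RNG seed.
#' @return A [MatingPlan-class] (its objective slot is 0: random plans
#'   carry no cost matrix).
#' @export
randomMatingPlan <- function(damIds, sireIds, kappaD, nMatings, seed = 1L) {
  nd <- length(damIds); ns <- length(sireIds)
  if (nd < 1L || ns < 1L) stop("need at least one dam and one sire")
  if (nMatings > kappaD * nd)
    stop("nMatings = ", nMatings, " exceeds total dam capacity kappaD*nd = ",
         kappaD * nd)
  M <- matrix(0L, nd, ns, dimnames = list(damIds, sireIds))
  withSeed(seed, {
    dam <- rep(seq_len(nd), each = kappaD)[seq_len(nMatings)]
    sire <- sample.int(ns, nMatings, replace = TRUE)
    for (k in seq_len(nMatings)) M[dam[k], sire[k]] <- M[dam[k], sire[k]] + 1L
  })
  new("MatingPlan", M = M, objective = 0, nMatings = as.integer(nMatings),
      solver = "random")
}

#' Truncation selection followed by random mating
#'
#' Selects the top `nDams` females and `nSires` males by breeding value
#' (ties broken by lowest id) and places `nMatings` random matings among
#' them via [randomMatingPlan()].
#'
#' @param pop population data.frame (`id`, `sex`, `ebv`).
#' @param nDams,nSires number of parents to keep per sex.
#' @param kappaD maximum matings per dam.
#' @param nMatings total matings (default `kappaD * nDams`).
#' @param seed RNG seed.
#' @return list with `plan` ([MatingPlan-class]), `damIds`, `sireIds`.
#' @export
truncationPlan <- function(pop, nDams, nSires, kappaD, nMatings = kappaD * nDams,
                           seed = 1L) {
  pop <- validatePopulation(pop)
  topIds <- function(sub, k) {
    if (nrow(sub) < k) stop("insufficient candidates: need ", k, " of sex ",
                            as.character(sub$sex[1]), ", have ", nrow(sub))
    sub$id[order(-sub$ebv, sub$id)][seq_len(k)]
  }
  damIds <- topIds(pop[pop$sex == "F", ], nDams)
  sireIds <- topIds(pop[pop$sex == "M", ], nSires)
  list(plan = randomMatingPlan(damIds, sireIds, kappaD, nMatings, seed),
       damIds = damIds, sireIds = sireIds)
}

## evaluate one plan against a population and full G
planStats <- function(plan, damIds, sireIds, pop, grm) {
  H <- grm@values[damIds, sireIds, drop = FALSE]
  ebv <- stats::setNames(pop$ebv, pop$id)
  data.frame(theta_f = futureCoancestry(plan, H),
             delta_u = geneticGain(plan, ebv[damIds], ebv[sireIds], pop$ebv),
             n_matings = plan@nMatings)
}

#' Compare breeding schemes on a common population
#'
#' Builds the four-scheme comparison: truncation selection + random mating
#' (TSRM), OCS-selected parents + random mating (GOCSRM), and OCS followed
#' by optimal binary / integer mate allocation (GOCSMA-bin / GOCSMA-int).
#' Random schemes are averaged over `replicates` seeded replicates
#' (replicate r uses `seed + r`); the optimized plans are deterministic and
#' evaluated once. TSRM uses the same numbers of dams and sires as the OCS
#' solution unless overridden, and the same total matings as the integer
#' plan.
#'
#' @param sel output of [extractSelected()] (OCS-selected parents).
#' @param binPlan,intPlan binary and integer [MatingPlan-class]s over
#'   `sel`'s dams and sires.
#' @param pop population data.frame (all candidates).
#' @param grm [RelationshipMatrix-class] over all candidates.
#' @param kappaD maximum matings per dam used by the random schemes.
#' @param replicates number of random-mating replicates (default 100).
#' @param seed master seed.
#' @param nDamsTS,nSiresTS truncation-selection parent counts
#'   (default: same as the OCS solution).
#' @return data.frame with one row per scheme: `scheme`, `theta_f`,
#'   `delta_u`, `n_matings`, `replicates`.
#' @export
compareSchemes <- function(sel, binPlan, intPlan, pop, grm, kappaD = 3L,
                           replicates = 100L, seed = 1L,
                           nDamsTS = length(sel$damIds),
                           nSiresTS = length(sel$sireIds)) {
  pop <- validatePopulation(pop)
  stopifnot(is(grm, "RelationshipMatrix"))
  nMatings <- intPlan@nMatings

  randomAvg <- function(scheme, planFun) {
    reps <- lapply(seq_len(replicates), function(r) planFun(seed + r))
    stats <- do.call(rbind, reps)
    data.frame(scheme = scheme, theta_f = mean(stats$theta_f),
               delta_u = mean(stats$delta_u),
               n_matings = stats$n_matings[1L], replicates = replicates)
  }

  tsrm <- randomAvg("TSRM", function(s) {
    tr <- truncationPlan(pop, nDamsTS, nSiresTS, kappaD, nMatings, seed = s)
    planStats(tr$plan, tr$damIds, tr$sireIds, pop, grm)
  })
  gocsrm <- randomAvg("GOCSRM", function(s) {
    pl <- randomMatingPlan(sel$damIds, sel$sireIds, kappaD, nMatings, seed = s)
    planStats(pl, sel$damIds, sel$sireIds, pop, grm)
  })
  det <- function(scheme, plan)
    cbind(scheme = scheme,
          planStats(plan, sel$damIds, sel$sireIds, pop, grm),
          replicates = 1L)

  out <- rbind(tsrm, gocsrm, det("GOCSMA-bin", binPlan),
               det("GOCSMA-int", intPlan))
  rownames(out) <- NULL
  out
}
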