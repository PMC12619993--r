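#' @import methods
#' @importFrom stats rbinom rnorm runif sd var
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GenotypeMatrix: individual-by-marker SNP dosages
#'
#' Holds additively coded SNP genotypes: each entry counts copies (0, 1 or 2)
#' of the tracked allele for one individual at one marker. Rows are
#' individuals, columns are marker loci; both carry identifiers. Missing
#' genotypes are `NA`.
#'
#' @slot dosages numeric matrix of codes in \{0, 1, 2, NA\} with rownames =
#'   individual ids and colnames = locus ids.
#'
#' @seealso [readGenotypes()], [alleleFrequencies()], [mafFilter()],
#'   [computeGRM()]
#' @export
setClass("GenotypeMatrix", representation(dosages = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  if (!is.numeric(d)) return("dosages must be a numeric matrix")
  if (is.null(rownames(d)) || (ncol(d) > 0L && is.null(colnames(d))))
    return("dosages must have individual ids as rownames and locus ids as colnames")
  if (anyDuplicated(rownames(d))) return("duplicated individual ids")
  if (anyDuplicated(colnames(d))) return("duplicated locus ids")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    return("all non-missing dosages must be 0, 1 or 2")
  TRUE
})

#' RelationshipMatrix: genomic coancestry coefficients
#'
#' A symmetric matrix of pairwise genomic relationship coefficients among a
#' set of individuals, typically built from centered SNP dosages by
#' [computeGRM()] (VanRaden method 1). With sample-estimated allele
#' frequencies the rows sum to zero, so off-diagonal entries below zero are
#' expected (less related than the population average).
#'
#' @slot values symmetric numeric matrix with identical row/col names
#'   (individual ids).
#'
#' @export
setClass("RelationshipMatrix", representation(values = "matrix"))

setValidity("RelationshipMatrix", function(object) {
  g <- object@values
  if (!is.numeric(g) || nrow(g) != ncol(g)) return("values must be a square numeric matrix")
  if (is.null(rownames(g)) || !identical(rownames(g), colnames(g)))
    return("row and column ids must be present and identical")
  if (max(abs(g - t(g))) > 1e-10) return("matrix not symmetric within 1e-10")
  if (any(diag(g) < 0)) return("negative diagonal entry")
  TRUE
})

#' ADMMSettings: tuning parameters for the conic ADMM solver
#'
#' @slot epsAbs absolute convergence tolerance on the primal/dual residual
#'   norms (default 1e-5).
#' @slot epsRel relative convergence tolerance (default 1e-5).
#' @slot gamma0 initial ADMM penalty parameter (default 0.1).
#' @slot adaptiveGamma logical; residual-balancing adaptation of the penalty
#'   (default TRUE).
#' @slot maxIter iteration cap (default 20000).
#' @slot rhoZero contributions below this threshold are set to exactly zero
#'   after solving (default 1e-4).
#' @slot feasTol feasibility tolerance the reported solution must meet on the
#'   original constraints (default 1e-6).
#'
#' @export
setClass("ADMMSettings",
  representation(epsAbs = "numeric", epsRel = "numeric", gamma0 = "numeric",
                 adaptiveGamma = "logical", maxIter = "integer",
                 rhoZero = "numeric", feasTol = "numeric"),
  prototype(epsAbs = 1e-5, epsRel = 1e-5, gamma0 = 0.1, adaptiveGamma = TRUE,
            maxIter = 20000L, rhoZero = 1e-4, feasTol = 1e-6))

setValidity("ADMMSettings", function(object) {
  if (object@epsAbs <= 0 || object@epsRel <= 0) return("tolerances must be > 0")
  if (object@gamma0 <= 0) return("gamma0 must be > 0")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@rhoZero < 0) return("rhoZero must be >= 0")
  if (object@feasTol <= 0) return("feasTol must be > 0")
  TRUE
})

#' OCSProblem: an optimum contribution selection instance
#'
#' Bundles the ingredients of the OCS program: maximize \eqn{c^\top \hat u}
#' over contributions \eqn{c \ge 0} subject to the coancestry bound
#' \eqn{c^\top G c / 2 \le \theta} and the per-sex sums
#' \eqn{c^\top s = c^\top d = 0.5}.
#'
#' @slot ebv numeric vector of estimated breeding values, one per candidate.
#' @slot grm [RelationshipMatrix-class] over the same candidates, same order.
#' @slot isMale logical vector; `TRUE` for sires, `FALSE` for dams.
#' @slot theta maximum allowed mean coancestry of the next generation (> 0).
#'
#' @export
setClass("OCSProblem",
  representation(ebv = "numeric", grm = "RelationshipMatrix",
                 isMale = "logical", theta = "numeric"))

setValidity("OCSProblem", function(object) {
  n <- length(object@ebv)
  if (nrow(object@grm@values) != n) return("ebv length must match grm dimension")
  if (length(object@isMale) != n) return("isMale length must match ebv")
  if (anyNA(object@isMale) || anyNA(object@ebv)) return("NA in ebv or isMale")
  if (!any(object@isMale) || all(object@isMale)) return("both sexes must be present")
  if (length(object@theta) != 1L || object@theta <= 0) return("theta must be a single value > 0")
  TRUE
})

#' ContributionSolution: output of the OCS solver
#'
#' @slot contributions named nonnegative vector c (0.5 per sex up to the
#'   feasibility tolerance).
#' @slot objective value of \eqn{c^\top \hat u} (trait units).
#' @slot iterations ADMM iterations performed.
#' @slot status `"converged"` or `"max_iter"`.
#' @slot rNorm,sNorm primal and dual residual norms at exit.
#' @slot jitter diagonal jitter added to G for the Cholesky factorization.
#' @slot gamma penalty parameter at exit.
#'
#' @export
setClass("ContributionSolution",
  representation(contributions = "numeric", objective = "numeric",
                 iterations = "integer", status = "character",
                 rNorm = "numeric", sNorm = "numeric", jitter = "numeric",
                 gamma = "numeric"))

#' MatingProblem: a mate-allocation instance
#'
#' Minimize \eqn{\sum_{ij} c_{d,i} H_{ij} c_{s,j} M_{ij}} over integer mating
#' counts M with at most `kappaD` matings per dam, at least `kappaS` per
#' sire, and per-pair cap 1 (binary mode) or `sigmaD` (integer mode).
#'
#' @slot cd,cs positive dam and sire contributions.
#' @slot H dam-by-sire genomic coancestry block.
#' @slot kappaD maximum matings per dam (>= 1).
#' @slot kappaS minimum matings per sire (>= 0; default 0 prunes low-use sires).
#' @slot sigmaD per-pair mating cap in integer mode.
#' @slot mode `"binary"` or `"integer"`.
#'
#' @export
setClass("MatingProblem",
  representation(cd = "numeric", cs = "numeric", H = "matrix",
                 kappaD = "integer", kappaS = "integer", sigmaD = "integer",
                 mode = "character"))

setValidity("MatingProblem", function(object) {
  if (any(object@cd <= 0) || any(object@cs <= 0)) return("contributions must be > 0")
  if (nrow(object@H) != length(object@cd) || ncol(object@H) != length(object@cs))
    return("H dimensions must match cd x cs")
  if (object@kappaD < 1L) return("kappaD must be >= 1")
  if (object@kappaS < 0L) return("kappaS must be >= 0")
  if (!object@mode %in% c("binary", "integer")) return("mode must be 'binary' or 'integer'")
  if (object@mode == "integer" && object@sigmaD < 1L) return("sigmaD must be >= 1")
  TRUE
})

#' MatingPlan: a mating-count matrix with its objective
#'
#' @slot M dam-by-sire matrix of nonnegative integer mating counts.
#' @slot objective \eqn{\sum_{ij} C_{ij} M_{ij}} under the plan's cost matrix.
#' @slot nMatings total number of matings, `sum(M)`.
#' @slot solver which algorithm produced the plan
#'   (`"greedy"`, `"bnb"`, `"exhaustive"` or `"random"`).
#'
#' @export
setClass("MatingPlan",
  representation(M = "matrix", objective = "numeric", nMatings = "integer",
                 solver = "character"))

setValidity("MatingPlan", function(object) {
  if (any(object@M < 0) || max(abs(object@M - round(object@M))) > 1e-9)
    return("M must contain nonnegative integers")
  if (object@nMatings != round(sum(object@M))) return("nMatings inconsistent with M")
  TRUE
})
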