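## Optimum contribution selection: maximize c'u subject to c'Gc/2 <= theta,
## per-sex contribution sums of 0.5 and c >= 0, solved by a conic
## operator-splitting ADMM (second-order-cone reformulation of the
## coancestry bound).

#' Construct ADMM solver settings
#'
#' @param epsAbs,epsRel absolute/relative residual tolerances (default 1e-5).
#' @param gamma0 initial penalty parameter (default 0.1).
#' @param adaptiveGamma residual-balancing penalty adaptation (default TRUE).
#' @param maxIter iteration cap (default 20000).
#' @param rhoZero post-solve zero threshold for contributions (default 1e-4).
#' @param feasTol feasibility tolerance guaranteed on the reported solution
#'   (default 1e-6).
#' @return An [ADMMSettings-class].
#' @export
ADMMSettings <- function(epsAbs = 1e-5, epsRel = 1e-5, gamma0 = 0.1,
                         adaptiveGamma = TRUE, maxIter = 20000L,
                         rhoZero = 1e-4, feasTol = 1e-6) {
  new("ADMMSettings", epsAbs = epsAbs, epsRel = epsRel, gamma0 = gamma0,
      adaptiveGamma = adaptiveGamma, maxIter = as.integer(maxIter),
      rhoZero = rhoZero, feasTol = feasTol)
}

#' Construct an OCS problem
#'
#' @param pop population data.frame with columns `id`, `sex` (F/M), `ebv`.
#' @param grm a [RelationshipMatrix-class] covering (at least) the
#'   population's ids.
#' @param theta maximum allowed mean coancestry of the next generation.
#' @return An [OCSProblem-class]; candidates are ordered as in `pop`.
#' @export
OCSProblem <- function(pop, grm, theta) {
  pop <- validatePopulation(pop)
  stopifnot(is(grm, "RelationshipMatrix"))
  if (!all(pop$id %in% individualIds(grm)))
    stop("population ids missing from the relationship matrix")
  g <- grm@values[pop$id, pop$id, drop = FALSE]
  new("OCSProblem", ebv = stats::setNames(pop$ebv, pop$id),
      grm = RelationshipMatrix(g, ids = pop$id),
      isMale = pop$sex == "M", theta = theta)
}

setMethod("show", "OCSProblem", function(object) {
  cat("OCSProblem:", length(object@ebv), "candidates (",
      sum(!object@isMale), "F /", sum(object@isMale), "M ), theta =",
      object@theta, "\n")
})

setMethod("show", "ContributionSolution", function(object) {
  cat("ContributionSolution:", object@status, "after", object@iterations,
      "iterations\n")
  cat(sprintf("  objective c'u = %.6g (minimized form %.6g)\n",
              object@objective, -object@objective))
  cat(sprintf("  nonzero contributions: %d of %d\n",
              sum(object@contributions > 0), length(object@contributions)))
})

## Cholesky of G with escalating diagonal jitter; G from centered dosages is
## singular (zero row sums), so some jitter is almost always required.
psdCholesky <- function(G) {
  n <- nrow(G)
  base <- sum(diag(G)) / n
  if (base <= 0) base <- 1
  jitter <- 0
  repeat {
    R <- tryCatch(chol(G + diag(jitter, n)), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = jitter))
    jitter <- if (jitter == 0) 1e-10 * base else 2 * jitter
    if (jitter > 1e-6 * base) stop("G not repairably PSD")
  }
}

#' Conic reformulation of an OCS problem
#'
#' Rewrites the program as minimize \eqn{-\hat u^\top c} subject to
#' \eqn{Ac + z = b}, \eqn{z \in \{0\}^2 \times R_+^n \times SOC_{n+1}}:
#' two zero-cone rows for the sex sums, n nonnegativity rows, and the
#' coancestry bound as \eqn{\|L^\top c\|_2 \le \sqrt{2\theta}} with
#' \eqn{G = LL^\top} (Cholesky of the jitter-repaired G).
#'
#' @param problem an [OCSProblem-class].
#' @return list with the objective vector `q`, structural constraint pieces
#'   (`s`, `d`, `R` = \eqn{L^\top}, `radius`), the stacked right-hand side
#'   `b`, cone block dimensions, and the applied `jitter`.
#' @export
buildConicForm <- function(problem) {
  stopifnot(is(problem, "OCSProblem"))
  if (problem@theta <= 0) stop("theta must be > 0")
  n <- length(problem@ebv)
  ch <- psdCholesky(problem@grm@values)
  s <- as.numeric(problem@isMale)
  d <- 1 - s
  radius <- sqrt(2 * problem@theta)
  list(q = -unname(problem@ebv), u = unname(problem@ebv), s = s, d = d,
       R = ch$R, radius = radius,
       b = c(0.5, 0.5, rep(0, n), radius, rep(0, n)),
       n = n, dims = c(zero = 2L, nonneg = n, soc = n + 1L),
       jitter = ch$jitter)
}

#' Euclidean projection onto the second-order cone
#'
#' Projects \eqn{(t, x)} onto \eqn{\{(t, x): \|x\|_2 \le t\}}: the identity
#' when \eqn{\|x\| \le t}, the origin when \eqn{\|x\| \le -t}, and otherwise
#' \eqn{\frac{\|x\| + t}{2}(1, x / \|x\|)}.
#'
#' @param t cone scalar.
#' @param x cone vector.
#' @return list with components `t` and `x`.
#' @export
projectSOC <- function(t, x) {
  nx <- sqrt(sum(x^2))
  if (nx <= t) return(list(t = t, x = x))
  if (nx <= -t) return(list(t = 0, x = numeric(length(x))))
  alpha <- (nx + t) / 2
  list(t = alpha, x = x * (alpha / nx))
}

## Structural products with the stacked constraint matrix
## A = [s'; d'; -I; 0; R]  (M = 2n + 3 rows).
conicAx <- function(cf, x)
  c(sum(cf$s * x), sum(cf$d * x), -x, 0, as.numeric(cf$R %*% x))

conicAty <- function(cf, w) {
  n <- cf$n
  cf$s * w[1L] + cf$d * w[2L] - w[3L:(n + 2L)] +
    as.numeric(crossprod(cf$R, w[(n + 4L):(2L * n + 3L)]))
}

projectCone <- function(cf, w) {
  n <- cf$n
  out <- w
  out[1:2] <- 0
  out[3L:(n + 2L)] <- pmax(w[3L:(n + 2L)], 0)
  pr <- projectSOC(w[n + 3L], w[(n + 4L):(2L * n + 3L)])
  out[n + 3L] <- pr$t
  out[(n + 4L):(2L * n + 3L)] <- pr$x
  out
}

## Projection onto the dual cone {R^2} x R+^n x SOC (SOC is self-dual).
projectDualCone <- function(cf, w) {
  n <- cf$n
  out <- w
  out[3L:(n + 2L)] <- pmax(w[3L:(n + 2L)], 0)
  pr <- projectSOC(w[n + 3L], w[(n + 4L):(2L * n + 3L)])
  out[n + 3L] <- pr$t
  out[(n + 4L):(2L * n + 3L)] <- pr$x
  out
}

## Farkas-type primal infeasibility certificate: v in K*, A'v = 0, b'v < 0.
certifiesInfeasible <- function(cf, v, tol = 1e-6) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(FALSE)
  v <- v / nv
  if (sqrt(sum((v - projectDualCone(cf, v))^2)) > tol) return(FALSE)
  if (sqrt(sum(conicAty(cf, v)^2)) > tol) return(FALSE)
  sum(cf$b * v) < -tol
}

directViolation <- function(problem, c) {
  s <- as.numeric(problem@isMale)
  max(abs(sum(c * s) - 0.5), abs(sum(c * (1 - s)) - 0.5),
      -min(c, 0),
      sum(c * as.numeric(problem@grm@values %*% c)) / 2 - problem@theta)
}

#' Solve an OCS problem by conic ADMM
#'
#' Alternates three steps on the consensus form of the conic program: a
#' regularized linear-system solve for the contributions, a projection of
#' the auxiliary variable onto the zero-cone x nonnegative-orthant x
#' second-order-cone product, and a scaled dual update. Terminates when both
#' the primal residual \eqn{\|r^k\|_2 \le \epsilon_{abs} +
#' \epsilon_{rel}\max(\|Ac^k\|, \|z^k\|)} and the dual residual
#' \eqn{\|s^k\|_2 \le \epsilon_{abs} + \epsilon_{rel}\|\gamma A^\top
#' \lambda^k\|} hold and the reported (projected) iterate satisfies the
#' original constraints within `feasTol`; otherwise the tolerances are
#' tightened and iteration continues.
#'
#' The reported contribution vector is the nonnegative-orthant block of the
#' projected variable, so `min(c) >= 0` exactly. Contributions below
#' `rhoZero` are set to zero (no renormalization).
#'
#' @param problem an [OCSProblem-class].
#' @param settings an [ADMMSettings-class].
#' @return A [ContributionSolution-class].
#' @export
solveOCS <- function(problem, settings = ADMMSettings()) {
  stopifnot(is(problem, "OCSProblem"), is(settings, "ADMMSettings"))
  cf <- buildConicForm(problem)
  n <- cf$n
  ids <- names(problem@ebv)

  ## A'A = ss' + dd' + I + G(+jitter); factor once, reused every iteration.
  AtA <- tcrossprod(cf$s) + tcrossprod(cf$d) + diag(n) + crossprod(cf$R)
  U <- chol(AtA)

  nF <- sum(cf$d); nM <- sum(cf$s)
  cvec <- 0.5 * (cf$d / nF + cf$s / nM)   # feasible uniform start
  z <- projectCone(cf, cf$b - conicAx(cf, cvec))
  lam <- numeric(length(z))
  gamma <- settings@gamma0
  epsA <- settings@epsAbs; epsR <- settings@epsRel
  status <- "max_iter"
  rNorm <- sNorm <- NA_real_
  lamCert <- lam
  iter <- 0L

  while (iter < settings@maxIter) {
    iter <- iter + 1L
    rhs <- cf$u / gamma + conicAty(cf, cf$b - z - lam)
    cvec <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
    v <- conicAx(cf, cvec)
    zold <- z
    z <- projectCone(cf, cf$b - v - lam)
    resid <- v + z - cf$b
    lam <- lam + resid
    rNorm <- sqrt(sum(resid^2))
    sNorm <- gamma * sqrt(sum(conicAty(cf, z - zold)^2))

    if (rNorm <= epsA + epsR * max(sqrt(sum(v^2)), sqrt(sum(z^2))) &&
        sNorm <= epsA + epsR * gamma * sqrt(sum(conicAty(cf, lam)^2))) {
      cOut <- z[3L:(n + 2L)]
      if (directViolation(problem, cOut) <= settings@feasTol) {
        status <- "converged"
        break
      }
      ## residual criteria met but reported iterate not yet feasible at
      ## feasTol: tighten and keep iterating
      epsA <- max(epsA * 0.1, 1e-12)
      epsR <- max(epsR * 0.1, 1e-12)
    }

    if (iter %% 50L == 0L) {
      dlam <- lam - lamCert
      lamCert <- lam
      if (certifiesInfeasible(cf, dlam) || certifiesInfeasible(cf, -dlam))
        stop("OCS problem primal infeasible: a Farkas certificate v with ",
             "A'v = 0, v in the dual cone and b'v < 0 was found ",
             "(theta too small for the sex-sum constraints)")
      if (gamma * sqrt(sum(lam^2)) > 1e8)
        stop("dual variable diverged (possible primal infeasibility)")
    }

    if (settings@adaptiveGamma && iter %% 25L == 0L) {
      gnew <- gamma
      if (rNorm > 10 * sNorm) gnew <- min(gamma * 2, 1e6)
      else if (sNorm > 10 * rNorm) gnew <- max(gamma / 2, 1e-6)
      if (gnew != gamma) {
        lam <- lam * (gamma / gnew)
        lamCert <- lamCert * (gamma / gnew)
        gamma <- gnew
      }
    }
  }

  cOut <- z[3L:(n + 2L)]
  cOut <- thresholdContributions(cOut, settings@rhoZero)
  names(cOut) <- ids
  new("ContributionSolution", contributions = cOut,
      objective = sum(cOut * unname(problem@ebv)),
      iterations = iter, status = status,
      rNorm = rNorm, sNorm = sNorm, jitter = cf$jitter, gamma = gamma)
}

#' Zero out negligible contributions
#'
#' Entries strictly below `rhoZero` are set to exactly zero; the rest are
#' unchanged (contributions are not renormalized afterwards, so they may
#' sum to slightly less than 1).
#'
#' @param c contribution vector.
#' @param rhoZero zero threshold (default 1e-4).
#' @return the thresholded vector.
#' @export
thresholdContributions <- function(c, rhoZero = 1e-4) {
  c[c < rhoZero] <- 0
  c
}

#' Extract selected parents and their coancestry block
#'
#' Splits a (thresholded) contribution vector into the selected dams and
#' sires and slices the dam-by-sire block H of G, preserving the original
#' candidate order.
#'
#' @param c named, thresholded contribution vector.
#' @param pop population data.frame aligned with `c` (same ids).
#' @param grm a [RelationshipMatrix-class] over the candidates.
#' @return list with `cd`, `cs` (named nonzero contributions), `H`
#'   (nd x ns matrix), `damIds`, `sireIds`.
#' @export
extractSelected <- function(c, pop, grm) {
  pop <- validatePopulation(pop)
  stopifnot(is(grm, "RelationshipMatrix"))
  if (is.null(names(c))) names(c) <- pop$id
  if (!identical(names(c), pop$id))
    stop("contribution names must match population ids in order")
  damIds <- pop$id[pop$sex == "F" & c > 0]
  sireIds <- pop$id[pop$sex == "M" & c > 0]
  if (length(damIds) == 0L || length(sireIds) == 0L)
    stop("empty parent set: no selected ", if (length(damIds)) "sires" else "dams")
  list(cd = c[damIds], cs = c[sireIds],
       H = grm@values[damIds, sireIds, drop = FALSE],
       damIds = damIds, sireIds = sireIds)
}
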