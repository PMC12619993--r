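# Shared fixture builders: all inputs are generated in code under fixed
# seeds, never stored on disk.

# feasible uniform contribution point for a population
uniformContribution <- function(pop) {
  cvec <- numeric(nrow(pop))
  cvec[pop$sex == "F"] <- 0.5 / sum(pop$sex == "F")
  cvec[pop$sex == "M"] <- 0.5 / sum(pop$sex == "M")
  stats::setNames(cvec, pop$id)
}

coancestryAt <- function(cvec, grm)
  as.numeric(t(cvec) %*% as.matrix(grm) %*% cvec) / 2

# random OCS instance; theta is scaled off the uniform-contribution
# coancestry so the bound is active but feasible
randomOCSInstance <- function(seed, nRange = 4:20, thetaFactor = c(1.2, 5)) {
  set.seed(seed)
  n <- if (length(nRange) == 1L) nRange else sample(nRange, 1L)
  sim <- simulatePopulation(n, 50, seed = seed + 10000L)
  grm <- computeGRM(sim$genotypes)
  base <- coancestryAt(uniformContribution(sim$pop), grm)
  theta <- base * runif(1, thetaFactor[1], thetaFactor[2])
  list(problem = OCSProblem(sim$pop, grm, theta), pop = sim$pop, grm = grm)
}

# independent convex-solver oracle (scipy SLSQP) for the OCS program
oracleOCS <- function(problem) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(
    list(u = I(unname(problem@ebv)), G = as.matrix(problem@grm),
         is_male = I(problem@isMale), theta = problem@theta),
    tf, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  out <- system2("python", c(shQuote(test_path("ocs_oracle.py")), shQuote(tf)),
                 stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# random mate-allocation instance at exhaustive-oracle scale
randomMatingInstance <- function(seed, ndMax = 3L, nsMax = 3L, capMax = 2L,
                                 ksMax = 1L) {
  set.seed(seed)
  nd <- sample.int(ndMax, 1L); ns <- sample.int(nsMax, 1L)
  cap <- sample.int(capMax, 1L)
  MatingProblem(cd = runif(nd, 0.01, 0.5), cs = runif(ns, 0.01, 0.5),
                H = matrix(rnorm(nd * ns, 0, 0.2), nd, ns),
                kappaD = sample.int(3L, 1L), kappaS = sample(0:ksMax, 1L),
                sigmaD = cap, mode = if (cap == 1L) "binary" else "integer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeTempGenotypes <- function(text) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(text, tf)
  tf
}
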