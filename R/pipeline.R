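## One-command wiring of the stages: GRM -> OCS -> mate allocation (binary
## and integer) -> scheme evaluation, with a manifest sufficient to
## reproduce the run.

#' Read a flat key=value run configuration
#'
#' One `key=value` per line; blank lines and lines starting with `#` are
#' ignored. Values are converted to numeric where possible.
#'
#' @param path configuration file.
#' @return named list of settings.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full two-stage pipeline
#'
#' Executes GRM construction (with MAF filtering), optimum contribution
#' selection, mate allocation in both binary and integer mode, and the
#' four-scheme evaluation, writing all stage artifacts plus a run manifest
#' to `out`.
#'
#' @param genotypes path to a genotype file, or a [GenotypeMatrix-class].
#' @param population path to a population table, or a data.frame.
#' @param out output directory (created if missing).
#' @param theta maximum allowed coancestry for OCS.
#' @param dialect genotype file dialect (see [readGenotypes()]).
#' @param grm optional precomputed [RelationshipMatrix-class] or path; when
#'   supplied, genotypes are not required.
#' @param mafThreshold MAF filter applied before the GRM (default 0.05;
#'   `NULL` disables).
#' @param settings an [ADMMSettings-class] for the OCS stage.
#' @param kappaD,kappaS,sigmaD mate-allocation constraints (defaults 3, 0,
#'   `kappaD`).
#' @param replicates random-mating replicates in the evaluation stage.
#' @param seed master seed for the random-mating baselines.
#' @return invisibly, a list with all stage results (`grm`, `ocs`, `sel`,
#'   `binPlan`, `intPlan`, `schemes`, `files`).
#' @export
runPipeline <- function(genotypes = NULL, population, out, theta,
                        dialect = "tsv-matrix", grm = NULL,
                        mafThreshold = 0.05, settings = ADMMSettings(),
                        kappaD = 3L, kappaS = 0L, sigmaD = kappaD,
                        replicates = 100L, seed = 1L) {
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    res
  }

  pop <- if (is.character(population)) readPopulation(population)
         else validatePopulation(population)

  G <- stage("grm", {
    if (!is.null(grm)) {
      if (is.character(grm)) readMatrix(grm) else grm
    } else {
      g <- if (is.character(genotypes)) readGenotypes(genotypes, dialect)
           else genotypes
      if (!is.null(mafThreshold)) g <- mafFilter(g, mafThreshold)
      computeGRM(g)
    }
  })
  writeMatrix(G, file.path(out, "grm.tsv"))

  ocsRes <- stage("ocs", solveOCS(OCSProblem(pop, G, theta), settings))
  contrib <- data.frame(id = pop$id, sex = as.character(pop$sex),
                        ebv = pop$ebv,
                        contribution = unname(ocsRes@contributions))
  utils::write.table(contrib, file.path(out, "contributions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(objective = ocsRes@objective,
                            objective_min_form = -ocsRes@objective,
                            iterations = ocsRes@iterations,
                            status = ocsRes@status,
                            r_norm = ocsRes@rNorm, s_norm = ocsRes@sNorm,
                            jitter = ocsRes@jitter),
                       file.path(out, "ocs_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)

  sel <- stage("extract", extractSelected(ocsRes@contributions, pop, G))

  plans <- stage("mate", {
    lapply(c(binary = "binary", integer = "integer"), function(mode)
      solveMatingBnB(MatingProblem(sel$cd, sel$cs, sel$H, kappaD = kappaD,
                                   kappaS = kappaS, sigmaD = sigmaD,
                                   mode = mode)))
  })
  for (mode in names(plans)) {
    pl <- plans[[mode]]
    nz <- which(pl@M > 0, arr.ind = TRUE)
    utils::write.table(
      data.frame(dam_id = rownames(pl@M)[nz[, 1L]],
                 sire_id = colnames(pl@M)[nz[, 2L]],
                 n_matings = pl@M[nz]),
      file.path(out, paste0("mating_", mode, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(mode = mode, objective = pl@objective,
           n_matings = pl@nMatings,
           n_dams_used = length(unique(nz[, 1L])),
           n_sires_used = length(unique(nz[, 2L])),
           kappa_d = kappaD, kappa_s = kappaS,
           sigma_d = if (mode == "integer") sigmaD else 1L),
      file.path(out, paste0("mating_", mode, ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  schemes <- stage("evaluate",
    compareSchemes(sel, plans$binary, plans$integer, pop, G,
                   kappaD = kappaD, replicates = replicates, seed = seed))
  utils::write.table(schemes, file.path(out, "schemes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "gocsma",
    version = as.character(utils::packageVersion("gocsma")),
    r_version = R.version.string,
    seed = seed, theta = theta, maf_threshold = mafThreshold,
    kappa_d = kappaD, kappa_s = kappaS, sigma_d = sigmaD,
    replicates = replicates,
    admm = list(eps_abs = settings@epsAbs, eps_rel = settings@epsRel,
                gamma0 = settings@gamma0,
                adaptive_gamma = settings@adaptiveGamma,
                max_iter = settings@maxIter, rho_zero = settings@rhoZero,
                feas_tol = settings@feasTol),
    timings = timings,
    total_elapsed = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(grm = G, ocs = ocsRes, sel = sel,
                 binPlan = plans$binary, intPlan = plans$integer,
                 schemes = schemes, out = out))
}
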