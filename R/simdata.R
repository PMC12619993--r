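## Synthetic diploid SNP panels with breeding values additive in the
## genotypes, so every pipeline stage is testable without external data.

#' Simulate a genotyped breeding population
#'
#' Draws a diploid SNP panel and matching population table with the
#' statistical structure the pipeline assumes: per-locus true allele
#' frequencies uniform on `mafRange`, dosages Binomial(2, p_j) independent
#' across individuals and loci (unrelated candidates; no pedigree
#' structure), sexes assigned at a fixed female fraction (at least one of
#' each sex), and breeding values \eqn{\hat u_i = \sum_j w_j z_{ij} +
#' e_i} that are additive in the sample-centered genotypes z with
#' standard-normal locus weights w. The noise variance is
#' `noiseRatio` times the genetic-signal variance, mimicking estimation
#' error in the supplied breeding values; `noiseRatio = 0` gives values
#' exactly linear in the centered genotypes. Fully reproducible from
#' `seed`.
#'
#' @param nIndividuals number of candidates (>= 2).
#' @param nLoci number of SNP loci.
#' @param mafRange range for the true allele frequencies (in (0, 0.5\]).
#' @param noiseRatio var(noise) / var(genetic signal) for the breeding
#'   values (default 0.25, i.e. an estimation accuracy of about 0.9).
#' @param femaleFraction fraction of females (default 0.6; breeding
#'   populations typically carry more dams than sires).
#' @param seed RNG seed.
#' @return list with `genotypes` (a [GenotypeMatrix-class]) and `pop`
#'   (a population data.frame with columns `id`, `sex`, `ebv`).
#' @export
simulatePopulation <- function(nIndividuals, nLoci, mafRange = c(0.1, 0.5),
                               noiseRatio = 0.25, femaleFraction = 0.6,
                               seed = 1L) {
  if (nIndividuals < 2L) stop("need at least two individuals")
  if (nLoci < 1L) stop("need at least one locus")
  if (length(mafRange) != 2L || mafRange[1L] <= 0 || mafRange[2L] > 0.5 ||
      mafRange[1L] > mafRange[2L])
    stop("mafRange must satisfy 0 < low <= high <= 0.5")
  if (noiseRatio < 0) stop("noiseRatio must be >= 0")
  if (femaleFraction <= 0 || femaleFraction >= 1)
    stop("femaleFraction must lie strictly between 0 and 1")

  withSeed(seed, {
    p <- runif(nLoci, mafRange[1L], mafRange[2L])
    d <- matrix(rbinom(nIndividuals * nLoci, 2L, rep(p, each = nIndividuals)),
                nIndividuals, nLoci)
    ids <- sprintf("ind%0*d", nchar(nIndividuals), seq_len(nIndividuals))
    loci <- sprintf("snp%0*d", nchar(nLoci), seq_len(nLoci))
    g <- GenotypeMatrix(d, ids = ids, loci = loci)

    nF <- min(max(round(femaleFraction * nIndividuals), 1L), nIndividuals - 1L)
    sex <- rep("M", nIndividuals)
    sex[sample.int(nIndividuals, nF)] <- "F"

    z <- sweep(d, 2L, colMeans(d), "-")
    w <- rnorm(nLoci)
    signal <- as.numeric(z %*% w)
    noiseSd <- sqrt(noiseRatio * stats::var(signal))
    ebv <- signal + rnorm(nIndividuals, 0, if (is.finite(noiseSd)) noiseSd else 0)

    list(genotypes = g,
         pop = data.frame(id = ids, sex = factor(sex, levels = c("F", "M")),
                          ebv = ebv, stringsAsFactors = FALSE))
  })
}

fixturePresets <- list(tiny = c(n = 6L, m = 10L),
                       small = c(n = 40L, m = 300L),
                       medium = c(n = 200L, m = 2000L))

#' Write a simulated fixture to disk
#'
#' Generates a preset-sized population with [simulatePopulation()] and
#' writes it in the package's file formats: `genotypes.tsv` (tsv-matrix
#' dialect), `genotypes.raw` (PLINK .raw dialect), `population.tsv` and a
#' `manifest.json` recording the preset, sizes and seed.
#'
#' @param name preset: `"tiny"` (6 x 10), `"small"` (40 x 300) or
#'   `"medium"` (200 x 2000).
#' @param dir output directory (created if missing).
#' @param seed RNG seed.
#' @return named character vector of the written file paths, invisibly.
#' @export
makeFixture <- function(name = c("tiny", "small", "medium"), dir, seed = 1L) {
  name <- match.arg(name)
  sz <- fixturePresets[[name]]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulatePopulation(sz[["n"]], sz[["m"]], seed = seed)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             raw = file.path(dir, "genotypes.raw"),
             population = file.path(dir, "population.tsv"),
             manifest = file.path(dir, "manifest.json"))
  writeGenotypes(sim$genotypes, paths[["genotypes"]], "tsv-matrix")
  writeGenotypes(sim$genotypes, paths[["raw"]], "plink-raw")
  writePopulation(sim$pop, paths[["population"]])
  jsonlite::write_json(list(preset = name, n_individuals = sz[["n"]],
                            n_loci = sz[["m"]], seed = seed),
                       paths[["manifest"]], auto_unbox = TRUE)
  invisible(paths)
}
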