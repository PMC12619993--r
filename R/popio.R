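## Genotype / population / matrix IO and the VanRaden method-1 GRM.

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix of 0/1/2 (or NA) dosage codes.
#' @param ids individual identifiers (default: rownames).
#' @param loci locus identifiers (default: colnames).
#' @return A [GenotypeMatrix-class].
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 2, 2, 0), 2, 2,
#'   dimnames = list(c("A", "B"), c("m1", "m2"))))
#' alleleFrequencies(g)
#' @export
GenotypeMatrix <- function(dosages, ids = rownames(dosages), loci = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(loci)) loci <- paste0("snp", seq_len(ncol(dosages)))
  dimnames(dosages) <- list(as.character(ids), as.character(loci))
  new("GenotypeMatrix", dosages = dosages)
}

#' Construct a RelationshipMatrix
#'
#' @param values symmetric numeric matrix of coancestry coefficients.
#' @param ids individual identifiers (default: rownames).
#' @return A [RelationshipMatrix-class].
#' @export
RelationshipMatrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(values)))
  dimnames(values) <- list(as.character(ids), as.character(ids))
  new("RelationshipMatrix", values = values)
}

#' @describeIn GenotypeMatrix-class individual identifiers
#' @param x a `GenotypeMatrix` or `RelationshipMatrix`.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @export
setMethod("individualIds", "RelationshipMatrix", function(x) rownames(x@values))

#' @describeIn GenotypeMatrix-class locus identifiers
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))

#' @export
setMethod("lociIds", "GenotypeMatrix", function(x) {
  cn <- colnames(x@dosages)
  if (is.null(cn)) character(0) else cn
})

#' @describeIn GenotypeMatrix-class dosage matrix
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @export
setMethod("as.matrix", "GenotypeMatrix", function(x, ...) x@dosages)

#' @export
setMethod("as.matrix", "RelationshipMatrix", function(x, ...) x@values)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat("GenotypeMatrix:", nrow(d), "individuals x", ncol(d), "loci\n")
  nm <- sum(is.na(d))
  if (nm) cat("  missing dosages:", nm, "\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  g <- object@values
  cat("RelationshipMatrix:", nrow(g), "x", ncol(g), "\n")
  cat(sprintf("  diagonal mean %.4f, off-diagonal range [%.4f, %.4f]\n",
              mean(diag(g)),
              if (nrow(g) > 1) min(g[upper.tri(g)]) else NA_real_,
              if (nrow(g) > 1) max(g[upper.tri(g)]) else NA_real_))
})

#' Read a genotype file
#'
#' Two dialects are supported. `"tsv-matrix"`: tab-separated with a header
#' line `id<TAB>locus1<TAB>...` and one row per individual. `"plink-raw"`:
#' the whitespace-separated PLINK `--recode A` additive format with six
#' leading pedigree columns (FID IID PAT MAT SEX PHENOTYPE); only IID and
#' the dosage columns are used, and the tracked allele is whatever allele
#' the dosage column counts.
#'
#' @param path file path.
#' @param dialect `"tsv-matrix"` (default) or `"plink-raw"`.
#' @param missing codes treated as missing (besides empty fields);
#'   default `"NA"`.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, dialect = c("tsv-matrix", "plink-raw"),
                          missing = "NA") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no individuals in genotype file: ", path)
  sep <- if (dialect == "tsv-matrix") "\t" else "[ \t]+"
  header <- strsplit(lines[1L], sep)[[1]]
  if (dialect == "tsv-matrix") {
    loci <- header[-1L]
    idcol <- 1L; first <- 2L
  } else {
    if (length(header) < 7L) stop("plink-raw file must have 6 pedigree columns plus dosages")
    loci <- header[-(1:6)]
    idcol <- 2L; first <- 7L
  }
  nfield <- length(header)
  body <- lines[-1L]
  ids <- character(length(body))
  out <- matrix(NA_real_, length(body), length(loci))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], sep)[[1]]
    if (length(f) != nfield)
      stop("malformed genotype row at line ", i + 1L, ": expected ", nfield,
           " fields, found ", length(f))
    ids[i] <- f[idcol]
    vals <- f[first:nfield]
    miss <- vals %in% missing | !nzchar(vals)
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!miss & (is.na(num) | !(num %in% c(0, 1, 2))))
    if (length(bad))
      stop("invalid dosage code '", vals[bad[1L]], "' at line ", i + 1L,
           ", locus ", loci[bad[1L]])
    num[miss] <- NA_real_
    out[i, ] <- num
  }
  GenotypeMatrix(out, ids = ids, loci = loci)
}

#' Write a genotype file
#'
#' Inverse of [readGenotypes()] for both dialects; `plink-raw` pedigree
#' columns are filled with the individual id (FID = IID) and zeros.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output file path.
#' @param dialect `"tsv-matrix"` or `"plink-raw"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(g, path, dialect = c("tsv-matrix", "plink-raw")) {
  dialect <- match.arg(dialect)
  stopifnot(is(g, "GenotypeMatrix"))
  d <- g@dosages
  fmt <- function(v) ifelse(is.na(v), "NA", format(v, trim = TRUE, scientific = FALSE))
  if (dialect == "tsv-matrix") {
    lines <- c(paste(c("id", colnames(d)), collapse = "\t"),
               vapply(seq_len(nrow(d)), function(i)
                 paste(c(rownames(d)[i], fmt(d[i, ])), collapse = "\t"), ""))
  } else {
    lines <- c(paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                       colnames(d)), collapse = " "),
               vapply(seq_len(nrow(d)), function(i)
                 paste(c(rownames(d)[i], rownames(d)[i], "0", "0", "0", "-9",
                         fmt(d[i, ])), collapse = " "), ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a population table
#'
#' The population table is a TSV with header `id  sex  ebv`; sex is coded
#' `F`/`M` and `ebv` is the estimated breeding value in trait units.
#'
#' @param path file path.
#' @return `readPopulation`: a data.frame with columns `id` (character),
#'   `sex` (factor F/M) and `ebv` (numeric).
#' @export
readPopulation <- function(path) {
  if (!file.exists(path)) stop("population file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  names(df) <- tolower(names(df))
  validatePopulation(df)
}

#' @rdname readPopulation
#' @param pop a population data.frame.
#' @export
writePopulation <- function(pop, path) {
  pop <- validatePopulation(pop)
  utils::write.table(data.frame(id = pop$id, sex = as.character(pop$sex),
                                ebv = pop$ebv),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readPopulation
#' @export
validatePopulation <- function(pop) {
  req <- c("id", "sex", "ebv")
  if (!all(req %in% names(pop)))
    stop("population table must have columns id, sex, ebv")
  if (anyDuplicated(pop$id)) stop("duplicated individual ids in population table")
  sex <- as.character(pop$sex)
  if (!all(sex %in% c("F", "M"))) stop("sex must be coded F or M")
  if (anyNA(pop$ebv)) stop("missing breeding values")
  data.frame(id = as.character(pop$id), sex = factor(sex, levels = c("F", "M")),
             ebv = as.numeric(pop$ebv), stringsAsFactors = FALSE)
}

#' Per-locus allele frequencies
#'
#' Frequency of the tracked (counted) allele at each locus:
#' \eqn{p_j = \sum_i n_{ij} / (2 n_j)} over non-missing dosages.
#'
#' @param g a [GenotypeMatrix-class].
#' @return named numeric vector of frequencies in \[0, 1\].
#' @export
alleleFrequencies <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- g@dosages
  nobs <- colSums(!is.na(d))
  if (any(nobs == 0L))
    stop("locus with all genotypes missing: ", colnames(d)[which(nobs == 0L)[1L]])
  colSums(d, na.rm = TRUE) / (2 * nobs)
}

#' Filter loci by minor allele frequency
#'
#' Keeps exactly the loci whose minor allele frequency
#' `min(p, 1 - p)` is strictly greater than `threshold`; individual order is
#' unchanged. May return zero loci.
#'
#' @param g a [GenotypeMatrix-class].
#' @param threshold MAF threshold in \[0, 0.5\] (default 0.05).
#' @return A [GenotypeMatrix-class] with the retained loci.
#' @export
mafFilter <- function(g, threshold = 0.05) {
  stopifnot(is(g, "GenotypeMatrix"), threshold >= 0, threshold <= 0.5)
  p <- alleleFrequencies(g)
  keep <- pmin(p, 1 - p) > threshold
  GenotypeMatrix(g@dosages[, keep, drop = FALSE],
                 ids = rownames(g@dosages), loci = colnames(g@dosages)[keep])
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Computes \eqn{G = Z Z^\top / (2 \sum_j p_j (1 - p_j))} with
#' \eqn{Z = N - P}, where N is the dosage matrix and the j-th column of P is
#' \eqn{2 p_j}. With sample-estimated frequencies the columns of Z are
#' centered, so every row of G sums to zero and negative off-diagonals
#' appear by construction.
#'
#' @param g a [GenotypeMatrix-class] without missing entries (or with
#'   `impute = TRUE`).
#' @param p optional externally supplied allele frequencies (same length and
#'   order as the loci). When given, the zero-row-sum property no longer
#'   holds.
#' @param impute if `TRUE`, missing dosages are replaced by the per-locus
#'   mean dosage before centering; by default missing entries are an error.
#' @return A [RelationshipMatrix-class].
#' @export
computeGRM <- function(g, p = NULL, impute = FALSE) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- g@dosages
  if (anyNA(d)) {
    if (!impute) stop("missing genotypes; set impute = TRUE for per-locus mean imputation")
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2L]]
  }
  if (is.null(p)) {
    p <- colSums(d) / (2 * nrow(d))
  } else {
    if (length(p) != ncol(d)) stop("length of p must equal the number of loci")
    if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all loci monomorphic: zero VanRaden denominator")
  z <- sweep(d, 2L, 2 * p, "-")
  gm <- tcrossprod(z) / denom
  gm <- (gm + t(gm)) / 2   # exact symmetry against fp round-off
  RelationshipMatrix(gm, ids = rownames(d))
}

#' Read / write a relationship matrix
#'
#' TSV with individual ids both as header row and as first column; the full
#' square matrix is stored. `readMatrix(writeMatrix(G))` reproduces G within
#' 1e-12.
#'
#' @param path file path.
#' @param rm a [RelationshipMatrix-class].
#' @return `readMatrix`: a [RelationshipMatrix-class].
#' @export
writeMatrix <- function(rm, path) {
  stopifnot(is(rm, "RelationshipMatrix"))
  g <- rm@values
  lines <- c(paste(c("id", colnames(g)), collapse = "\t"),
             vapply(seq_len(nrow(g)), function(i)
               paste(c(rownames(g)[i],
                       format(g[i, ], digits = 17, trim = TRUE, scientific = TRUE)),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeMatrix
#' @export
readMatrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[1L], "\t")[[1]][-1L]
  body <- lines[-1L]
  if (length(body) != length(header))
    stop("matrix file not square: ", length(header), " columns vs ",
         length(body), " rows")
  ids <- character(length(body))
  vals <- matrix(NA_real_, length(body), length(header))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    if (length(f) != length(header) + 1L)
      stop("malformed matrix row at line ", i + 1L)
    ids[i] <- f[1L]
    vals[i, ] <- as.numeric(f[-1L])
  }
  if (!identical(ids, header))
    stop("matrix header ids do not match first-column ids")
  RelationshipMatrix(vals, ids = ids)
}
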