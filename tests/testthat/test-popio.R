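test_that("tsv-matrix parsing transcribes ids and dosages and flags bad input", {
  path <- writeTempGenotypes("id\tm1\tm2\nA\t0\t2\nB\t2\t0")
  g <- readGenotypes(path)
  expect_identical(individualIds(g), c("A", "B"))
  expect_identical(lociIds(g), c("m1", "m2"))
  expect_equal(unname(dosages(g)), matrix(c(0, 2, 2, 0), 2, 2))

  expect_error(readGenotypes(writeTempGenotypes("id\tm1\tm2")),
               "no individuals")
  expect_error(readGenotypes(writeTempGenotypes("id\tm1\tm2\nA\t0")),
               "line 2")
  expect_error(readGenotypes(writeTempGenotypes("id\tm1\tm2\nA\t0\t3")),
               "m2")
  path <- writeTempGenotypes("id\tm1\tm2\nA\t0\tNA\nB\t1\t2")
  expect_true(is.na(dosages(readGenotypes(path))["A", "m2"]))
})

test_that("plink-raw fixtures round-trip through write and read", {
  sim <- simulatePopulation(3, 4, seed = 11)
  tf <- tempfile(fileext = ".raw")
  writeGenotypes(sim$genotypes, tf, "plink-raw")
  back <- readGenotypes(tf, "plink-raw")
  expect_identical(dosages(back), dosages(sim$genotypes))

  tf2 <- tempfile(fileext = ".tsv")
  writeGenotypes(sim$genotypes, tf2, "tsv-matrix")
  expect_identical(dosages(readGenotypes(tf2)), dosages(sim$genotypes))
})

test_that("allele frequencies equal a brute-force per-column tally", {
  g <- GenotypeMatrix(matrix(c(0, 2), 2, 1,
                             dimnames = list(c("a", "b"), "m1")))
  expect_equal(unname(alleleFrequencies(g)), 0.5)
  g2 <- GenotypeMatrix(matrix(c(2, 2, 2), 3, 1,
                              dimnames = list(letters[1:3], "m1")))
  expect_equal(unname(alleleFrequencies(g2)), 1.0)

  sim <- simulatePopulation(20, 50, seed = 3)
  p <- alleleFrequencies(sim$genotypes)
  d <- dosages(sim$genotypes)
  brute <- vapply(seq_len(ncol(d)), function(j) {
    v <- d[, j][!is.na(d[, j])]
    sum(v) / (2 * length(v))
  }, 0)
  expect_equal(unname(p), brute, tolerance = 1e-15)
  expect_true(all(p >= 0 & p <= 1))

  # invariant to row permutation
  perm <- sample(20)
  gp <- GenotypeMatrix(d[perm, ])
  expect_equal(unname(alleleFrequencies(gp)), unname(p))

  gna <- GenotypeMatrix(matrix(NA_real_, 2, 1,
                               dimnames = list(c("a", "b"), "mAll")))
  expect_error(alleleFrequencies(gna), "mAll")
})

test_that("MAF filter keeps exactly the loci strictly above the threshold", {
  d <- cbind(mono = c(2, 2, 2, 2), rare = c(1, 0, 0, 0), common = c(1, 1, 2, 0))
  rownames(d) <- paste0("i", 1:4)
  g <- GenotypeMatrix(d)
  # p = 1, 0.125, 0.5 -> MAF = 0, 0.125, 0.5
  expect_identical(lociIds(mafFilter(g, 0.05)), c("rare", "common"))
  expect_identical(lociIds(mafFilter(g, 0)), c("rare", "common"))
  expect_identical(lociIds(mafFilter(g, 0.5)), character(0))
  # strictness: MAF exactly at the threshold is dropped
  expect_identical(lociIds(mafFilter(g, 0.125)), "common")

  sim <- simulatePopulation(25, 80, seed = 9, mafRange = c(0.02, 0.5))
  p <- alleleFrequencies(sim$genotypes)
  keep <- which(pmin(p, 1 - p) > 0.1)
  expect_identical(lociIds(mafFilter(sim$genotypes, 0.1)),
                   lociIds(sim$genotypes)[keep])
  expect_identical(individualIds(mafFilter(sim$genotypes, 0.1)),
                   individualIds(sim$genotypes))
})

test_that("VanRaden GRM matches the closed form and a double-loop oracle", {
  g <- GenotypeMatrix(matrix(c(0, 2, 2, 0), 2, 2,
                             dimnames = list(c("A", "B"), c("m1", "m2"))))
  G <- computeGRM(g)
  expect_equal(unname(as.matrix(G)), matrix(c(2, -2, -2, 2), 2, 2))

  sim <- simulatePopulation(30, 200, seed = 5)
  G2 <- as.matrix(computeGRM(sim$genotypes))
  d <- dosages(sim$genotypes)
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  naive <- matrix(0, 30, 30)
  for (i in 1:30) for (k in 1:30)
    naive[i, k] <- sum((d[i, ] - 2 * p) * (d[k, ] - 2 * p)) / denom
  expect_equal(unname(G2), naive, tolerance = 1e-10)

  # structural invariants with sample-estimated frequencies
  expect_lt(max(abs(rowSums(G2))), 1e-8 * nrow(G2))
  expect_equal(G2, t(G2))
  ev <- eigen(G2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  expect_true(all(diag(G2) >= 0))

  # commutes with simultaneous row permutation
  perm <- sample(30)
  Gp <- as.matrix(computeGRM(GenotypeMatrix(d[perm, ])))
  expect_equal(unname(Gp), unname(G2[perm, perm]), tolerance = 1e-12)
})

test_that("GRM handles external frequencies, missingness and degenerate loci", {
  d <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("m1", "m2")))
  g <- GenotypeMatrix(d)
  # external frequencies waive the zero-row-sum property
  Gx <- as.matrix(computeGRM(g, p = c(0.25, 0.25)))
  expect_gt(max(abs(rowSums(Gx))), 1e-6)

  dna <- d; dna[1, 1] <- NA
  expect_error(computeGRM(GenotypeMatrix(dna)), "missing")
  Gi <- computeGRM(GenotypeMatrix(dna), impute = TRUE)
  expect_true(all(is.finite(as.matrix(Gi))))

  mono <- GenotypeMatrix(matrix(2, 3, 2, dimnames = list(letters[1:3], c("x", "y"))))
  expect_error(computeGRM(mono), "monomorphic")
})

test_that("relationship-matrix TSV files round-trip", {
  G1 <- RelationshipMatrix(matrix(1.0, 1, 1, dimnames = list("A", "A")))
  tf <- tempfile()
  writeMatrix(G1, tf)
  expect_equal(as.matrix(readMatrix(tf)), as.matrix(G1))

  sim <- simulatePopulation(8, 40, seed = 2)
  G <- computeGRM(sim$genotypes)
  writeMatrix(G, tf)
  expect_equal(as.matrix(readMatrix(tf)), as.matrix(G), tolerance = 1e-12)

  writeLines("id\tA\tB\nA\t1\t0\nC\t0\t1", tf)
  expect_error(readMatrix(tf), "do not match")
})

test_that("population tables validate and round-trip", {
  pop <- data.frame(id = c("a", "b"), sex = c("F", "M"), ebv = c(1.5, -2))
  tf <- tempfile()
  writePopulation(pop, tf)
  back <- readPopulation(tf)
  expect_identical(back$id, pop$id)
  expect_identical(as.character(back$sex), pop$sex)
  expect_equal(back$ebv, pop$ebv)

  expect_error(validatePopulation(data.frame(id = "a", sex = "X", ebv = 1)),
               "F or M")
  expect_error(validatePopulation(data.frame(id = c("a", "a"),
                                             sex = c("F", "M"), ebv = 1:2)),
               "duplicated")
})
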