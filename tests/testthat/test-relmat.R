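test_that("tabular A reproduces classical hand-derived relationships", {
  # two unrelated founders
  ped2 <- Pedigree(data.frame(animal = c("A", "B"), sire = "0", dam = "0",
                              birth_date = as.Date("2000-01-01"),
                              sex = c("M", "F"), breed = "t"))
  expect_equal(relValues(numeratorRelationship(ped2)),
               diag(2), ignore_attr = TRUE)

  # full sibs share 0.5; their offspring is inbred with F = 0.25
  A <- relValues(numeratorRelationship(toySibPedigree()))
  expect_equal(A["C", "D"], 0.5)
  expect_equal(A["E", "E"], 1.25)
  expect_equal(inbreedingCoefficients(toySibPedigree())[["E"]], 0.25)
})

test_that("Henderson A-inverse agrees with the tabular method", {
  # founders only: identity
  pedf <- Pedigree(data.frame(animal = letters[1:4], sire = "0", dam = "0",
                              birth_date = as.Date("2000-01-01"),
                              sex = "U", breed = "t"))
  expect_equal(relValues(aInverse(pedf)), diag(4), ignore_attr = TRUE)

  # trio: Henderson's closed-form entries with d = 1/2 give 2 on C's diagonal
  trio <- Pedigree(data.frame(animal = c("A", "B", "C"),
                              sire = c("0", "0", "A"), dam = c("0", "0", "B"),
                              birth_date = as.Date("2000-01-01") + 0:2,
                              sex = c("M", "F", "F"), breed = "t"))
  Ai <- relValues(aInverse(trio))
  expect_equal(Ai["C", "C"], 2)
  expect_equal(Ai["A", "C"], -1)
  expect_equal(Ai["A", "B"], 0.5)

  # property: A^-1 A = I on random pedigrees, inbreeding included
  for (seed in 1:4) {
    ped <- randomPedigree(80, seed)
    A <- relValues(numeratorRelationship(ped))
    Ai <- relValues(aInverse(ped))
    expect_lt(max(abs(Ai %*% A - diag(nrow(A)))), 1e-8)
  }
})

test_that("matrices are invariant to input record order", {
  rec <- pedRecords(randomPedigree(60, 2))
  perm <- sample(nrow(rec))
  A1 <- relValues(numeratorRelationship(Pedigree(rec)))
  A2 <- relValues(numeratorRelationship(Pedigree(rec[perm, ])))
  ids <- rownames(A1)
  expect_equal(A2[ids, ids], A1, tolerance = 1e-12)
})

test_that("VanRaden G matches hand evaluation and duplicates behave", {
  # 2 animals, 1 SNP, calls {0, 2}: p = 0.5, G = [[2,-2],[-2,2]]
  cl <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("x", "y"), NULL))
  G1 <- GenotypeMatrix(cl, data.frame(snp_id = "s", chrom = 1, bp = 1,
                                      alleleA = "A", alleleB = "B"))
  expect_equal(relValues(genomicRelationship(G1)),
               matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)

  # monomorphic marker is an error
  clm <- matrix(c(2L, 2L), 2, 1, dimnames = list(c("x", "y"), NULL))
  Gm <- GenotypeMatrix(clm, data.frame(snp_id = "s", chrom = 1, bp = 1,
                                       alleleA = "A", alleleB = "B"))
  expect_error(genomicRelationship(Gm), "monomorphic")

  # a duplicated animal gives identical rows and off-diagonal = diagonal
  G <- randomGenotypeMatrix(n = 12, m = 80, seed = 4, miss = 0)
  v <- calls(G); v[2, ] <- v[1, ]
  Gd <- GenotypeMatrix(v, markerMap(G))
  Gr <- genomicRelationship(Gd)
  gv <- relValues(Gr)
  expect_equal(gv[1, ], gv[2, ], ignore_attr = TRUE)
  expect_equal(gv[1, 2], gv[1, 1])

  # that singular G becomes positive definite after blending with A22
  pedu <- Pedigree(data.frame(animal = rownames(v), sire = "0", dam = "0",
                              birth_date = as.Date("2000-01-01"),
                              sex = "U", breed = "t"))
  A22 <- a22Matrix(numeratorRelationship(pedu), rownames(v))
  Gb <- blendG(Gr, A22, 0.95)
  expect_gt(min(eigen(relValues(Gb), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  # blend arithmetic is entrywise exact, and w = 1 is the identity
  expect_equal(relValues(Gb), 0.95 * gv + 0.05 * relValues(A22),
               tolerance = 1e-12)
  expect_identical(relValues(blendG(Gr, A22, 1)), gv)
  expect_error(blendG(Gr, A22, 0), "weight")
})

test_that("G recovers known relatedness in simulated half-sib families", {
  cfg <- simConfig(n_breeds = 1L, breed_sizes = 400L, breed_names = "B",
                   markers_per_chrom = 60L, n_chromosomes = 10L,
                   missing_rate = 0, n_founders_per_breed = 120L,
                   n_generations = 1L, founder_freq_divergence = 0,
                   seed = 12)
  ped <- simulatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  rec <- pedRecords(ped)
  cohort <- phenotypedCohort(ped)
  sub <- new("GenotypeMatrix", calls = calls(g)[cohort, ], map = markerMap(g))
  Gv <- relValues(genomicRelationship(sub))
  sire <- rec$sire[match(cohort, rec$animal)]
  dam <- rec$dam[match(cohort, rec$animal)]
  same_sire <- outer(sire, sire, "==") & !outer(dam, dam, "==")
  unrel <- !outer(sire, sire, "==") & !outer(dam, dam, "==")
  off <- row(Gv) != col(Gv)
  expect_lt(abs(mean(Gv[same_sire & off]) - 0.25), 0.05)
  expect_lt(abs(mean(Gv[unrel & off])), 0.05)
  # mean diagonal of a breed-homogeneous G is near 1
  expect_gt(mean(diag(Gv)), 0.9)
  expect_lt(mean(diag(Gv)), 1.3)
})

hFixture <- function(seed = 33, n = 30, n_geno = 12) {
  ped <- randomPedigree(n, seed)
  A <- numeratorRelationship(ped)
  ids <- animalIds(ped)
  geno_ids <- ids[ids %in% sample(ids, n_geno)]
  set.seed(seed + 1)
  cl <- matrix(rbinom(length(geno_ids) * 120, 2, 0.5), length(geno_ids), 120)
  cl[1, ] <- 1L
  rownames(cl) <- geno_ids
  map <- data.frame(snp_id = paste0("s", 1:120), chrom = rep(1:4, each = 30),
                    bp = rep(1:30 * 100L, 4), alleleA = "A", alleleB = "B")
  Graw <- genomicRelationship(GenotypeMatrix(cl, map))
  A22 <- a22Matrix(A, geno_ids)
  list(ped = ped, A = A, A22 = A22, G = blendG(Graw, A22, 0.95))
}

test_that("H reduces to A when G = A22, in all three representations", {
  fx <- hFixture()
  Gequal <- new("RelationshipMatrix", kind = "G", ids = animalIds(fx$A22),
                values = relValues(fx$A22), meta = list())
  hl <- hMatrix(fx$A, Gequal)
  expect_lt(max(abs(relValues(hl$H) - relValues(fx$A))), 1e-8)
  L <- relValues(hl$L)
  expect_lt(max(abs(L %*% t(L) - relValues(fx$A))), 1e-8)
  Ai <- aInverse(fx$ped)
  Hi <- hInverse(Ai, Gequal, fx$A22)
  expect_lt(max(abs(relValues(Hi) - relValues(Ai))), 1e-8)
  # zero genotyped animals: the correction block is empty
  Hi0 <- hInverse(Ai)
  expect_identical(relValues(Hi0), relValues(Ai))
})

test_that("assembled H, its Cholesky factor and H-inverse are consistent", {
  fx <- hFixture()
  hl <- hMatrix(fx$A, fx$G)
  Hv <- relValues(hl$H)
  # genotyped block is exactly G
  gids <- animalIds(fx$G)
  expect_equal(Hv[gids, gids], relValues(fx$G), ignore_attr = TRUE)
  # L L' = H
  L <- relValues(hl$L)
  expect_lt(max(abs(L %*% t(L) - Hv)), 1e-8)
  # block-form inverse equals brute-force inversion
  Hi <- hInverse(aInverse(fx$ped), fx$G, fx$A22)
  expect_lt(max(abs(relValues(Hi) - solve(Hv))), 1e-6)
  expect_error(hInverse(aInverse(fx$ped), fx$G,
                        a22Matrix(fx$A, animalIds(fx$G)[-1])),
               "same genotyped animals")
})

test_that("GRM principal components separate known structure", {
  # two identical unrelated groups: PC1 splits them with opposite signs
  blockG <- new("RelationshipMatrix", kind = "G",
                ids = paste0("a", 1:10),
                values = {
                  m <- matrix(0, 10, 10)
                  m[1:5, 1:5] <- 0.5; m[6:10, 6:10] <- 0.5
                  diag(m) <- 1
                  m
                }, meta = list())
  pc <- grmPCA(blockG, 3)
  s1 <- sign(pc$scores[1:5, 1]); s2 <- sign(pc$scores[6:10, 1])
  expect_true(all(s1 == s1[1]) && all(s2 == s2[1]) && s1[1] != s2[1])
  expect_true(all(diff(pc$varfrac) <= 1e-12))
  expect_lte(sum(pc$varfrac), 1 + 1e-12)

  # simulated breeds with diverged founder frequencies cluster on (PC1, PC2)
  cfg <- simConfig(n_breeds = 3L, breed_sizes = c(60L, 60L, 60L),
                   breed_names = c("P", "Q", "R"), markers_per_chrom = 80L,
                   n_chromosomes = 8L, missing_rate = 0,
                   founder_freq_divergence = 0.05, sire_sharing_rate = 0,
                   seed = 19)
  ped <- simulatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  cohort <- phenotypedCohort(ped)
  keep <- colMeans(calls(g)[cohort, ]) / 2
  ok <- keep > 0 & keep < 1
  sub <- new("GenotypeMatrix", calls = calls(g)[cohort, ok],
             map = markerMap(g)[ok, ])
  pc2 <- grmPCA(genomicRelationship(sub), 2)
  labels <- pedRecords(ped)$breed[match(cohort, pedRecords(ped)$animal)]
  expect_gt(meanSilhouette(pc2$scores, labels), 0.2)
})

test_that("composite LD r2 behaves at its boundaries and under independence", {
  G <- randomGenotypeMatrix(n = 40, m = 10, seed = 6, miss = 0)
  s <- markerMap(G)$snp_id
  expect_equal(ldR2(G, s[1], s[1]), 1.0)
  # duplicated column
  v <- calls(G); v[, 2] <- v[, 1]
  Gd <- GenotypeMatrix(v, markerMap(G))
  expect_equal(ldR2(Gd, s[1], s[2]), 1.0)
  # independent markers at n = 10,000
  set.seed(10)
  big <- cbind(rbinom(10000, 2, 0.4), rbinom(10000, 2, 0.6))
  rownames(big) <- paste0("i", 1:10000)
  Gi <- GenotypeMatrix(big, data.frame(snp_id = c("u", "w"), chrom = 1,
                                       bp = c(1, 2), alleleA = "A",
                                       alleleB = "B"))
  expect_lt(ldR2(Gi, "u", "w"), 0.01)
  # monomorphic marker: NA with a warning
  vm <- calls(G); vm[, 3] <- 2L
  Gm <- GenotypeMatrix(vm, markerMap(G))
  expect_warning(r <- ldR2(Gm, s[3], s[4]), "monomorphic")
  expect_true(is.na(r))
})
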