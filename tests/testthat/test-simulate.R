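smallCfg <- function(seed, ...) {
  args <- list(n_breeds = 2L, breed_sizes = c(50L, 50L),
               breed_names = c("B1", "B2"), markers_per_chrom = 20L,
               n_chromosomes = 4L, missing_rate = 0.01, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}

test_that("configuration validation rejects impossible settings", {
  expect_error(simConfig(seed = NULL), "seed")
  expect_error(smallCfg(1, h2_polygenic = 0.9,
                        qtl_spec = data.frame(chrom = 1, bp = NA,
                                              variance_fraction = 0.3)),
               "fractions")
  expect_error(smallCfg(1, sire_sharing_rate = 2), "sire_sharing_rate")
  expect_error(simulateGenotypes(simulatePedigree(smallCfg(1)),
                                 smallCfg(1, qtl_spec = data.frame(
                                   chrom = 40, bp = NA,
                                   variance_fraction = 0.1))),
               "outside the simulated map")
})

test_that("all generator output is a pure function of the seed", {
  cfg <- smallCfg(123)
  p1 <- simulatePedigree(cfg); p2 <- simulatePedigree(cfg)
  expect_identical(pedRecords(p1), pedRecords(p2))
  g1 <- simulateGenotypes(p1, cfg); g2 <- simulateGenotypes(p2, cfg)
  expect_identical(calls(g1), calls(g2))
  ph1 <- simulatePhenotypes(p1, g1, cfg); ph2 <- simulatePhenotypes(p2, g2, cfg)
  expect_identical(ph1$height, ph2$height)
})

test_that("sire sharing rate zero keeps stallion pools breed-exclusive", {
  cfg <- smallCfg(7, sire_sharing_rate = 0)
  rec <- pedRecords(simulatePedigree(cfg))
  sires <- unique(rec$sire[rec$sire != "0"])
  for (s in sires) {
    breeds_served <- unique(rec$breed[rec$sire == s])
    expect_length(breeds_served, 1L)
  }
})

test_that("preset-scale family sizes are long-tailed with mean near 3.5", {
  maxes <- means <- numeric(5)
  for (k in 1:5) {
    cfg <- simConfig(seed = 100 + k, markers_per_chrom = 10L)
    ped <- simulatePedigree(cfg)
    rec <- pedRecords(ped)
    cohort <- phenotypedCohort(ped)
    fam <- table(rec$sire[rec$animal %in% cohort])
    maxes[k] <- max(fam); means[k] <- mean(fam)
    # pedigree about seven times the genotyped cohort
    expect_gt(nAnimals(ped) / length(cohort), 5)
    expect_lt(nAnimals(ped) / length(cohort), 9)
  }
  expect_true(all(maxes >= 20))
  expect_true(all(means >= 2 & means <= 6))
})

test_that("gene-dropped offspring calls are Mendelian-consistent", {
  cfg <- smallCfg(31, missing_rate = 0)
  ped <- simulatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  v <- calls(g); rec <- pedRecords(ped)
  both <- which(rec$sire != "0" & rec$dam != "0")
  for (i in both) {
    off <- v[rec$animal[i], ]
    s <- v[rec$sire[i], ]; d <- v[rec$dam[i], ]
    lo <- (s == 2L) + (d == 2L)
    hi <- 2L - (s == 0L) - (d == 0L)
    expect_true(all(off >= lo & off <= hi))
  }
})

test_that("founder allele-frequency divergence scales with the Fst knob", {
  between_var <- function(fst, seed) {
    cfg <- smallCfg(seed, founder_freq_divergence = fst, missing_rate = 0,
                    n_founders_per_breed = c(120L, 120L))
    ped <- simulatePedigree(cfg)
    g <- simulateGenotypes(ped, cfg)
    rec <- pedRecords(ped)
    founders <- rec$animal[rec$sire == "0" & rec$dam == "0"]
    f1 <- alleleFreqs(g, intersect(founders, rec$animal[rec$breed == "B1"]))
    f2 <- alleleFreqs(g, intersect(founders, rec$animal[rec$breed == "B2"]))
    list(diff = f1 - f2, var = mean((f1 - f2)^2) / 2)
  }
  # no divergence: per-breed founder frequency differences centred at zero
  d0 <- between_var(0, 41)
  expect_lt(abs(mean(d0$diff)), 0.02)
  # divergence increases monotonically along a parameter grid
  grid <- c(0.01, 0.05, 0.15)
  vs <- vapply(seq_along(grid), function(k) {
    mean(vapply(1:3, function(s) between_var(grid[k], 500 + 10 * k + s)$var,
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
})

test_that("phenotypes decompose into the configured mean, age and genetic terms", {
  # no random terms: height is exactly mean + age-class effect
  cfg0 <- smallCfg(9, sd_env = 0, h2_polygenic = 0,
                   qtl_spec = data.frame(chrom = integer(0), bp = integer(0),
                                         variance_fraction = numeric(0)))
  ped <- simulatePedigree(cfg0)
  g <- simulateGenotypes(ped, cfg0)
  ph <- simulatePhenotypes(ped, g, cfg0)
  expect_equal(ph$height,
               cfg0$mean_height + cfg0$age_class_effects[ph$age_class])
  expect_setequal(unique(ph$age_class), 1:5)

  # default-composition runs land near the configured mean and implied SD
  implied_sd <- sqrt(2.475^2 / 0.5)
  mns <- sds <- numeric(4)
  for (k in 1:4) {
    cfg <- simConfig(scale = 0.15, markers_per_chrom = 20L, seed = 70 + k)
    ped <- simulatePedigree(cfg)
    g <- simulateGenotypes(ped, cfg)
    ph <- simulatePhenotypes(ped, g, cfg)
    mns[k] <- mean(ph$height); sds[k] <- sd(ph$height)
  }
  expect_lt(abs(mean(mns) - 167.6), 0.5)
  expect_lt(abs(mean(sds) - implied_sd), 0.25 * implied_sd)
})

test_that("a planted QTL explains its configured share of variance", {
  r2s <- numeric(6)
  for (k in 1:6) {
    cfg <- simConfig(n_breeds = 2L, breed_sizes = c(200L, 200L),
                     breed_names = c("B1", "B2"), markers_per_chrom = 15L,
                     n_chromosomes = 4L, missing_rate = 0,
                     qtl_spec = data.frame(chrom = 2L, bp = NA,
                                           variance_fraction = 0.2),
                     h2_polygenic = 0.2, seed = 900 + k)
    ped <- simulatePedigree(cfg)
    g <- simulateGenotypes(ped, cfg)
    ph <- simulatePhenotypes(ped, g, cfg)
    x <- calls(g)[ph$animal_id, attr(g, "qtl_snp_ids")]
    r2s[k] <- summary(lm(ph$height ~ x))$r.squared
  }
  expect_lt(abs(mean(r2s) - 0.2), 0.05)
})

test_that("realized genetic variance matches the configured heritability", {
  cfg <- simConfig(n_breeds = 1L, breed_sizes = 600L, breed_names = "B",
                   markers_per_chrom = 15L, n_chromosomes = 4L,
                   missing_rate = 0, h2_polygenic = 0.27,
                   qtl_spec = data.frame(chrom = 2L, bp = NA,
                                         variance_fraction = 0.23),
                   seed = 77)
  ped <- simulatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  ph <- simulatePhenotypes(ped, g, cfg)
  truth <- attr(ph, "truth")
  gval <- truth$u[ph$animal_id] + truth$qtl[ph$animal_id]
  h2_real <- var(gval) / var(ph$height)
  expect_lt(abs(h2_real - truth$h2_total), 0.08)
})
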