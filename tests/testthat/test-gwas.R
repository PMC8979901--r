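simCohortGenotypes <- function(seed, n = 300, mpc = 20, chroms = 6,
                               qtl_frac = 0, h2 = 0.3) {
  qs <- if (qtl_frac > 0)
    data.frame(chrom = 3L, bp = NA, variance_fraction = qtl_frac)
  else data.frame(chrom = integer(0), bp = integer(0),
                  variance_fraction = numeric(0))
  cfg <- simConfig(n_breeds = 1L, breed_sizes = as.integer(n),
                   breed_names = "B", markers_per_chrom = as.integer(mpc),
                   n_chromosomes = as.integer(chroms), missing_rate = 0,
                   h2_polygenic = h2, qtl_spec = qs, seed = seed)
  ped <- simulatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  ph <- simulatePhenotypes(ped, g, cfg)
  cohort <- ph$animal_id
  v <- calls(g)[cohort, ]
  p <- colMeans(v) / 2
  ok <- p > 0 & p < 1
  list(G = new("GenotypeMatrix", calls = v[, ok], map = markerMap(g)[ok, ]),
       y = ph$height, qtl = attr(g, "qtl_snp_ids"), ph = ph)
}

test_that("LOCO GRMs never contain the left-out chromosome", {
  fx <- simCohortGenotypes(1, n = 80, mpc = 10, chroms = 4)
  loco <- locoGrms(fx$G)
  map <- markerMap(fx$G)
  for (ch in names(loco)) {
    keep <- map$chrom != as.integer(ch)
    expect_equal(loco[[ch]]@meta$n_markers, sum(keep))
    # direct reconstruction from the marker complement
    sub <- new("GenotypeMatrix", calls = calls(fx$G)[, keep],
               map = map[keep, ])
    expect_lt(max(abs(relValues(loco[[ch]]) -
                        relValues(genomicRelationship(sub)))), 1e-10)
  }
})

test_that("REML on the spectral profile recovers variance components", {
  # pure-noise phenotype: heritability estimate stays low
  h2s <- vapply(1:5, function(s) {
    fx <- simCohortGenotypes(s + 100, n = 250, mpc = 30, chroms = 4)
    set.seed(s)
    y <- rnorm(250)
    K <- genomicRelationship(fx$G)
    locoReml(y, NULL, K)$h2
  }, numeric(1))
  expect_lt(mean(h2s), 0.1)

  # h2 = 0.5 signal drawn directly on the GRM is recovered within +-0.1
  hits <- 0
  for (s in 1:10) {
    fx <- simCohortGenotypes(s + 200, n = 300, mpc = 40, chroms = 4)
    Kv <- relValues(genomicRelationship(fx$G))
    e <- eigen(Kv, symmetric = TRUE)
    set.seed(s)
    g <- e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(300))
    y <- as.vector(g) + rnorm(300, 0, sd(g))
    est <- locoReml(y, NULL, Kv)$h2
    if (abs(est - 0.5) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # identity kinship: variance split unidentifiable, boundary flagged or
  # estimate harmless; the GLS weights stay uniform either way
  set.seed(2)
  y <- rnorm(100)
  res <- locoReml(y, NULL, diag(100))
  expect_true(is.finite(res$loglik))
})

test_that("with identity kinship the Wald scan equals ordinary least squares", {
  fx <- simCohortGenotypes(7, n = 200, mpc = 8, chroms = 3)
  set.seed(99)
  y <- rnorm(200)
  n <- length(y)
  idK <- new("RelationshipMatrix", kind = "G", ids = animalIds(fx$G),
             values = diag(n), meta = list())
  loco <- setNames(rep(list(idK), 3), c("1", "2", "3"))
  gw <- mlmaLoco(y, NULL, fx$G, loco = loco)
  tb <- gwasTable(gw)
  # OLS oracle with the same variance convention (null-model residual
  # variance, chi-square reference)
  v <- calls(fx$G)
  sig0 <- sum((y - mean(y))^2) / (n - 1)
  for (j in sample(nrow(tb), 10)) {
    x <- v[, tb$snp_id[j]]
    xc <- x - mean(x)
    beta <- sum(xc * y) / sum(xc^2)
    chi2 <- beta^2 * sum(xc^2) / sig0
    p_ols <- pchisq(chi2, 1, lower.tail = FALSE)
    expect_equal(tb$p[j], p_ols, tolerance = 1e-6)
  }
})

test_that("the rotated per-SNP test reproduces a direct GLS solve", {
  fx <- simCohortGenotypes(31, n = 120, mpc = 6, chroms = 3, qtl_frac = 0.15)
  gw <- mlmaLoco(fx$y, NULL, fx$G)
  tb <- gwasTable(gw)
  map <- markerMap(fx$G)
  v <- calls(fx$G)
  for (ch in c("1", "3")) {
    vc <- gw@meta$varcomp[[ch]]
    on_c <- map$chrom == as.integer(ch)
    Kv <- relValues(genomicRelationship(
      new("GenotypeMatrix", calls = v[, !on_c], map = map[!on_c, ])))
    V <- vc$sigma2_g * Kv + vc$sigma2_e * diag(nrow(v))
    Vi <- solve(V)
    for (sid in map$snp_id[on_c][1:2]) {
      Xs <- cbind(1, v[, sid])
      XtVi <- t(Xs) %*% Vi
      bhat <- solve(XtVi %*% Xs, XtVi %*% fx$y)
      se <- sqrt(solve(XtVi %*% Xs)[2, 2])
      row <- tb[tb$snp_id == sid, ]
      expect_equal(row$beta, bhat[2], tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(row$se, se, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("Bonferroni thresholds scale with the number of tests", {
  expect_equal(significanceThresholds(1)[c("p05", "p01")],
               list(p05 = 0.05, p01 = 0.01))
  expect_equal(significanceThresholds(62070)$p05, 0.05 / 62070)
  ns <- c(1, 10, 1000, 62070)
  ths <- vapply(ns, function(n) significanceThresholds(n)$p05, numeric(1))
  expect_true(all(diff(ths) < 0))
  expect_error(significanceThresholds(0), "at least 1")
})

test_that("a planted QTL is found and conditioning removes its signal", {
  fx <- simCohortGenotypes(55, n = 400, mpc = 25, chroms = 6,
                           qtl_frac = 0.2, h2 = 0.2)
  gw <- mlmaLoco(fx$y, NULL, fx$G)
  tb <- gwasTable(gw)
  top <- tb$snp_id[which.min(tb$p)]
  map <- markerMap(fx$G)
  qtl_pos <- which(map$snp_id == fx$qtl)
  top_pos <- which(map$snp_id == top)
  expect_lte(abs(top_pos - qtl_pos), 2)
  expect_lt(min(tb$p), significanceThresholds(nrow(tb))$p05)

  # conditioning on the causal SNP empties its chromosome of signal
  gw2 <- mlmaLoco(fx$y, NULL, fx$G, conditioning = fx$qtl, chromosomes = 3)
  tb2 <- gwasTable(gw2)
  expect_false(fx$qtl %in% tb2$snp_id)  # conditioning SNP is not re-tested
  expect_gt(min(tb2$p), significanceThresholds(nrow(tb))$p05)

  expect_error(mlmaLoco(fx$y, NULL, fx$G, conditioning = "no_such_snp"),
               "absent")
})

test_that("variance partitioning recovers planted components", {
  fx <- simCohortGenotypes(77, n = 350, mpc = 25, chroms = 6,
                           qtl_frac = 0.25, h2 = 0.2)
  map <- markerMap(fx$G)
  # single component = the full GRM reduces to the REML heritability
  Kfull <- genomicRelationship(fx$G)
  pv1 <- partitionVariance(fx$y, NULL, list(all = Kfull))
  h2_reml <- locoReml(fx$y, NULL, Kfull)$h2
  expect_lt(abs(pv1$share - h2_reml), 0.05)

  # the QTL component's share lands near its simulated fraction
  Kq <- grmFromMarkers(fx$G, fx$qtl)
  Krest <- grmFromMarkers(fx$G, setdiff(map$snp_id, fx$qtl))
  pv <- partitionVariance(fx$y, NULL, list(qtl = Kq, rest = Krest))
  expect_lt(abs(pv$share[pv$component == "qtl"] - 0.25), 0.1)

  # null phenotypes: component shares centred at zero (averaged over draws
  # because one Haseman-Elston estimate carries sampling noise of its own)
  set.seed(5)
  sh0 <- replicate(5, {
    pv0 <- partitionVariance(rnorm(350), NULL, list(qtl = Kq, rest = Krest))
    pv0$share
  })
  expect_true(all(abs(rowMeans(sh0)) < 0.05))

  # identical components are rejected
  expect_error(partitionVariance(fx$y, NULL, list(a = Kq, b = Kq)),
               "collinear")
})
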