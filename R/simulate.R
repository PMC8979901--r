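#' Simulation configuration for a multi-breed reference population
#'
#' Bundles and validates every parameter of the pedigree / genotype /
#' phenotype generator. The defaults emulate the structure of a German
#' Warmblood withers-height reference population: five studbooks of unequal
#' size, a shallow (three ancestral generations) pedigree roughly seven
#' times the size of the final genotyped mare cohort, long-tailed sire
#' family sizes (a few sires with tens of daughters), ~60k autosomal SNPs on
#' 31 chromosomes, one major stature QTL on chromosome 3 contributing ~23%
#' of phenotypic variance plus a polygenic background, and heights around
#' 167.6 cm with total SD 3.5 cm.
#'
#' @param n_breeds number of subpopulations.
#' @param breed_sizes final-cohort (genotyped mare) count per breed.
#' @param breed_names labels, recycled to \code{n_breeds}.
#' @param scale multiplier applied to \code{breed_sizes} (sizes are rounded,
#'   minimum 5); convenience for reduced-scale runs.
#' @param n_founders_per_breed founder count per breed, or \code{NULL} to
#'   size founder tiers automatically so the whole pedigree is about seven
#'   times the final cohort.
#' @param n_generations number of ancestral generations above the final
#'   cohort.
#' @param sire_sharing_rate probability that a sire family in one breed is
#'   sired from another breed's stallion pool (sires approved across
#'   studbooks).
#' @param n_chromosomes autosome count (31 for the horse).
#' @param markers_per_chrom SNPs per chromosome, evenly spaced at 100 kb.
#' @param chrom_length_morgans genetic length per chromosome (uniform map).
#' @param founder_freq_divergence Fst-like scalar: founder allele
#'   frequencies per breed are Balding-Nichols draws around a shared
#'   ancestral frequency with this divergence.
#' @param qtl_spec data.frame (chrom, bp, variance_fraction); each QTL is
#'   snapped to the nearest simulated marker and forced polymorphic in every
#'   breed. \code{bp = NA} places the QTL mid-chromosome, whatever the map
#'   size.
#' @param h2_polygenic fraction of phenotypic variance from the pedigree
#'   polygenic term (simulated down the pedigree, not from markers, so
#'   marker-based and pedigree-based heritability can legitimately differ).
#' @param mean_height population mean height, cm.
#' @param sd_env residual (environmental) SD, cm. The implied total
#'   phenotypic variance is \code{sd_env^2 / (1 - h2_polygenic - sum(qtl))}.
#' @param age_class_effects additive cm effects of measurement age classes
#'   1..5 (class 1 = younger than 3 years).
#' @param missing_rate per-call missing-genotype probability.
#' @param seed integer seed; mandatory, all generator output is a pure
#'   function of the configuration.
#' @return a validated list of class \code{"SimConfig"}
#' @export
simConfig <- function(n_breeds = 5L,
                      breed_sizes = c(982L, 444L, 98L, 416L, 173L),
                      breed_names = c("HOL", "OL", "OS", "TRAK", "WESTF"),
                      scale = 1,
                      n_founders_per_breed = NULL,
                      n_generations = 3L,
                      sire_sharing_rate = 0.1,
                      n_chromosomes = 31L,
                      markers_per_chrom = 2000L,
                      chrom_length_morgans = 1,
                      founder_freq_divergence = 0.03,
                      qtl_spec = data.frame(chrom = 3L, bp = NA_integer_,
                                            variance_fraction = 0.23),
                      h2_polygenic = 0.27,
                      mean_height = 167.6,
                      sd_env = 2.475,
                      age_class_effects = c(-1.2, -0.3, 0, 0.2, 0.4),
                      missing_rate = 0.01,
                      seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  breed_sizes <- pmax(5L, as.integer(round(breed_sizes * scale)))
  if (length(breed_sizes) != n_breeds)
    stop("breed_sizes must have length n_breeds")
  if (any(breed_sizes <= 0)) stop("breed_sizes must be positive")
  breed_names <- rep_len(as.character(breed_names), n_breeds)
  qtl_spec <- as.data.frame(qtl_spec)
  if (nrow(qtl_spec) &&
      !all(c("chrom", "bp", "variance_fraction") %in% names(qtl_spec)))
    stop("qtl_spec needs columns chrom, bp, variance_fraction")
  fr <- if (nrow(qtl_spec)) qtl_spec$variance_fraction else numeric(0)
  if (any(fr < 0 | fr > 1) || h2_polygenic < 0 || h2_polygenic > 1 ||
      sum(fr) + h2_polygenic > 1)
    stop("variance fractions must lie in [0,1] and sum (with h2_polygenic) to at most 1")
  if (!is.null(n_founders_per_breed))
    n_founders_per_breed <- rep_len(as.integer(n_founders_per_breed), n_breeds)
  if (sire_sharing_rate < 0 || sire_sharing_rate > 1)
    stop("sire_sharing_rate must lie in [0,1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0,1)")
  cfg <- list(n_breeds = as.integer(n_breeds), breed_sizes = breed_sizes,
              breed_names = breed_names,
              n_founders_per_breed = n_founders_per_breed,
              n_generations = as.integer(n_generations),
              sire_sharing_rate = sire_sharing_rate,
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chrom = as.integer(markers_per_chrom),
              chrom_length_morgans = chrom_length_morgans,
              founder_freq_divergence = founder_freq_divergence,
              qtl_spec = qtl_spec, h2_polygenic = h2_polygenic,
              mean_height = mean_height, sd_env = sd_env,
              age_class_effects = age_class_effects,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

# family sizes with a long right tail (a few sires have tens of offspring):
# rounded lognormal, mean ~3.5, truncated at >= 1
drawFamilySizes <- function(n_needed) {
  sizes <- integer(0)
  while (sum(sizes) < n_needed)
    sizes <- c(sizes, pmax(1L, as.integer(round(
      rlnorm(max(8L, ceiling(n_needed / 3)), meanlog = 0.7, sdlog = 1.05)))))
  cut <- which(cumsum(sizes) >= n_needed)[1L]
  sizes <- sizes[seq_len(cut)]
  sizes[cut] <- sizes[cut] - (sum(sizes) - n_needed)
  sizes[sizes > 0L]
}

#' Simulate a multi-breed pedigree
#'
#' Builds \code{n_generations} ancestral tiers above a final all-female
#' cohort (the mares that later get genotypes and phenotypes). Offspring in
#' each tier draw their sire from the previous tier's stallions with
#' long-tailed family sizes, optionally from another breed's pool at rate
#' \code{sire_sharing_rate}, and their dam nearly one-to-one from the
#' previous tier's mares. Ancestral tiers shrink toward the present so the
#' whole pedigree is about seven times the final cohort. Deterministic given
#' \code{config$seed}.
#'
#' @param config a [simConfig()] object
#' @return a [Pedigree-class]; final-cohort animals are the females without
#'   recorded offspring (see [phenotypedCohort()])
#' @export
simulatePedigree <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nb <- config$n_breeds
  ng <- config$n_generations
  # ancestral tier size factors, oldest largest; chosen so total ~= 7x final
  fac <- if (ng > 0) seq(2.3, 1.5, length.out = ng) else numeric(0)
  tiers <- vector("list", ng + 1L)
  rec_all <- list()
  base_year <- 1997 - 6L * ng
  for (t in seq_len(ng + 1L)) {
    final <- t == ng + 1L
    recs <- list()
    for (b in seq_len(nb)) {
      bn <- config$breed_names[b]
      size <- if (final) config$breed_sizes[b]
              else if (t == 1L && !is.null(config$n_founders_per_breed))
                config$n_founders_per_breed[b]
              else as.integer(ceiling(config$breed_sizes[b] * fac[t]))
      ids <- sprintf("%s_G%d_%04d", bn, t, seq_len(size))
      sex <- if (final) rep("F", size)
             else sample(rep_len(c("F", "M"), size))  # balanced pools
      if (t == 1L) {
        sire <- dam <- rep(UNKNOWN_PARENT, size)
      } else {
        prev <- tiers[[t - 1L]]
        own_males <- prev$animal[prev$breed == bn & prev$sex == "M"]
        other_males <- prev$animal[prev$breed != bn & prev$sex == "M"]
        fams <- drawFamilySizes(size)
        pool <- if (length(own_males) >= length(fams))
          sample(own_males, length(fams)) else
          sample(own_males, length(fams), replace = TRUE)
        if (length(other_males) && config$sire_sharing_rate > 0) {
          shared <- runif(length(fams)) < config$sire_sharing_rate
          if (any(shared))
            pool[shared] <- sample(other_males, sum(shared), replace = TRUE)
        }
        sire <- rep(pool, fams)[sample.int(size)]
        own_females <- prev$animal[prev$breed == bn & prev$sex == "F"]
        dam <- if (length(own_females) >= size) sample(own_females, size)
               else sample(rep_len(sample(own_females), size))
      }
      yr0 <- base_year + 6L * (t - 1L)
      span <- if (final) 18L else 5L
      bd <- as.Date(sprintf("%d-01-01", yr0)) +
        sample.int(365L * (span + 1L), size, replace = TRUE) - 1L
      recs[[b]] <- data.frame(animal = ids, sire = sire, dam = dam,
                              birth_date = bd, sex = sex, breed = bn,
                              stringsAsFactors = FALSE)
    }
    tiers[[t]] <- do.call(rbind, recs)
    rec_all[[t]] <- tiers[[t]]
  }
  Pedigree(do.call(rbind, rec_all))
}

#' Final-cohort animals of a simulated pedigree
#'
#' The mares that receive phenotypes (and, in the default design, genotypes):
#' females with no recorded offspring.
#'
#' @param ped a [Pedigree-class]
#' @return character vector of animal ids, pedigree order
#' @export
phenotypedCohort <- function(ped) {
  rec <- pedRecords(ped)
  parents <- unique(c(rec$sire, rec$dam))
  rec$animal[rec$sex == "F" & !(rec$animal %in% parents)]
}

simMarkerMap <- function(config) {
  m <- config$markers_per_chrom
  data.frame(
    snp_id = sprintf("SNP_%d_%d", rep(seq_len(config$n_chromosomes), each = m),
                     rep(seq_len(m), config$n_chromosomes)),
    chrom = rep(seq_len(config$n_chromosomes), each = m),
    bp = rep(seq_len(m) * 100000L, config$n_chromosomes),
    alleleA = "A", alleleB = "B", stringsAsFactors = FALSE)
}

# map qtl_spec rows to column indices of the simulated marker map
qtlMarkerIndex <- function(map, config) {
  qs <- config$qtl_spec
  if (!nrow(qs)) return(integer(0))
  vapply(seq_len(nrow(qs)), function(k) {
    ch <- qs$chrom[k]
    on_chr <- which(map$chrom == ch)
    if (!length(on_chr))
      stop("QTL chromosome ", ch, " outside the simulated map")
    bp <- qs$bp[k]
    if (is.na(bp)) bp <- stats::median(map$bp[on_chr])  # mid-chromosome
    if (bp < 1 || bp > max(map$bp[on_chr]))
      stop("QTL position ", bp, " outside chromosome ", ch)
    on_chr[which.min(abs(map$bp[on_chr] - bp))]
  }, integer(1))
}

#' Simulate SNP genotypes down a pedigree
#'
#' Founder haplotypes are drawn from breed-specific allele frequencies
#' (Balding-Nichols perturbation of a shared ancestral frequency with
#' divergence \code{founder_freq_divergence}); descendants are gene-dropped
#' with recombination as a Poisson/Haldane process along a uniform genetic
#' map of \code{chrom_length_morgans} per chromosome. QTL markers are forced
#' polymorphic (frequency clamped to [0.1, 0.9]) in every breed. Missing
#' calls are masked at \code{missing_rate}. Deterministic given
#' \code{config$seed}.
#'
#' @param ped a [Pedigree-class] (topologically ordered, as the class
#'   guarantees)
#' @param config a [simConfig()] object
#' @return a [GenotypeMatrix-class] covering every pedigree animal; the QTL
#'   marker ids are attached as \code{attr(, "qtl_snp_ids")}
#' @export
simulateGenotypes <- function(ped, config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  rec <- pedRecords(ped)
  n <- nrow(rec)
  map <- simMarkerMap(config)
  m <- nrow(map)
  qtl_idx <- qtlMarkerIndex(map, config)
  breeds <- unique(rec$breed)

  p_anc <- runif(m, 0.05, 0.95)
  Fst <- config$founder_freq_divergence
  pb <- matrix(0, length(breeds), m, dimnames = list(breeds, NULL))
  for (b in seq_along(breeds)) {
    pb[b, ] <- if (Fst > 0)
      rbeta(m, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst)
    else p_anc
    if (length(qtl_idx))
      pb[b, qtl_idx] <- pmin(0.9, pmax(0.1, pb[b, qtl_idx]))
  }

  # per-chromosome adjacent recombination fractions (Haldane, uniform map)
  mc <- config$markers_per_chrom
  d <- config$chrom_length_morgans / max(1L, mc - 1L)
  r_adj <- 0.5 * (1 - exp(-2 * d))
  chrom_of <- map$chrom

  H1 <- matrix(raw(1), n, m)
  H2 <- matrix(raw(1), n, m)
  idx <- seq_len(n); names(idx) <- rec$animal
  breed_row <- match(rec$breed, breeds)

  gamete <- function(parent_id, breed_i) {
    if (parent_id == UNKNOWN_PARENT)
      return(as.raw(runif(m) < pb[breed_i, ]))
    pi <- idx[[parent_id]]
    sw <- runif(m) < r_adj
    # restart the switch chain at each chromosome boundary with a fresh coin
    newchrom <- c(TRUE, chrom_of[-1L] != chrom_of[-m])
    sw[newchrom] <- runif(sum(newchrom)) < 0.5
    state <- cumsum(sw) %% 2L
    g <- H1[pi, ]
    w <- state == 1L
    g[w] <- H2[pi, w]
    g
  }
  for (i in seq_len(n)) {
    H1[i, ] <- gamete(rec$sire[i], breed_row[i])
    H2[i, ] <- gamete(rec$dam[i], breed_row[i])
  }
  callsm <- matrix(as.integer(H1) + as.integer(H2), n, m)
  if (config$missing_rate > 0)
    callsm[runif(n * m) < config$missing_rate] <- NA_integer_
  rownames(callsm) <- rec$animal
  G <- GenotypeMatrix(callsm, map)
  attr(G, "qtl_snp_ids") <- map$snp_id[qtl_idx]
  G
}

#' Simulate withers-height phenotypes
#'
#' Height = mean + age-class effect + QTL dosage effects (each scaled so it
#' contributes its configured fraction of the implied total phenotypic
#' variance) + a polygenic value transmitted down the pedigree (founder draw
#' plus Mendelian sampling) + environmental noise. Phenotyped animals are
#' the final-cohort mares ([phenotypedCohort()]); measurement ages are drawn
#' so all five age classes occur. Deterministic given \code{config$seed}.
#'
#' @param ped a [Pedigree-class]
#' @param genotypes a [GenotypeMatrix-class] covering the phenotyped animals
#' @param config a [simConfig()] object
#' @return data.frame (animal_id, height, measurement_date, source,
#'   age_years, age_class) with an attached \code{attr(, "truth")}:
#'   per-pedigree-animal polygenic values, per-cohort QTL values, and the
#'   implied total variance
#' @export
simulatePhenotypes <- function(ped, genotypes, config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 2L)
  rec <- pedRecords(ped)
  cohort <- phenotypedCohort(ped)
  if (!length(cohort)) stop("pedigree has no final-cohort females")
  if (!all(cohort %in% animalIds(genotypes)))
    stop("genotypes do not cover all phenotyped animals")

  qfrac <- if (nrow(config$qtl_spec)) config$qtl_spec$variance_fraction
           else numeric(0)
  env_frac <- 1 - config$h2_polygenic - sum(qfrac)
  v_total <- if (env_frac > 0) config$sd_env^2 / env_frac
             else (config$sd_env^2 + 1) # degenerate: no env variance planned
  if (config$sd_env == 0) v_total <- 1  # fractions then act on unit variance

  # polygenic values for the whole pedigree: founder draw + Mendelian sampling
  sig_u <- sqrt(config$h2_polygenic * v_total)
  u <- numeric(nrow(rec)); names(u) <- rec$animal
  for (i in seq_len(nrow(rec))) {
    s <- rec$sire[i]; dd <- rec$dam[i]
    ks <- s != UNKNOWN_PARENT; kd <- dd != UNKNOWN_PARENT
    pa <- (if (ks) u[[s]] else 0) / 2 + (if (kd) u[[dd]] else 0) / 2
    msv <- sig_u^2 * (1 - 0.25 * ks - 0.25 * kd)
    u[i] <- pa + rnorm(1, 0, sqrt(msv))
  }

  # QTL values, scaled on realized cohort dosage variance
  qtl_ids <- attr(genotypes, "qtl_snp_ids")
  gq <- numeric(length(cohort))
  if (length(qtl_ids)) {
    X <- calls(genotypes)[cohort, qtl_ids, drop = FALSE]
    for (k in seq_along(qtl_ids)) {
      x <- X[, k]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      vx <- var(x)
      if (vx <= 0) stop("QTL marker ", qtl_ids[k],
                        " is monomorphic in the phenotyped cohort")
      alpha <- sqrt(qfrac[k] * v_total / vx)
      gq <- gq + alpha * (x - mean(x))
    }
  }

  nc <- length(cohort)
  age <- pmin(14, pmax(1.6, rnorm(nc, 4.4, 2.6)))
  if (nc >= 5L) age[1:5] <- c(2.5, 3.5, 4.5, 5.5, 7.0)  # every class occurs
  acl <- ageClass(age)
  bd <- rec$birth_date[match(cohort, rec$animal)]
  mdate <- bd + round(age * 365.25)
  height <- config$mean_height + config$age_class_effects[acl] +
    gq + u[cohort] + rnorm(nc, 0, config$sd_env)
  out <- data.frame(animal_id = cohort, height = height,
                    measurement_date = mdate,
                    source = sample(c("SBR", "MPT"), nc, replace = TRUE,
                                    prob = c(0.94, 0.06)),
                    age_years = age, age_class = acl,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(u = u, qtl = setNames(gq, cohort),
                             v_total = v_total,
                             h2_total = config$h2_polygenic + sum(qfrac))
  out
}
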