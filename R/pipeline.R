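#' Pipeline run configuration
#'
#' One flat, serialisable source of truth for an end-to-end run:
#' simulate -> QC -> relationship matrices -> single-step fit -> LOCO GWAS
#' -> report. The default preset is the full-scale multi-breed population preset
#' at quarter scale with 200 SNPs per chromosome, sized so a full run
#' completes on a single desktop core.
#'
#' @param out_dir output directory for all artifacts
#' @param seed integer seed driving every stochastic stage (mandatory)
#' @param stages character vector of stages to run, in fixed order
#' @param scale multiplier on the preset breed sizes
#' @param markers_per_chrom simulated SNPs per chromosome
#' @param maf_min,callrate_min,hwe_p_min QC thresholds
#' @param blend_weight G blending weight passed to [blendG()]
#' @param n_iter,burn_in,thin Gibbs chain settings
#' @param genotype_format \code{"bed"} or \code{"ped"} for on-disk genotypes
#' @param sim_args extra arguments for [simConfig()] (e.g. \code{qtl_spec},
#'   \code{h2_polygenic})
#' @return list of class \code{"RunConfig"}
#' @export
runConfig <- function(out_dir, seed,
                      stages = c("simulate", "qc", "relmat", "fit", "gwas",
                                 "report"),
                      scale = 0.25, markers_per_chrom = 200L,
                      maf_min = 0.01, callrate_min = 0.90, hwe_p_min = 0.001,
                      blend_weight = 0.95,
                      n_iter = 6000L, burn_in = 1000L, thin = 5L,
                      genotype_format = c("bed", "ped"),
                      sim_args = list()) {
  if (missing(seed)) stop("seed is mandatory")
  if (missing(out_dir)) stop("out_dir is required")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
              scale = scale, markers_per_chrom = as.integer(markers_per_chrom),
              maf_min = maf_min, callrate_min = callrate_min,
              hwe_p_min = hwe_p_min, blend_weight = blend_weight,
              n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              thin = as.integer(thin),
              genotype_format = match.arg(genotype_format),
              sim_args = sim_args)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a flat key-value run configuration file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment. Numeric
#' values are coerced; \code{stages} is comma-separated.
#'
#' @param path config file
#' @param out_dir,seed overrides (take precedence over the file)
#' @return list of class \code{"RunConfig"}
#' @export
readRunConfig <- function(path, out_dir = NULL, seed = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  args <- as.list(vals)
  names(args) <- keys
  num <- suppressWarnings(vapply(args, function(x) !is.na(as.numeric(x)),
                                 logical(1)))
  args[num] <- lapply(args[num], as.numeric)
  if ("stages" %in% keys)
    args$stages <- trimws(strsplit(as.character(args$stages), ",")[[1L]])
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(seed)) args$seed <- seed
  do.call(runConfig, args)
}

.manifestAdd <- function(run_dir, stage, files) {
  mf <- file.path(run_dir, "manifest.tsv")
  rows <- data.frame(stage = stage, file = basename(files),
                     md5 = as.character(tools::md5sum(files)))
  write.table(rows, mf, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !file.exists(mf), append = file.exists(mf))
}

#' Run the end-to-end single-step evaluation pipeline
#'
#' Executes the enabled stages in fixed order inside \code{out_dir}, writing
#' every artifact together with a manifest of content hashes. Re-running
#' with an identical configuration reproduces identical numeric outputs. On
#' stage failure a \code{FAILED} marker naming the stage is left behind and
#' the error is rethrown.
#'
#' @param config a [runConfig()] object
#' @return invisibly, the run directory
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  downstream <- setdiff(config$stages, "simulate")
  if (length(downstream) && !("simulate" %in% config$stages))
    stop("validation error: downstream stages enabled without the simulate ",
         "stage (external inputs are not configured)")
  run_dir <- config$out_dir
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(run_dir, c("manifest.tsv", "FAILED")))
  stage <- "init"
  run <- function(name, expr) {
    stage <<- name
    if (!(name %in% config$stages)) return(invisible(NULL))
    expr
  }
  tryCatch({
    sc <- do.call(simConfig, c(list(seed = config$seed, scale = config$scale,
                                    markers_per_chrom = config$markers_per_chrom),
                               config$sim_args))
    ped <- genos <- phenos <- NULL
    run("simulate", {
      ped <- simulatePedigree(sc)
      genos <- simulateGenotypes(ped, sc)
      phenos <- simulatePhenotypes(ped, genos, sc)
      writePedigree(ped, file.path(run_dir, "pedigree.csv"))
      writePhenotypes(phenos, file.path(run_dir, "phenotypes.tsv"))
      cohort <- phenotypedCohort(ped)
      gsub_ <- new("GenotypeMatrix", calls = calls(genos)[cohort, , drop = FALSE],
                   map = markerMap(genos))
      writeGenotypes(gsub_, file.path(run_dir, "genotypes"),
                     format = config$genotype_format)
      ext <- if (config$genotype_format == "bed") c(".bed", ".bim", ".fam")
             else c(".ped", ".map")
      .manifestAdd(run_dir, "simulate",
                   file.path(run_dir, c("pedigree.csv", "phenotypes.tsv",
                                        paste0("genotypes", ext))))
      invisible(NULL)
    })
    qcd <- NULL
    run("qc", {
      cohort <- phenotypedCohort(ped)
      gsub_ <- new("GenotypeMatrix", calls = calls(genos)[cohort, , drop = FALSE],
                   map = markerMap(genos))
      res <- qcFilter(gsub_, maf_min = config$maf_min,
                      callrate_min = config$callrate_min,
                      hwe_p_min = config$hwe_p_min)
      qcd <- imputeMissing(res$genotypes, seed = config$seed + 11L)
      writeQcReport(res$report, file.path(run_dir, "qc_report.tsv"))
      .manifestAdd(run_dir, "qc", file.path(run_dir, "qc_report.tsv"))
    })
    Gblend <- NULL
    run("relmat", {
      A <- numeratorRelationship(ped)
      Graw <- genomicRelationship(qcd)
      A22 <- a22Matrix(A, animalIds(Graw))
      Gblend <- blendG(Graw, A22, weight = config$blend_weight)
      pca <- grmPCA(Graw, 2L)
      ptab <- data.frame(animal_id = rownames(pca$scores),
                         PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
      write.table(ptab, file.path(run_dir, "grm_pca.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      writeLines(sprintf("PC%d\t%.6f", seq_along(pca$varfrac), pca$varfrac),
                 file.path(run_dir, "grm_pca_varfrac.tsv"))
      .manifestAdd(run_dir, "relmat",
                   file.path(run_dir, c("grm_pca.tsv", "grm_pca_varfrac.tsv")))
    })
    fit <- NULL
    run("fit", {
      fit <- fitSingleStep(phenos, ped, Gblend, n_iter = config$n_iter,
                            burn_in = config$burn_in, thin = config$thin,
                            seed = config$seed + 21L)
      writeResults(fit, file.path(run_dir, "ebv.tsv"))
      vc <- varianceComponents(fit)
      writeLines(c(sprintf("sigma2_a\t%.6g", vc["sigma2_a"]),
                   sprintf("sigma2_e\t%.6g", vc["sigma2_e"]),
                   sprintf("h2\t%.6g", vc["h2"]),
                   sprintf("h2_sd\t%.6g", fit@se$h2)),
                 file.path(run_dir, "varcomp.tsv"))
      .manifestAdd(run_dir, "fit", file.path(run_dir, c("ebv.tsv", "varcomp.tsv")))
    })
    run("gwas", {
      ord <- match(rownames(calls(qcd)), phenos$animal_id)
      yv <- phenos$height[ord]
      acl <- phenos$age_class[ord]
      Xg <- cbind(intercept = 1,
                  vapply(2:5, function(cl) as.numeric(acl == cl), numeric(length(yv))))
      Xg <- Xg[, c(TRUE, vapply(2:5, function(cl) any(acl == cl), logical(1))),
               drop = FALSE]
      gw <- mlmaLoco(yv, Xg, qcd)
      writeResults(gw, file.path(run_dir, "gwas.tsv"))
      .manifestAdd(run_dir, "gwas", file.path(run_dir, "gwas.tsv"))
    })
    run("report", {
      rep_lines <- reportSummary(run_dir, ped = ped, phenos = phenos,
                                 fit = fit, genotyped = animalIds(qcd))
      .manifestAdd(run_dir, "report", file.path(run_dir, "report.txt"))
      invisible(rep_lines)
    })
  }, error = function(e) {
    writeLines(paste("stage:", stage), file.path(run_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(run_dir)
}

#' Summarise a completed run
#'
#' Emits descriptive phenotype statistics per breed (count, mean, SD, min,
#' max), the variance components and heritability, and reliability
#' summaries (mean/min/max) for three strata: all pedigree animals, animals
#' with neither genotype nor phenotype, and the genotyped-and-phenotyped
#' reference cohort.
#'
#' @param run_dir a completed run directory
#' @param ped,phenos,fit,genotyped optional in-memory objects; when absent
#'   they are re-read from the run directory
#' @return character vector of report lines (also written to
#'   \code{report.txt}), invisibly
#' @export
reportSummary <- function(run_dir, ped = NULL, phenos = NULL, fit = NULL,
                          genotyped = NULL) {
  ebv_path <- file.path(run_dir, "ebv.tsv")
  if (is.null(fit) && !file.exists(ebv_path))
    stop("missing fit-stage output (ebv.tsv) in ", run_dir)
  if (is.null(ped)) ped <- readPedigree(file.path(run_dir, "pedigree.csv"), "csv")
  if (is.null(phenos))
    phenos <- readPhenotypes(file.path(run_dir, "phenotypes.tsv"), ped)
  rec <- pedRecords(ped)
  if (is.null(genotyped)) {
    qcr <- file.path(run_dir, "qc_report.tsv")
    genotyped <- phenos$animal_id  # reference-cohort design
  }
  if (!is.null(fit)) {
    ids <- animalIds(fit); r2 <- reliabilities(fit)
    vc <- varianceComponents(fit)
  } else {
    tb <- read.table(ebv_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    ids <- as.character(tb$animal_id); r2 <- setNames(tb$reliability, ids)
    vct <- read.table(file.path(run_dir, "varcomp.tsv"), sep = "\t",
                      row.names = 1)
    vc <- setNames(vct[[1]], rownames(vct))
  }
  br <- rec$breed[match(phenos$animal_id, rec$animal)]
  lines <- c("== Phenotype summary by breed ==",
             "breed\tn\tmean\tsd\tmin\tmax")
  for (b in unique(br)) {
    h <- phenos$height[br == b]
    lines <- c(lines, sprintf("%s\t%d\t%.1f\t%.1f\t%.1f\t%.1f", b,
                              length(h), mean(h), sd(h), min(h), max(h)))
  }
  h <- phenos$height
  lines <- c(lines, sprintf("Total\t%d\t%.1f\t%.1f\t%.1f\t%.1f",
                            length(h), mean(h), sd(h), min(h), max(h)),
             "", "== Variance components ==",
             sprintf("sigma2_a = %.4g cm^2, sigma2_e = %.4g cm^2, h2 = %.3f",
                     vc[["sigma2_a"]], vc[["sigma2_e"]], vc[["h2"]]),
             "", "== Reliability (r2 = 1 - PEV/sigma2_a) by stratum ==",
             "stratum\tn\tmean\tmin\tmax")
  phen_ids <- phenos$animal_id
  strata <- list(
    "all animals" = ids,
    "no genotype, no phenotype" = setdiff(ids, union(genotyped, phen_ids)),
    "genotyped and phenotyped" = intersect(genotyped, phen_ids))
  for (snm in names(strata)) {
    sids <- strata[[snm]]
    if (!length(sids)) {
      lines <- c(lines, sprintf("%s\t0\tNA\tNA\tNA", snm))
    } else {
      rr <- r2[sids]
      lines <- c(lines, sprintf("%s\t%d\t%.2f\t%.2f\t%.2f", snm,
                                length(sids), mean(rr), min(rr), max(rr)))
    }
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
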