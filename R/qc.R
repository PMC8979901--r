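#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the counts expected at the sample allele frequency. Monomorphic
#' input returns p = 1 (no testable heterozygote class).
#'
#' @param nAA,nAB,nBB genotype counts
#' @return p-value
#' @export
hweTest <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stop("counts must be non-negative")
  n <- nAA + nAB + nBB
  if (n == 0) stop("all genotype counts are zero")
  p <- (2 * nBB + nAB) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((c(nAA, nAB, nBB) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Marker quality control
#'
#' Removes markers in a fixed rule order, each marker counted once under the
#' first rule it fails: duplicates (same chromosome and position; the first
#' marker in snp_id order is kept), call rate below \code{callrate_min},
#' minor allele frequency below \code{maf_min}, and Hardy-Weinberg
#' chi-square p below \code{hwe_p_min} (pooled over all animals).
#' Non-autosomal markers are already excluded by the GenotypeMatrix class;
#' their count on read is reported as 0 here. Surviving markers keep their
#' order. Running the filter on its own output changes nothing.
#'
#' @param G a [GenotypeMatrix-class]
#' @param maf_min minimum minor allele frequency (default 0.01)
#' @param callrate_min minimum per-marker call rate (default 0.90)
#' @param hwe_p_min minimum HWE chi-square p-value (default 0.001)
#' @return list with elements \code{genotypes} (filtered
#'   [GenotypeMatrix-class]) and \code{report} (a QC report list: input /
#'   output counts, per-rule removal counts, and a per-SNP removal table)
#' @export
qcFilter <- function(G, maf_min = 0.01, callrate_min = 0.90,
                     hwe_p_min = 0.001) {
  v <- calls(G); map <- markerMap(G)
  m <- ncol(v); n <- nrow(v)
  reason <- rep(NA_character_, m)

  # duplicates share (chrom, bp); the first in snp_id order is kept
  o <- order(map$chrom, map$bp, map$snp_id)
  dup_o <- duplicated(map[o, c("chrom", "bp")])
  dup <- logical(m); dup[o] <- dup_o
  reason[dup] <- "duplicate"

  todo <- is.na(reason)
  called <- colSums(!is.na(v))
  callrate <- called / n
  reason[todo & callrate < callrate_min] <- "callrate"

  todo <- is.na(reason)
  pB <- colMeans(v, na.rm = TRUE) / 2
  maf <- pmin(pB, 1 - pB)
  maf[called == 0] <- 0
  reason[todo & maf < maf_min] <- "maf"

  todo <- is.na(reason)
  if (any(todo)) {
    hwe_p <- vapply(which(todo), function(j) {
      x <- v[, j]
      hweTest(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
              sum(x == 2L, na.rm = TRUE))
    }, numeric(1))
    reason[which(todo)[hwe_p < hwe_p_min]] <- "hwe"
  }

  keep <- is.na(reason)
  report <- list(
    n_input = m,
    removed_nonautosomal = 0L,
    removed_duplicate = sum(reason == "duplicate", na.rm = TRUE),
    removed_callrate = sum(reason == "callrate", na.rm = TRUE),
    removed_maf = sum(reason == "maf", na.rm = TRUE),
    removed_hwe = sum(reason == "hwe", na.rm = TRUE),
    n_output = sum(keep),
    removals = data.frame(snp_id = map$snp_id[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE))
  if (!any(keep)) warning("no markers survive QC")
  out <- new("GenotypeMatrix", calls = v[, keep, drop = FALSE],
             map = { mm <- map[keep, , drop = FALSE]; rownames(mm) <- NULL; mm })
  list(genotypes = out, report = report)
}

#' Write a QC report as TSV
#' @param report the \code{report} element of [qcFilter()]
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeQcReport <- function(report, path) {
  counts <- report[c("n_input", "removed_nonautosomal", "removed_duplicate",
                     "removed_callrate", "removed_maf", "removed_hwe",
                     "n_output")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(counts), unlist(counts), sep = "\t"), con)
  if (nrow(report$removals)) {
    writeLines("", con)
    write.table(report$removals, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Seeded allele-frequency imputation of missing calls
#'
#' Each missing call is drawn from Binomial(2, p) with p the marker's
#' observed allele-B frequency. This is a deliberately simple stand-in for
#' LD-haplotype imputation: the downstream pipeline needs complete dosage
#' matrices, not phasing accuracy. Deterministic given \code{seed}.
#'
#' @param G a [GenotypeMatrix-class] (QC already applied)
#' @param seed integer seed
#' @return a [GenotypeMatrix-class] with no missing calls
#' @export
imputeMissing <- function(G, seed) {
  v <- calls(G)
  if (!anyNA(v)) return(G)
  set.seed(as.integer(seed))
  called <- colSums(!is.na(v))
  if (any(called == 0))
    stop("cannot impute: marker(s) with no observed calls: ",
         paste(markerMap(G)$snp_id[called == 0], collapse = ", "))
  pB <- colMeans(v, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(v)) > 0)) {
    miss <- is.na(v[, j])
    v[miss, j] <- rbinom(sum(miss), 2L, pB[j])
  }
  new("GenotypeMatrix", calls = v, map = markerMap(G))
}
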