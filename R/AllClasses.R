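#' @import methods
#' @importFrom stats var sd cor rnorm runif rbinom rbeta rlnorm pchisq qchisq
#'   optimize setNames
#' @importFrom utils read.table write.table head
#' @useDynLib stepreins, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

UNKNOWN_PARENT <- "0"

#' Pedigree of a (horse) population
#'
#' Holds one record per animal with sire/dam links, birth date, sex and breed
#' label, stored in topological order (every parent precedes its offspring).
#' Unknown parents are represented by the sentinel \code{"0"}; any parent that
#' is named but has no own record is materialised as a founder on
#' construction.
#'
#' @slot records data.frame with columns \code{animal}, \code{sire},
#'   \code{dam} (character; \code{"0"} for unknown), \code{birth_date}
#'   (Date), \code{sex} (\code{"F"}, \code{"M"} or \code{"U"}) and
#'   \code{breed} (character label).
#'
#' @seealso [readPedigree()], [simulatePedigree()], [numeratorRelationship()]
#' @export
setClass("Pedigree", representation(records = "data.frame"))

setValidity("Pedigree", function(object) {
  rec <- object@records
  need <- c("animal", "sire", "dam", "birth_date", "sex", "breed")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$animal))
    return(paste("duplicate animal ids:",
                 paste(unique(rec$animal[duplicated(rec$animal)]), collapse = ", ")))
  if (!all(rec$sex %in% c("F", "M", "U")))
    return("sex must be one of F, M, U")
  idx <- seq_len(nrow(rec))
  names(idx) <- rec$animal
  for (p in c("sire", "dam")) {
    known <- rec[[p]] != UNKNOWN_PARENT
    if (!all(rec[[p]][known] %in% rec$animal))
      return(sprintf("%s ids without a record: %s", p,
                     paste(setdiff(rec[[p]][known], rec$animal), collapse = ", ")))
    if (any(idx[rec[[p]][known]] >= idx[known]))
      return(sprintf("records not topologically ordered (a %s follows its offspring)", p))
  }
  # parent-sex consistency (only where sex is declared)
  sx <- setNames(rec$sex, rec$animal)
  sire_sex <- sx[rec$sire[rec$sire != UNKNOWN_PARENT]]
  if (any(sire_sex == "F")) return("a sire has sex F")
  dam_sex <- sx[rec$dam[rec$dam != UNKNOWN_PARENT]]
  if (any(dam_sex == "M")) return("a dam has sex M")
  TRUE
})

#' SNP genotype matrix
#'
#' Animals by markers dosage matrix with values in \{0, 1, 2, NA\}, counting
#' copies of allele B (the second allele column of the marker map, the
#' \code{.bim} convention). Markers are kept sorted by (chromosome, bp) and
#' restricted to autosomes 1--31 (the equine autosome count).
#'
#' @slot calls integer matrix, animals in rows (rownames = animal ids),
#'   markers in columns (colnames = SNP ids); \code{NA} = missing call.
#' @slot map data.frame with columns \code{snp_id}, \code{chrom} (integer,
#'   1--31), \code{bp} (1-based integer position), \code{alleleA},
#'   \code{alleleB}.
#'
#' @seealso [readGenotypes()], [qcFilter()], [genomicRelationship()]
#' @export
setClass("GenotypeMatrix", representation(calls = "matrix", map = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@map
  need <- c("snp_id", "chrom", "bp", "alleleA", "alleleB")
  if (!all(need %in% names(m)))
    return(paste("map must have columns:", paste(need, collapse = ", ")))
  if (ncol(object@calls) != nrow(m))
    return("ncol(calls) != nrow(map)")
  if (is.null(rownames(object@calls)))
    return("calls must have animal ids as rownames")
  if (nrow(m) > 0) {
    if (!all(m$chrom %in% 1:31))
      return("chrom must be an autosome code in 1..31")
    if (!identical(order(m$chrom, m$bp), seq_len(nrow(m))))
      return("markers must be sorted by (chrom, bp)")
    # duplicate (chrom, bp) markers are representable here; qcFilter()
    # removes them, restoring the post-QC uniqueness invariant
    v <- object@calls
    if (!all(v[!is.na(v)] %in% 0:2))
      return("calls must be in {0,1,2,NA}")
  }
  TRUE
})

#' Relationship matrix (A, G, H and relatives)
#'
#' A symmetric additive-relationship matrix (or a lower-triangular Cholesky
#' factor of one) together with the animal ids indexing its rows, and the
#' parameters it was built with.
#'
#' @slot kind one of \code{"A"}, \code{"A_inverse"}, \code{"A22"}, \code{"G"},
#'   \code{"H"}, \code{"H_inverse"}, \code{"H_cholesky"}.
#' @slot ids character, animal ids in row order.
#' @slot values numeric matrix (dense) with dimnames = ids.
#' @slot meta list of construction parameters (blend weight, allele-frequency
#'   source, jitter applied, ...).
#'
#' @seealso [numeratorRelationship()], [genomicRelationship()], [hMatrix()]
#' @export
setClass("RelationshipMatrix",
         representation(kind = "character", ids = "character",
                        values = "matrix", meta = "list"))

setValidity("RelationshipMatrix", function(object) {
  kinds <- c("A", "A_inverse", "A22", "G", "H", "H_inverse", "H_cholesky")
  if (!(length(object@kind) == 1L && object@kind %in% kinds))
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  v <- object@values
  n <- length(object@ids)
  if (!(nrow(v) == n && ncol(v) == n))
    return("values must be square with one row per id")
  if (object@kind != "H_cholesky" && n > 0 &&
      max(abs(v - t(v))) > 1e-6 * max(1, max(abs(v))))
    return("values must be symmetric")
  TRUE
})

#' Fitted single-step animal model
#'
#' Posterior summaries (or deterministic BLUP solutions) for the animal model
#' y = Xb + Za + e with Var(a) proportional to a relationship matrix:
#' fixed effects, per-animal breeding values with prediction error variances,
#' and variance components.
#'
#' @slot b named numeric, fixed-effect estimates (cm).
#' @slot a named numeric, breeding values for every pedigree animal (cm).
#' @slot pev named numeric, per-animal prediction error variance (cm^2).
#' @slot sigma2_a additive genetic variance (cm^2).
#' @slot sigma2_e residual variance (cm^2).
#' @slot h2 heritability sigma2_a / (sigma2_a + sigma2_e).
#' @slot se list of standard errors / posterior SDs (elements \code{b},
#'   \code{a}, \code{sigma2_a}, \code{sigma2_e}, \code{h2} when available).
#' @slot diagnostics list: chain settings, effective sizes, solver notes.
#'
#' @seealso [fitGibbs()], [solveMME()], [reliabilities()]
#' @export
setClass("ModelFit",
         representation(b = "numeric", a = "numeric", pev = "numeric",
                        sigma2_a = "numeric", sigma2_e = "numeric",
                        h2 = "numeric", se = "list", diagnostics = "list"))

setValidity("ModelFit", function(object) {
  if (length(object@sigma2_a) != 1L || object@sigma2_a <= 0)
    return("sigma2_a must be a single positive number")
  if (length(object@sigma2_e) != 1L || object@sigma2_e <= 0)
    return("sigma2_e must be a single positive number")
  if (object@h2 < 0 || object@h2 > 1) return("h2 must lie in [0,1]")
  if (length(object@pev) && length(object@pev) != length(object@a))
    return("pev must align with a")
  if (length(object@pev) && any(object@pev < -1e-8))
    return("pev must be non-negative")
  TRUE
})

#' Genome-wide association scan result
#'
#' One row per tested SNP with the mixed-linear-model Wald test, plus the
#' leave-one-chromosome-out bookkeeping (variance components per left-out
#' chromosome, conditioning SNPs, thresholds).
#'
#' @slot table data.frame with columns \code{chrom}, \code{snp_id}, \code{bp},
#'   \code{alleleB}, \code{freq}, \code{beta} (cm per allele-B copy),
#'   \code{se}, \code{chi2}, \code{p}, \code{minus_log10_p}.
#' @slot meta list: \code{loco} flag, \code{conditioning} SNP ids,
#'   \code{varcomp} per left-out chromosome, \code{thresholds}.
#'
#' @seealso [mlmaLoco()], [significanceThresholds()]
#' @export
setClass("GwasResult", representation(table = "data.frame", meta = "list"))

setValidity("GwasResult", function(object) {
  tb <- object@table
  need <- c("chrom", "snp_id", "bp", "alleleB", "freq", "beta", "se",
            "chi2", "p", "minus_log10_p")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  ok <- !is.na(tb$p)
  if (any(tb$p[ok] <= 0 | tb$p[ok] > 1)) return("p must lie in (0,1]")
  if (any(tb$freq[!is.na(tb$freq)] < 0 | tb$freq[!is.na(tb$freq)] > 1))
    return("freq must lie in [0,1]")
  TRUE
})
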