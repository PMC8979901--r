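# Accessor generics: slot access stays behind these.

#' Animal identifiers of an object
#' @param x a Pedigree, GenotypeMatrix, RelationshipMatrix or ModelFit
#' @return character vector of animal ids, in the object's storage order
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' Number of animals in an object
#' @param x a Pedigree or GenotypeMatrix
#' @return integer count
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' Pedigree records as a data.frame
#' @param x a Pedigree
#' @return data.frame (animal, sire, dam, birth_date, sex, breed),
#'   topologically ordered
#' @export
setGeneric("pedRecords", function(x) standardGeneric("pedRecords"))

#' Dosage calls of a GenotypeMatrix
#' @param x a GenotypeMatrix
#' @return integer matrix animals x markers, values 0/1/2/NA (allele-B count)
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' Marker map of a GenotypeMatrix
#' @param x a GenotypeMatrix
#' @return data.frame (snp_id, chrom, bp, alleleA, alleleB), sorted
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' Numeric values of a RelationshipMatrix
#' @param x a RelationshipMatrix
#' @return dense numeric matrix with animal ids as dimnames
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))

#' Kind tag of a RelationshipMatrix
#' @param x a RelationshipMatrix
#' @return single string, e.g. "A", "G", "H_inverse"
#' @export
setGeneric("relKind", function(x) standardGeneric("relKind"))

#' Breeding values of a fitted model
#' @param x a ModelFit
#' @return named numeric vector, one (G)EBV per pedigree animal, in cm
#' @export
setGeneric("breedingValues", function(x) standardGeneric("breedingValues"))

#' Prediction error variances of a fitted model
#' @param x a ModelFit
#' @return named numeric vector of PEVs (cm^2)
#' @export
setGeneric("predictionErrorVariance",
           function(x) standardGeneric("predictionErrorVariance"))

#' Variance components of a fitted model
#' @param x a ModelFit
#' @return named numeric: sigma2_a, sigma2_e, h2
#' @export
setGeneric("varianceComponents",
           function(x) standardGeneric("varianceComponents"))

#' Fixed-effect estimates of a fitted model
#' @param x a ModelFit
#' @return named numeric (intercept and age-class contrasts, cm)
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' Association results table
#' @param x a GwasResult
#' @return data.frame, one row per tested SNP
#' @export
setGeneric("gwasTable", function(x) standardGeneric("gwasTable"))

#' @rdname animalIds
setMethod("animalIds", "Pedigree", function(x) x@records$animal)
#' @rdname animalIds
setMethod("animalIds", "GenotypeMatrix", function(x) rownames(x@calls))
#' @rdname animalIds
setMethod("animalIds", "RelationshipMatrix", function(x) x@ids)
#' @rdname animalIds
setMethod("animalIds", "ModelFit", function(x) names(x@a))

#' @rdname nAnimals
setMethod("nAnimals", "Pedigree", function(x) nrow(x@records))
#' @rdname nAnimals
setMethod("nAnimals", "GenotypeMatrix", function(x) nrow(x@calls))

#' @rdname pedRecords
setMethod("pedRecords", "Pedigree", function(x) x@records)

#' @rdname calls
setMethod("calls", "GenotypeMatrix", function(x) x@calls)
#' @rdname markerMap
setMethod("markerMap", "GenotypeMatrix", function(x) x@map)

#' @rdname relValues
setMethod("relValues", "RelationshipMatrix", function(x) x@values)
#' @rdname relKind
setMethod("relKind", "RelationshipMatrix", function(x) x@kind)

#' @rdname breedingValues
setMethod("breedingValues", "ModelFit", function(x) x@a)
#' @rdname predictionErrorVariance
setMethod("predictionErrorVariance", "ModelFit", function(x) x@pev)
#' @rdname varianceComponents
setMethod("varianceComponents", "ModelFit", function(x)
  c(sigma2_a = x@sigma2_a, sigma2_e = x@sigma2_e, h2 = x@h2))
#' @rdname fixedEffects
setMethod("fixedEffects", "ModelFit", function(x) x@b)

#' @rdname gwasTable
setMethod("gwasTable", "GwasResult", function(x) x@table)

setMethod("show", "Pedigree", function(object) {
  rec <- object@records
  founders <- sum(rec$sire == UNKNOWN_PARENT & rec$dam == UNKNOWN_PARENT)
  cat(sprintf("Pedigree: %d animals (%d founders), %d breed(s)\n",
              nrow(rec), founders, length(unique(rec$breed))))
  tb <- table(rec$breed)
  cat("  breeds:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@calls
  miss <- if (length(v)) mean(is.na(v)) else 0
  cat(sprintf("GenotypeMatrix: %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(v), ncol(v), length(unique(object@map$chrom)), 100 * miss))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix[%s]: %d x %d\n", object@kind,
              length(object@ids), length(object@ids)))
  if (object@kind %in% c("A", "G", "H", "A22") && length(object@ids))
    cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
                mean(diag(object@values)),
                (sum(object@values) - sum(diag(object@values))) /
                  max(1, length(object@ids)^2 - length(object@ids))))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit: %d animals; sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
              length(object@a), object@sigma2_a, object@sigma2_e, object@h2))
  if (!is.null(object@diagnostics$method))
    cat("  method:", object@diagnostics$method, "\n")
})

setMethod("show", "GwasResult", function(object) {
  tb <- object@table
  cat(sprintf("GwasResult: %d SNPs on %d chromosome(s)%s\n", nrow(tb),
              length(unique(tb$chrom)),
              if (isTRUE(object@meta$loco)) " (LOCO)" else ""))
  if (nrow(tb)) {
    top <- tb[which.min(tb$p), ]
    cat(sprintf("  top SNP: %s (chr %d, bp %d), p = %.3g\n",
                top$snp_id, top$chrom, top$bp, top$p))
  }
})
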