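#' Pedigree numerator relationship matrix (A)
#'
#' Tabular method over the topologically ordered pedigree:
#' a(i,i) = 1 + a(s,d)/2 and a(i,j) = (a(j,s) + a(j,d))/2 for earlier j,
#' with unknown parents contributing zero. The diagonal is 1 + F with F the
#' inbreeding coefficient.
#'
#' @param ped a [Pedigree-class]
#' @return a [RelationshipMatrix-class] of kind \code{"A"}
#' @export
numeratorRelationship <- function(ped) {
  rec <- pedRecords(ped)
  n <- nrow(rec)
  idx <- seq_len(n); names(idx) <- rec$animal
  si <- ifelse(rec$sire == UNKNOWN_PARENT, 0L, idx[rec$sire])
  di <- ifelse(rec$dam == UNKNOWN_PARENT, 0L, idx[rec$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(rec$animal, rec$animal)
  new("RelationshipMatrix", kind = "A", ids = rec$animal, values = A,
      meta = list())
}

#' Inbreeding coefficients from a pedigree
#' @param ped a [Pedigree-class]
#' @return named numeric vector F (diag(A) - 1)
#' @export
inbreedingCoefficients <- function(ped) {
  A <- relValues(numeratorRelationship(ped))
  diag(A) - 1
}

#' Inverse numerator relationship matrix (Henderson's rules)
#'
#' Direct construction of A^-1 with inbreeding: each animal contributes
#' 1/d_i to the (animal, parent) triplet pattern, where the Mendelian
#' sampling variance d_i is computed from the parents' inbreeding
#' coefficients (0.5 - 0.25 (F_s + F_d) with both parents known, 0.75 -
#' 0.25 F_p with one, 1 with none).
#'
#' @param ped a [Pedigree-class]
#' @return a [RelationshipMatrix-class] of kind \code{"A_inverse"}
#' @export
aInverse <- function(ped) {
  rec <- pedRecords(ped)
  n <- nrow(rec)
  idx <- seq_len(n); names(idx) <- rec$animal
  si <- ifelse(rec$sire == UNKNOWN_PARENT, 0L, idx[rec$sire])
  di <- ifelse(rec$dam == UNKNOWN_PARENT, 0L, idx[rec$dam])
  Fc <- inbreedingCoefficients(ped)
  Ai <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dd <- 1 - (if (s > 0L) 0.25 * (1 + Fc[s]) else 0) -
              (if (d > 0L) 0.25 * (1 + Fc[d]) else 0)
    al <- 1 / dd
    Ai[i, i] <- Ai[i, i] + al
    for (p in c(s, d)) if (p > 0L) {
      Ai[i, p] <- Ai[i, p] - al / 2
      Ai[p, i] <- Ai[p, i] - al / 2
    }
    for (p in c(s, d)) for (q in c(s, d)) if (p > 0L && q > 0L)
      Ai[p, q] <- Ai[p, q] + al / 4
  }
  dimnames(Ai) <- list(rec$animal, rec$animal)
  new("RelationshipMatrix", kind = "A_inverse", ids = rec$animal,
      values = Ai, meta = list())
}

#' Subset a relationship matrix to the genotyped animals (A22)
#' @param A a [RelationshipMatrix-class] of kind \code{"A"}
#' @param ids animal ids of the genotyped subset; returned in the order they
#'   appear in \code{A} (pedigree order)
#' @return a [RelationshipMatrix-class] of kind \code{"A22"}
#' @export
a22Matrix <- function(A, ids) {
  stopifnot(relKind(A) == "A")
  missing_ids <- setdiff(ids, animalIds(A))
  if (length(missing_ids))
    stop("ids absent from A: ", paste(head(missing_ids, 5), collapse = ", "))
  keep <- animalIds(A)[animalIds(A) %in% ids]
  new("RelationshipMatrix", kind = "A22", ids = keep,
      values = relValues(A)[keep, keep, drop = FALSE], meta = list())
}

#' Observed allele-B frequencies
#' @param G a [GenotypeMatrix-class]
#' @param animals optional subset of animal ids
#' @return named numeric vector of per-marker allele-B frequencies
#' @export
alleleFreqs <- function(G, animals = NULL) {
  v <- calls(G)
  if (!is.null(animals)) v <- v[animals, , drop = FALSE]
  setNames(colMeans(v, na.rm = TRUE) / 2, markerMap(G)$snp_id)
}

#' Realized genomic relationship matrix (G)
#'
#' VanRaden method 1: dosages centred by twice the allele frequency,
#' G = ZZ' / (2 * sum p (1 - p)). Frequencies come from the genotyped
#' sample unless supplied. Requires a complete (imputed) matrix and no
#' monomorphic markers.
#'
#' @param G a [GenotypeMatrix-class] with no missing calls
#' @param freq_source \code{"observed"} or \code{"supplied"}
#' @param freqs allele-B frequencies when \code{freq_source = "supplied"}
#' @return a [RelationshipMatrix-class] of kind \code{"G"}
#' @export
genomicRelationship <- function(G, freq_source = c("observed", "supplied"),
                                freqs = NULL) {
  freq_source <- match.arg(freq_source)
  v <- calls(G)
  if (anyNA(v)) stop("missing calls present; run imputeMissing() first")
  p <- if (freq_source == "observed") colMeans(v) / 2 else {
    if (is.null(freqs) || length(freqs) != ncol(v))
      stop("freqs must be supplied with one value per marker")
    as.numeric(freqs)
  }
  if (any(p <= 0 | p >= 1))
    stop("monomorphic marker(s) present (frequency 0 or 1); QC should have removed them")
  Z <- sweep(v, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  Gm <- tcrossprod(Z) / denom
  dimnames(Gm) <- list(rownames(v), rownames(v))
  new("RelationshipMatrix", kind = "G", ids = rownames(v), values = Gm,
      meta = list(method = "VanRaden1", freq_source = freq_source,
                  n_markers = ncol(v)))
}

#' Blend G with A22 for invertibility
#'
#' G* = w G + (1 - w) A22. Any w < 1 makes the blend positive definite when
#' A22 is.
#'
#' @param Graw a [RelationshipMatrix-class] of kind \code{"G"}
#' @param A22 a [RelationshipMatrix-class] of kind \code{"A22"} over the
#'   same animals in the same order
#' @param weight blend weight w in (0, 1], default 0.95
#' @return a [RelationshipMatrix-class] of kind \code{"G"}
#' @export
blendG <- function(Graw, A22, weight = 0.95) {
  if (weight <= 0 || weight > 1) stop("weight must lie in (0, 1]")
  if (!identical(animalIds(Graw), animalIds(A22)))
    stop("Graw and A22 must index the same animals in the same order")
  if (weight == 1) return(Graw)
  v <- weight * relValues(Graw) + (1 - weight) * relValues(A22)
  new("RelationshipMatrix", kind = "G", ids = animalIds(Graw), values = v,
      meta = c(Graw@meta, list(blend_weight = weight)))
}

invertRel <- function(R) {
  v <- relValues(R)
  vi <- tryCatch(chol2inv(chol(v)), error = function(e)
    stop(relKind(R), " is not positive definite (min eigenvalue ",
         signif(min(eigen(v, symmetric = TRUE, only.values = TRUE)$values), 3),
         ")"))
  dimnames(vi) <- dimnames(v)
  vi
}

#' Inverse of the combined relationship matrix (single-step form)
#'
#' H^-1 = A^-1 + blockdiag(0, G^-1 - A22^-1) with the correction placed on
#' the genotyped block.
#'
#' @param Ainv a [RelationshipMatrix-class] of kind \code{"A_inverse"} over
#'   the full pedigree
#' @param Ginv inverse of the (blended) genomic relationship matrix: either
#'   a kind-\code{"G"} matrix (inverted here) or a plain matrix with ids as
#'   dimnames
#' @param A22inv inverse of A22, same convention
#' @return a [RelationshipMatrix-class] of kind \code{"H_inverse"}
#' @export
hInverse <- function(Ainv, Ginv = NULL, A22inv = NULL) {
  stopifnot(relKind(Ainv) == "A_inverse")
  if (is.null(Ginv) || (is.matrix(Ginv) && nrow(Ginv) == 0L)) {
    # no genotyped animals: the correction block is empty
    return(new("RelationshipMatrix", kind = "H_inverse",
               ids = animalIds(Ainv), values = relValues(Ainv),
               meta = list(n_genotyped = 0L)))
  }
  asInv <- function(x, what) {
    if (is(x, "RelationshipMatrix")) {
      list(v = invertRel(x), ids = animalIds(x))
    } else {
      if (is.null(rownames(x))) stop(what, " needs animal ids as dimnames")
      list(v = x, ids = rownames(x))
    }
  }
  gi <- asInv(Ginv, "Ginv"); ai <- asInv(A22inv, "A22inv")
  if (!identical(gi$ids, ai$ids))
    stop("Ginv and A22inv must index the same genotyped animals in the same order")
  if (!all(gi$ids %in% animalIds(Ainv)))
    stop("genotyped animals missing from the pedigree A inverse")
  Hi <- relValues(Ainv)
  pos <- match(gi$ids, animalIds(Ainv))
  Hi[pos, pos] <- Hi[pos, pos] + (gi$v - ai$v)
  new("RelationshipMatrix", kind = "H_inverse", ids = animalIds(Ainv),
      values = Hi, meta = list(n_genotyped = length(pos)))
}

#' Combined relationship matrix H and its Cholesky factor
#'
#' Assembles H in the standard block form over the pedigree order:
#' H11 = A11 + A12 A22^-1 (G - A22) A22^-1 A21, H12 = A12 A22^-1 G,
#' H22 = G (indices 1 = non-genotyped, 2 = genotyped). The Cholesky factor
#' is lower triangular with L L' = H; if the factorisation fails, a single
#' diagonal jitter of 1e-8 is added (recorded in \code{meta} and messaged),
#' and failure after that is an error reporting the minimum eigenvalue.
#'
#' @param A a [RelationshipMatrix-class] of kind \code{"A"} (full pedigree)
#' @param G a blended, positive definite [RelationshipMatrix-class] of kind
#'   \code{"G"} whose ids are a subset of A's
#' @return list with elements \code{H} (kind \code{"H"}) and \code{L}
#'   (kind \code{"H_cholesky"}), both indexed in pedigree order
#' @export
hMatrix <- function(A, G) {
  stopifnot(relKind(A) == "A", relKind(G) == "G")
  ids <- animalIds(A)
  g_ids <- animalIds(G)
  if (!all(g_ids %in% ids)) stop("genotyped animals missing from A")
  Av <- relValues(A)
  pos2 <- match(g_ids, ids)
  pos1 <- setdiff(seq_along(ids), pos2)
  Gv <- relValues(G)
  H <- Av
  if (length(pos2)) {
    A22 <- Av[pos2, pos2, drop = FALSE]
    A22i <- chol2inv(chol(A22))
    if (length(pos1)) {
      A12 <- Av[pos1, pos2, drop = FALSE]
      B <- A12 %*% A22i                      # A12 A22^-1
      H[pos1, pos1] <- Av[pos1, pos1] + B %*% (Gv - A22) %*% t(B)
      H12 <- B %*% Gv
      H[pos1, pos2] <- H12
      H[pos2, pos1] <- t(H12)
    }
    H[pos2, pos2] <- Gv
  }
  H <- (H + t(H)) / 2
  jitter <- 0
  L <- tryCatch(t(chol(H)), error = function(e) NULL)
  if (is.null(L)) {
    jitter <- 1e-8
    message("hMatrix: adding diagonal jitter 1e-8 before Cholesky")
    L <- tryCatch(t(chol(H + jitter * diag(nrow(H)))), error = function(e) {
      ev <- min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
      stop("H is not positive definite even after jitter (min eigenvalue ",
           signif(ev, 3), ")")
    })
  }
  dimnames(L) <- dimnames(H)
  list(H = new("RelationshipMatrix", kind = "H", ids = ids, values = H,
               meta = list(n_genotyped = length(pos2), jitter = jitter)),
       L = new("RelationshipMatrix", kind = "H_cholesky", ids = ids,
               values = L,
               meta = list(n_genotyped = length(pos2), jitter = jitter)))
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of G; scores are eigenvectors scaled by the square
#' root of their eigenvalue, and variance-explained fractions are
#' eigenvalues over the summed positive eigenvalues (negative eigenvalues
#' are floored at zero for the denominator).
#'
#' @param G a [RelationshipMatrix-class] (kind \code{"G"} or \code{"H"})
#' @param n_components number of components to return
#' @return list: \code{scores} (animals x components), \code{varfrac}
#'   (variance-explained fractions), \code{values} (all eigenvalues)
#' @export
grmPCA <- function(G, n_components = 2L) {
  v <- relValues(G)
  e <- eigen(v, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  rank <- sum(pos > 1e-10 * max(pos))
  if (n_components > rank) {
    warning("n_components exceeds rank ", rank, "; truncated")
    n_components <- rank
  }
  k <- seq_len(n_components)
  scores <- e$vectors[, k, drop = FALSE] %*% diag(sqrt(pos[k]), n_components)
  rownames(scores) <- animalIds(G)
  colnames(scores) <- paste0("PC", k)
  list(scores = scores, varfrac = pos[k] / sum(pos), values = e$values)
}

#' Linkage disequilibrium between two markers
#'
#' Composite LD: squared Pearson correlation of genotype dosages (no
#' phasing), clipped to [0, 1].
#'
#' @param G a [GenotypeMatrix-class]
#' @param snp_a,snp_b SNP ids
#' @param animals optional subset of animal ids
#' @return r^2 in [0,1], or NA (with a warning) if either marker is
#'   monomorphic in the evaluated subset
#' @export
ldR2 <- function(G, snp_a, snp_b, animals = NULL) {
  v <- calls(G)
  if (!is.null(animals)) v <- v[animals, , drop = FALSE]
  for (s in c(snp_a, snp_b))
    if (!(s %in% colnames(v))) stop("unknown SNP id: ", s)
  x <- v[, snp_a]; y <- v[, snp_b]
  ok <- !is.na(x) & !is.na(y)
  if (var(x[ok]) == 0 || var(y[ok]) == 0) {
    warning("monomorphic marker in the evaluated subset; LD undefined")
    return(NA_real_)
  }
  min(1, max(0, cor(x[ok], y[ok])^2))
}
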