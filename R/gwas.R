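#' Leave-one-chromosome-out genomic relationship matrices
#'
#' For each chromosome c, a VanRaden method-1 GRM built from all markers
#' except those on c, so the tested chromosome never contributes to its own
#' background kinship. Computed by subtracting each chromosome's
#' cross-product from the genome-wide one.
#'
#' @param G a [GenotypeMatrix-class] with no missing calls
#' @return named list (one entry per chromosome present) of
#'   [RelationshipMatrix-class] objects; each \code{meta} records the
#'   excluded chromosome and the marker count used
#' @export
locoGrms <- function(G) {
  v <- calls(G); map <- markerMap(G)
  if (anyNA(v)) stop("missing calls present; run imputeMissing() first")
  p <- colMeans(v) / 2
  if (any(p <= 0 | p >= 1)) stop("monomorphic marker(s) present; run qcFilter() first")
  Z <- sweep(v, 2L, 2 * p)
  full_cp <- tcrossprod(Z)
  het <- 2 * p * (1 - p)
  chroms <- sort(unique(map$chrom))
  out <- lapply(chroms, function(ch) {
    on_c <- map$chrom == ch
    cp <- full_cp - tcrossprod(Z[, on_c, drop = FALSE])
    denom <- sum(het[!on_c])
    Gm <- cp / denom
    dimnames(Gm) <- list(rownames(v), rownames(v))
    new("RelationshipMatrix", kind = "G", ids = rownames(v), values = Gm,
        meta = list(method = "VanRaden1", excluded_chrom = ch,
                    n_markers = sum(!on_c)))
  })
  names(out) <- as.character(chroms)
  out
}

# restricted log-likelihood of the variance ratio gamma = sigma2_g/sigma2_e
# on the rotated model; returns the profile pieces
.remlProfile <- function(gamma, s, ty, tX) {
  n <- length(ty); p <- ncol(tX)
  w <- 1 / (gamma * s + 1)
  XtWX <- crossprod(tX, tX * w)
  XtWy <- crossprod(tX, ty * w)
  b <- solve(XtWX, XtWy)
  r <- ty - tX %*% b
  rss <- sum(w * r^2)
  sigma2_e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma2_e) + sum(log(gamma * s + 1)) +
                  determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  list(ll = as.numeric(ll), sigma2_e = sigma2_e, b = b)
}

#' REML variance components on a relationship matrix
#'
#' Restricted maximum likelihood for y = Xb + g + e with Var(g) = K
#' sigma2_g, using one spectral decomposition of K and a one-dimensional
#' search over the variance ratio (residual variance profiled out).
#'
#' @param y phenotype vector
#' @param X fixed-effect design (intercept prepended if missing)
#' @param K a [RelationshipMatrix-class] (e.g. one entry of [locoGrms()]) or
#'   a plain symmetric matrix
#' @param eig optional precomputed \code{eigen(K, symmetric = TRUE)} to
#'   reuse across calls
#' @return list: \code{sigma2_g}, \code{sigma2_e}, \code{h2},
#'   \code{boundary} (TRUE when the ratio estimate sits at the search
#'   boundary), \code{loglik}, \code{eig} (the decomposition, for reuse)
#' @export
locoReml <- function(y, X = NULL, K, eig = NULL) {
  Kv <- if (is(K, "RelationshipMatrix")) relValues(K) else as.matrix(K)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (is.null(eig)) eig <- eigen(Kv, symmetric = TRUE)
  s <- pmax(eig$values, 0)
  ty <- crossprod(eig$vectors, y)
  tX <- crossprod(eig$vectors, X)
  f <- function(lg) .remlProfile(exp(lg), s, ty, tX)$ll
  opt <- optimize(f, c(-12, 12), maximum = TRUE, tol = 1e-7)
  gamma <- exp(opt$maximum)
  prof <- .remlProfile(gamma, s, ty, tX)
  boundary <- opt$maximum < -11.5 || opt$maximum > 11.5
  sigma2_e <- prof$sigma2_e
  sigma2_g <- gamma * sigma2_e
  list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
       h2 = sigma2_g / (sigma2_g + sigma2_e),
       boundary = boundary, loglik = prof$ll, eig = eig)
}

#' Genome-wide Bonferroni significance thresholds
#'
#' @param n_tests number of tested SNPs
#' @return list: \code{p05}, \code{p01} (Bonferroni-corrected per-test
#'   p-value thresholds 0.05/n and 0.01/n) and their \code{minus_log10}
#'   counterparts
#' @export
significanceThresholds <- function(n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  p05 <- 0.05 / n_tests; p01 <- 0.01 / n_tests
  list(p05 = p05, p01 = p01,
       minus_log10 = c(p05 = -log10(p05), p01 = -log10(p01)))
}

#' Mixed-linear-model association scan with LOCO kinship
#'
#' Per SNP on chromosome c, a generalized-least-squares Wald test of the
#' SNP dosage effect in y = Xb + beta SNP + g + e with Var(g) =
#' sigma2_g G_loco(c), the variance components estimated once per left-out
#' chromosome by [locoReml()] and then held fixed for the SNPs on it. The
#' model is rotated once per chromosome by the eigenvectors of its LOCO
#' GRM, so each SNP test is a weighted regression. Conditioning SNPs are
#' appended to the fixed effects (and excluded from testing); monomorphic
#' SNPs are skipped and listed in \code{meta$skipped}.
#'
#' @param y phenotype vector aligned with the rows of \code{genotypes}
#' @param X fixed-effect design (intercept prepended if NULL)
#' @param genotypes a [GenotypeMatrix-class] for the tested cohort, no
#'   missing calls
#' @param loco optional precomputed [locoGrms()] list; by default each LOCO
#'   GRM is built on the fly and discarded (memory stays at one GRM)
#' @param conditioning character vector of SNP ids to condition on
#' @param chromosomes chromosomes to scan (default: all); the Bonferroni
#'   thresholds in \code{meta} always count the tested SNPs of the scan
#' @return a [GwasResult-class]
#' @export
mlmaLoco <- function(y, X = NULL, genotypes, loco = NULL,
                     conditioning = NULL, chromosomes = NULL) {
  v <- calls(genotypes); map <- markerMap(genotypes)
  if (anyNA(v)) stop("missing calls present; run imputeMissing() first")
  n <- length(y)
  if (nrow(v) != n) stop("genotypes and phenotypes are misaligned")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(conditioning)) {
    absent <- setdiff(conditioning, map$snp_id)
    if (length(absent))
      stop("conditioning SNP(s) absent from the marker set: ",
           paste(absent, collapse = ", "))
    X <- cbind(X, v[, conditioning, drop = FALSE])
  }
  p_all <- colMeans(v) / 2
  mono <- p_all <= 0 | p_all >= 1
  if (is.null(loco)) {
    if (any(mono[!(map$snp_id %in% conditioning)]))
      stop("monomorphic marker(s) present; run qcFilter() first")
    Zc <- sweep(v, 2L, 2 * p_all)
    full_cp <- tcrossprod(Zc)
    het <- 2 * p_all * (1 - p_all)
  }
  chroms <- sort(unique(map$chrom))
  if (!is.null(chromosomes)) chroms <- intersect(chroms, chromosomes)
  varcomp <- list()
  rows <- list()
  for (ch in chroms) {
    test_j <- which(map$chrom == ch & !mono &
                      !(map$snp_id %in% conditioning))
    if (!is.null(loco)) {
      K <- loco[[as.character(ch)]]
      if (is.null(K)) stop("no LOCO GRM for chromosome ", ch)
    } else {
      on_c <- map$chrom == ch
      K <- (full_cp - tcrossprod(Zc[, on_c, drop = FALSE])) /
        sum(het[!on_c])
    }
    vc <- locoReml(y, X, K)
    varcomp[[as.character(ch)]] <- vc[c("sigma2_g", "sigma2_e", "h2",
                                        "boundary")]
    if (!length(test_j)) next
    U <- vc$eig$vectors
    s <- pmax(vc$eig$values, 0)
    w <- 1 / (vc$sigma2_g * s + vc$sigma2_e)
    ty <- crossprod(U, y)
    tX <- crossprod(U, X)
    tS <- crossprod(U, v[, test_j, drop = FALSE])
    WX <- tX * w
    XtWX_inv <- solve(crossprod(tX, WX))
    # projection P = W - WX (X'WX)^-1 X'W applied to y and each SNP column
    Py <- as.vector(w * ty - WX %*% (XtWX_inv %*% crossprod(WX, ty)))
    XtWS <- crossprod(WX, tS)
    PS <- tS * w - WX %*% (XtWX_inv %*% XtWS)
    denom <- colSums(tS * PS)
    num <- as.vector(crossprod(tS, Py))
    beta <- num / denom
    se <- sqrt(1 / denom)
    chi2 <- beta^2 * denom
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    rows[[as.character(ch)]] <- data.frame(
      chrom = map$chrom[test_j], snp_id = map$snp_id[test_j],
      bp = map$bp[test_j], alleleB = map$alleleB[test_j],
      freq = p_all[test_j], beta = beta, se = se, chi2 = chi2,
      p = pmax(p, .Machine$double.xmin),
      stringsAsFactors = FALSE)
  }
  tb <- do.call(rbind, rows)
  if (is.null(tb)) tb <- data.frame(chrom = integer(0), snp_id = character(0),
                                    bp = integer(0), alleleB = character(0),
                                    freq = numeric(0), beta = numeric(0),
                                    se = numeric(0), chi2 = numeric(0),
                                    p = numeric(0))
  tb <- tb[order(tb$chrom, tb$bp), , drop = FALSE]
  rownames(tb) <- NULL
  tb$minus_log10_p <- -log10(tb$p)
  new("GwasResult", table = tb,
      meta = list(loco = TRUE, conditioning = conditioning,
                  varcomp = varcomp,
                  thresholds = significanceThresholds(max(1L, nrow(tb))),
                  skipped = map$snp_id[mono]))
}

#' Partition phenotypic variance onto GRM components
#'
#' Haseman-Elston regression: phenotypes are adjusted for the fixed effects
#' by ordinary least squares, and the off-diagonal cross-products of the
#' adjusted values are regressed on the stacked GRM entries, giving each
#' component's variance and its share of the (adjusted) phenotypic
#' variance. Standard errors come from a delete-group jackknife over
#' animals.
#'
#' @param y phenotype vector
#' @param X fixed-effect design (intercept prepended if NULL)
#' @param components named list of [RelationshipMatrix-class] objects built
#'   from disjoint marker sets
#' @param n_jackknife number of jackknife groups (default 30)
#' @return data.frame, one row per component: \code{variance},
#'   \code{share} (of adjusted phenotypic variance) and \code{share_se}
#' @export
partitionVariance <- function(y, X = NULL, components, n_jackknife = 30L) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  k <- length(components)
  if (k < 1) stop("at least one component is required")
  if (is.null(names(components)))
    names(components) <- paste0("component", seq_len(k))
  e <- stats::lm.fit(X, y)$residuals
  vp <- sum(e^2) / (n - ncol(X))
  lt <- lower.tri(matrix(0, n, n))
  cp <- tcrossprod(e)[lt]
  D <- vapply(components, function(K) {
    Kv <- if (is(K, "RelationshipMatrix")) relValues(K) else as.matrix(K)
    if (!all(dim(Kv) == n)) stop("component dimension does not match y")
    Kv[lt]
  }, numeric(sum(lt)))
  if (k > 1) {
    cc <- cor(D)
    if (any(cc[upper.tri(cc)] > 0.99999))
      stop("collinear components (effectively identical GRMs)")
  }
  fit <- stats::lm.fit(cbind(1, D), cp)
  est <- fit$coefficients[-1L]

  pair_idx <- which(lt, arr.ind = TRUE)
  groups <- rep(seq_len(n_jackknife), length.out = n)  # deterministic blocks
  theta <- matrix(0, n_jackknife, k)
  for (g in seq_len(n_jackknife)) {
    drop_an <- which(groups == g)
    keep <- !(pair_idx[, 1] %in% drop_an | pair_idx[, 2] %in% drop_an)
    theta[g, ] <- stats::lm.fit(cbind(1, D[keep, , drop = FALSE]),
                                cp[keep])$coefficients[-1L]
  }
  jk_se <- sqrt((n_jackknife - 1) / n_jackknife *
                  colSums(sweep(theta, 2L, colMeans(theta))^2))
  data.frame(component = names(components),
             variance = as.numeric(est),
             share = as.numeric(est) / vp,
             share_se = jk_se / vp,
             stringsAsFactors = FALSE)
}

#' GRM from an explicit marker subset
#'
#' Convenience for variance partitioning: VanRaden method-1 GRM restricted
#' to the given SNP ids.
#'
#' @param G a [GenotypeMatrix-class] with no missing calls
#' @param snp_ids markers to use
#' @return a [RelationshipMatrix-class] of kind \code{"G"}
#' @export
grmFromMarkers <- function(G, snp_ids) {
  map <- markerMap(G)
  absent <- setdiff(snp_ids, map$snp_id)
  if (length(absent)) stop("unknown SNP id(s): ", paste(absent, collapse = ", "))
  keep <- map$snp_id %in% snp_ids
  sub <- new("GenotypeMatrix", calls = calls(G)[, keep, drop = FALSE],
             map = { mm <- map[keep, , drop = FALSE]; rownames(mm) <- NULL; mm })
  genomicRelationship(sub)
}
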