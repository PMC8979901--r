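#' Design matrices for the single-step animal model
#'
#' Builds y = Xb + Za + e with X = intercept + age-class indicators (class 1
#' is the reference; a class absent from the data loses its column with a
#' warning) and Z mapping phenotype records to pedigree animals. The
#' transformed design Fa = Z L (rows of the H Cholesky factor for the
#' phenotyped animals) makes the random animal effects independent.
#'
#' @param phenos phenotype data.frame as from [readPhenotypes()] /
#'   [simulatePhenotypes()]
#' @param ped a [Pedigree-class]
#' @param Hchol a [RelationshipMatrix-class] of kind \code{"H_cholesky"}
#'   indexed by the full pedigree (use the A Cholesky factor for classical
#'   pedigree BLUP)
#' @return list: \code{y}, \code{X}, \code{z_index} (pedigree position per
#'   record), \code{Z} (dense indicator matrix), \code{Fa}, \code{ids}
#'   (pedigree animal ids), \code{record_ids}
#' @export
buildDesign <- function(phenos, ped, Hchol) {
  if (!nrow(phenos)) stop("empty phenotype set")
  rec <- pedRecords(ped)
  if (!all(phenos$animal_id %in% rec$animal))
    stop("phenotyped animals absent from pedigree: ",
         paste(setdiff(phenos$animal_id, rec$animal), collapse = ", "))
  if (!identical(animalIds(Hchol), rec$animal))
    stop("Hchol index must equal the pedigree animal order")
  # pedigree-consistent record order
  phenos <- phenos[order(match(phenos$animal_id, rec$animal)), , drop = FALSE]
  n <- nrow(phenos)
  y <- phenos$height
  classes <- 2:5
  present <- classes[classes %in% unique(phenos$age_class)]
  if (length(present) < length(classes))
    warning("age class(es) absent from data: ",
            paste(setdiff(classes, present), collapse = ", "),
            "; column(s) dropped")
  X <- cbind(intercept = rep(1, n))
  for (cl in present)
    X <- cbind(X, as.numeric(phenos$age_class == cl))
  colnames(X) <- c("intercept",
                   if (length(present)) paste0("age_class", present))
  zi <- match(phenos$animal_id, rec$animal)
  N <- nrow(rec)
  Z <- matrix(0, n, N, dimnames = list(phenos$animal_id, rec$animal))
  Z[cbind(seq_len(n), zi)] <- 1
  Fa <- relValues(Hchol)[zi, , drop = FALSE]
  rownames(Fa) <- phenos$animal_id
  list(y = y, X = X, z_index = zi, Z = Z, Fa = Fa, ids = rec$animal,
       record_ids = phenos$animal_id)
}

#' Gibbs sampler for the transformed single-step model
#'
#' Samples fixed effects, transformed animal effects c_a, and the two
#' variance components in y = Xb + Fa c_a + e with c_a ~ N(0, I sigma2_a),
#' using single-site conjugate updates; each stored sample is
#' back-transformed to breeding values a = L c_a, whose posterior mean and
#' variance give the GEBVs and their prediction error variances. Variance
#' components get scaled-inverse-chi-square priors (default df 5 with the
#' scale set from an even split of the phenotypic variance); pass
#' \code{sigma2_a} / \code{sigma2_e} to hold either fixed (degenerate
#' prior). Deterministic given \code{seed}.
#'
#' @param design output of [buildDesign()]
#' @param n_iter,burn_in,thin chain settings (defaults 30000 / 5000 / 5)
#' @param seed integer seed
#' @param priors list with elements \code{df_a}, \code{df_e} (both default
#'   5) and optional \code{S_a}, \code{S_e} scale overrides
#' @param sigma2_a,sigma2_e optional fixed values for the variance
#'   components
#' @return a [ModelFit-class]
#' @export
fitGibbs <- function(design, n_iter = 30000L, burn_in = 5000L, thin = 5L,
                     seed, priors = list(), sigma2_a = NULL,
                     sigma2_e = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  vy <- var(design$y)
  if (vy == 0) vy <- 1e-8
  df_a <- priors$df_a %||% 5
  df_e <- priors$df_e %||% 5
  # prior mean = vy/2 for each component: S = mean * (df - 2) / df
  S_a <- priors$S_a %||% (0.5 * vy * (df_a - 2) / df_a)
  S_e <- priors$S_e %||% (0.5 * vy * (df_e - 2) / df_e)
  set.seed(as.integer(seed))
  # the full Cholesky factor is needed for the back-transform a = L c_a
  L <- attr(design, "L")
  if (is.null(L)) stop("design must carry the Cholesky factor; use fitSingleStep() or attach attr(design, 'L')")
  # Rotate c_a by the eigenvectors of Fa'Fa: the rotated coordinates have a
  # diagonal conditional precision, so one single-site sweep is an exact
  # joint draw and the chain mixes essentially independently. The prior
  # c_a ~ N(0, I sigma2_a) is rotation-invariant and a = (L V) c_a'.
  V <- eigen(crossprod(design$Fa), symmetric = TRUE)$vectors
  Wstar <- design$Fa %*% V
  Lstar <- L %*% V
  res <- .gibbs_ssgblup(design$y, design$X, Wstar, Lstar,
                        as.integer(n_iter), as.integer(burn_in),
                        as.integer(thin), df_a, S_a, df_e, S_e,
                        if (is.null(sigma2_a)) -1 else sigma2_a,
                        if (is.null(sigma2_e)) -1 else sigma2_e,
                        0.5 * vy, 0.5 * vy)
  a <- setNames(as.numeric(res$a$mean), design$ids)
  pev <- setNames(as.numeric(res$a$var), design$ids)
  s2a <- if (is.null(sigma2_a)) res$sigma2_a[["mean"]] else sigma2_a
  s2e <- if (is.null(sigma2_e)) res$sigma2_e[["mean"]] else sigma2_e
  new("ModelFit",
      b = setNames(as.numeric(res$b$mean), colnames(design$X)),
      a = a, pev = pev, sigma2_a = s2a, sigma2_e = s2e,
      h2 = s2a / (s2a + s2e),
      se = list(b = setNames(sqrt(as.numeric(res$b$var)), colnames(design$X)),
                a = sqrt(pev),
                sigma2_a = res$sigma2_a[["sd"]],
                sigma2_e = res$sigma2_e[["sd"]],
                h2 = res$h2[["sd"]]),
      diagnostics = list(method = "gibbs", n_iter = n_iter,
                         burn_in = burn_in, thin = thin,
                         n_saved = res$n_saved, seed = seed,
                         h2_posterior_mean = res$h2[["mean"]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call single-step fit
#'
#' Convenience wrapper: builds H (or uses A when no genotyped animals are
#' given), its Cholesky factor, the design matrices, and runs the Gibbs
#' sampler.
#'
#' @param phenos phenotype data.frame
#' @param ped a [Pedigree-class]
#' @param G optional blended [RelationshipMatrix-class] of kind \code{"G"};
#'   \code{NULL} fits classical pedigree BLUP (H = A)
#' @param ... passed to [fitGibbs()] (chain settings, seed, priors)
#' @return a [ModelFit-class]
#' @export
fitSingleStep <- function(phenos, ped, G = NULL, ...) {
  A <- numeratorRelationship(ped)
  if (is.null(G)) {
    Hv <- relValues(A)
    L <- t(chol(Hv))
    dimnames(L) <- dimnames(Hv)
    Lrel <- new("RelationshipMatrix", kind = "H_cholesky", ids = animalIds(A),
                values = L, meta = list(n_genotyped = 0L, jitter = 0))
  } else {
    Lrel <- hMatrix(A, G)$L
  }
  design <- buildDesign(phenos, ped, Lrel)
  attr(design, "L") <- relValues(Lrel)
  fitGibbs(design, ...)
}

#' Solve Henderson's mixed-model equations
#'
#' Deterministic BLUP at fixed variance components: solves
#' [X'X, X'Z; Z'X, Z'Z + Kinv lambda] [b; a] = [X'y; Z'y] with
#' lambda = sigma2_e / sigma2_a, and reports per-animal prediction error
#' variances from the diagonal of the inverted coefficient matrix times
#' sigma2_e. With K = A this is the classical pedigree BLUP comparator;
#' with K = H it is the deterministic cross-check of the sampler.
#'
#' @param y phenotype vector
#' @param X fixed-effect design matrix
#' @param Z records x animals incidence matrix
#' @param Kinv inverse relationship matrix: a [RelationshipMatrix-class] of
#'   kind \code{"A_inverse"} / \code{"H_inverse"}, or a plain matrix
#' @param sigma2_a,sigma2_e positive variance components
#' @return list: \code{b}, \code{a}, \code{pev}
#' @export
solveMME <- function(y, X, Z, Kinv, sigma2_a, sigma2_e) {
  if (sigma2_a <= 0 || sigma2_e <= 0) stop("variance components must be positive")
  Ki <- if (is(Kinv, "RelationshipMatrix")) relValues(Kinv) else as.matrix(Kinv)
  lambda <- sigma2_e / sigma2_a
  p <- ncol(X); N <- ncol(Z)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ki))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular mixed-model equations (confounded fixed effects or ",
         "disconnected design): ", conditionMessage(e)))
  sol <- Ci %*% rhs
  b <- setNames(sol[seq_len(p)], colnames(X))
  a <- setNames(sol[p + seq_len(N)], colnames(Z))
  pev <- setNames(diag(Ci)[p + seq_len(N)] * sigma2_e, colnames(Z))
  list(b = b, a = a, pev = pev)
}

#' Deterministic single-step fit via the mixed-model equations
#'
#' Convenience wrapper around [solveMME()] producing a [ModelFit-class] at
#' fixed variance components.
#'
#' @param phenos phenotype data.frame
#' @param ped a [Pedigree-class]
#' @param G optional blended genomic relationship matrix; \code{NULL} for
#'   pedigree BLUP
#' @param sigma2_a,sigma2_e variance components
#' @return a [ModelFit-class]
#' @export
fitMME <- function(phenos, ped, G = NULL, sigma2_a, sigma2_e) {
  Ainv <- aInverse(ped)
  Kinv <- if (is.null(G)) Ainv else {
    A <- numeratorRelationship(ped)
    A22 <- a22Matrix(A, animalIds(G))
    hInverse(Ainv, G, A22)
  }
  A <- numeratorRelationship(ped)
  L <- t(chol(relValues(A)))  # only for design shape; MME ignores Fa
  dimnames(L) <- dimnames(relValues(A))
  Lrel <- new("RelationshipMatrix", kind = "H_cholesky", ids = animalIds(A),
              values = L, meta = list())
  d <- buildDesign(phenos, ped, Lrel)
  sol <- solveMME(d$y, d$X, d$Z, Kinv, sigma2_a, sigma2_e)
  new("ModelFit", b = sol$b, a = sol$a, pev = pmax(sol$pev, 0),
      sigma2_a = sigma2_a, sigma2_e = sigma2_e,
      h2 = sigma2_a / (sigma2_a + sigma2_e),
      se = list(a = sqrt(pmax(sol$pev, 0))),
      diagnostics = list(method = "mme",
                         kinship = if (is.null(G)) "A" else "H"))
}

#' Breeding-value reliabilities
#'
#' r^2 = 1 - PEV / sigma2_a per animal, clipped to [0, 1]; the number of
#' clipped values is messaged.
#'
#' @param fit a [ModelFit-class]
#' @return named numeric vector of reliabilities in [0, 1]
#' @export
reliabilities <- function(fit) {
  if (fit@sigma2_a <= 0) stop("sigma2_a must be positive")
  pev <- predictionErrorVariance(fit)
  if (!length(pev)) stop("fit carries no prediction error variances")
  r2 <- 1 - pev / fit@sigma2_a
  n_clip <- sum(r2 < 0 | r2 > 1)
  if (n_clip) message(n_clip, " reliability value(s) clipped to [0, 1]")
  setNames(pmin(1, pmax(0, r2)), names(pev))
}
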