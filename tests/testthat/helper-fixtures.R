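# Fixture builders and independent oracles used across the suite.
# Everything here is deliberately written without calling the package's own
# I/O or matrix code paths wherever it serves as an oracle.

# small hand-built pedigree: founders A, B; full sibs C, D; inbred E = C x D
toySibPedigree <- function() {
  Pedigree(data.frame(
    animal = c("A", "B", "C", "D", "E"),
    sire = c("0", "0", "A", "A", "C"),
    dam = c("0", "0", "B", "B", "D"),
    birth_date = as.Date("2000-01-01") + 0:4,
    sex = c("M", "F", "M", "F", "F"),
    breed = "toy"))
}

# random acyclic pedigree, independent of the package simulator: parents are
# always drawn among earlier animals of the right sex (or unknown)
randomPedigree <- function(n, seed, p_founder = 0.25) {
  set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sire <- dam <- rep("0", n)
  for (i in seq_len(n)) {
    if (i > 2 && runif(1) > p_founder) {
      males <- which(sex[seq_len(i - 1)] == "M")
      females <- which(sex[seq_len(i - 1)] == "F")
      if (length(males))
        sire[i] <- paste0("an", males[sample.int(length(males), 1)])
      if (length(females))
        dam[i] <- paste0("an", females[sample.int(length(females), 1)])
    }
  }
  Pedigree(data.frame(animal = paste0("an", seq_len(n)), sire = sire,
                      dam = dam, birth_date = as.Date("1990-01-01") + seq_len(n),
                      sex = sex, breed = "rand"))
}

# random genotype matrix; every marker carries both alleles so text round
# trips are unambiguous
randomGenotypeMatrix <- function(n = 10, m = 50, seed = 1, miss = 0.05,
                                 chroms = 5) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  calls[1, ] <- 1L  # guarantees both alleles observed at every marker
  if (miss > 0) {
    idx <- which(matrix(runif(n * m) < miss, n, m) & row(calls) > 1)
    calls[idx] <- NA_integer_
  }
  rownames(calls) <- paste0("an", seq_len(n))
  per <- ceiling(m / chroms)
  map <- data.frame(snp_id = paste0("s", seq_len(m)),
                    chrom = rep(seq_len(chroms), each = per)[seq_len(m)],
                    bp = rep(seq_len(per) * 1000L, chroms)[seq_len(m)],
                    alleleA = "A", alleleB = "C",
                    stringsAsFactors = FALSE)
  GenotypeMatrix(calls, map)
}

# independent PLINK bed writer (bit packing coded from the format spec, not
# shared with the package reader/writer)
oracleWriteBed <- function(G, prefix) {
  v <- calls(G); map <- markerMap(G)
  n <- nrow(v); m <- ncol(v)
  write.table(data.frame(map$chrom, map$snp_id, 0, map$bp, map$alleleA,
                         map$alleleB),
              paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(1, rownames(v), 0, 0, 0, -9),
              paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  code_of <- function(g) {
    if (is.na(g)) return(c(1L, 0L))        # 01 = missing
    if (g == 0L) return(c(0L, 0L))         # 00 = hom alleleA
    if (g == 1L) return(c(0L, 1L))         # 10 = het (bits little-endian)
    c(1L, 1L)                              # 11 = hom alleleB
  }
  for (j in seq_len(m)) {
    bits <- integer(0)
    for (i in seq_len(n)) bits <- c(bits, code_of(v[i, j]))
    pad <- 8L * ceiling(length(bits) / 8) - length(bits)
    bits <- c(bits, rep(0L, pad))
    bytes <- vapply(seq_len(length(bits) / 8), function(k) {
      b <- bits[(8 * k - 7):(8 * k)]
      sum(b * 2^(0:7))
    }, numeric(1))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

# gene-dropping kinship oracle: Monte-Carlo estimate of 2 x kinship with
# per-pair standard errors, via founder-allele labels dropped down the
# pedigree
geneDropKinship <- function(ped, n_drops, seed, pairs) {
  set.seed(seed)
  rec <- pedRecords(ped)
  n <- nrow(rec)
  idx <- seq_len(n); names(idx) <- rec$animal
  si <- ifelse(rec$sire == "0", 0L, idx[rec$sire])
  di <- ifelse(rec$dam == "0", 0L, idx[rec$dam])
  A1 <- matrix(0L, n, n_drops)
  A2 <- matrix(0L, n, n_drops)
  lab <- 0L
  for (i in seq_len(n)) {
    if (si[i] == 0L) {
      lab <- lab + 1L; A1[i, ] <- lab
    } else {
      pick <- runif(n_drops) < 0.5
      A1[i, ] <- ifelse(pick, A1[si[i], ], A2[si[i], ])
    }
    if (di[i] == 0L) {
      lab <- lab + 1L; A2[i, ] <- lab
    } else {
      pick <- runif(n_drops) < 0.5
      A2[i, ] <- ifelse(pick, A1[di[i], ], A2[di[i], ])
    }
  }
  t(vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i == j) {
      # a(i,i) = 1 + F, F = P(the two alleles of i are IBD)
      ind <- as.numeric(A1[i, ] == A2[i, ])
      c(est = 1 + mean(ind), se = sd(ind) / sqrt(n_drops))
    } else {
      # a(i,j) = 2 x kinship; kinship = mean IBD prob over the 4 allele picks
      sh <- ((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
               (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 4
      c(est = 2 * mean(sh), se = 2 * sd(sh) / sqrt(n_drops))
    }
  }, numeric(2)))
}

# small silhouette computation on a 2-D embedding with known labels
meanSilhouette <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

writeLinesTmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
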