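#' Construct a Pedigree from raw records
#'
#' Normalises unknown-parent codes (\code{NA}, \code{""}, \code{"-"},
#' \code{"0"}) to the internal sentinel, appends implicit founder records for
#' parents that are named but never defined, sorts records topologically and
#' validates the result (acyclicity, parent-sex consistency).
#'
#' @param records data.frame with columns \code{animal}, \code{sire},
#'   \code{dam}, and optionally \code{birth_date}, \code{sex}, \code{breed}.
#' @return a [Pedigree-class]
#' @export
Pedigree <- function(records) {
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  for (cl in c("animal", "sire", "dam"))
    rec[[cl]] <- as.character(rec[[cl]])
  if (is.null(rec$birth_date)) rec$birth_date <- as.Date(NA)
  rec$birth_date <- as.Date(rec$birth_date)
  if (is.null(rec$sex)) rec$sex <- "U"
  rec$sex <- toupper(as.character(rec$sex))
  rec$sex[is.na(rec$sex) | !(rec$sex %in% c("F", "M"))] <- "U"
  if (is.null(rec$breed)) rec$breed <- "unknown"
  rec$breed <- as.character(rec$breed)

  for (p in c("sire", "dam")) {
    v <- rec[[p]]
    v[is.na(v) | v %in% c("", "-", "0", ".", "NA")] <- UNKNOWN_PARENT
    rec[[p]] <- v
  }
  if (anyDuplicated(rec$animal))
    stop("duplicate animal ids: ",
         paste(unique(rec$animal[duplicated(rec$animal)]), collapse = ", "))

  # materialise implicit founders; inherit the offspring's breed label
  for (p in c("sire", "dam")) {
    miss <- setdiff(rec[[p]], c(rec$animal, UNKNOWN_PARENT))
    if (length(miss)) {
      first_breed <- vapply(miss, function(id)
        rec$breed[match(id, rec[[p]])], character(1))
      rec <- rbind(rec, data.frame(
        animal = miss, sire = UNKNOWN_PARENT, dam = UNKNOWN_PARENT,
        birth_date = as.Date(NA),
        sex = if (p == "sire") "M" else "F",
        breed = first_breed, stringsAsFactors = FALSE))
    }
  }
  rec <- topoSortPedigree(rec)
  rownames(rec) <- NULL
  new("Pedigree", records = rec)
}

# Kahn's algorithm over parent->offspring edges; errors naming a cycle member.
topoSortPedigree <- function(rec) {
  n <- nrow(rec)
  idx <- seq_len(n)
  names(idx) <- rec$animal
  si <- ifelse(rec$sire == UNKNOWN_PARENT, NA_integer_, idx[rec$sire])
  di <- ifelse(rec$dam == UNKNOWN_PARENT, NA_integer_, idx[rec$dam])
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in idx) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  # stable order: among available nodes, keep by birth date then input order
  bd <- as.numeric(rec$birth_date)
  bd[is.na(bd)] <- -Inf
  while (length(queue)) {
    queue <- queue[order(bd[queue], queue)]
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order_out) < n) {
    incyc <- rec$animal[setdiff(idx, order_out)]
    stop("pedigree contains a cycle involving animal '", incyc[1L], "'")
  }
  rec[order_out, , drop = FALSE]
}

#' Read a pedigree file
#'
#' Expects a delimited file with a header naming six columns: animal, sire,
#' dam, birth_date (ISO-8601), sex (F/M or empty) and breed. Unknown parents
#' are written as \code{0} (empty and \code{-} are accepted on input).
#'
#' @param path file path
#' @param dialect \code{"csv"} or \code{"tsv"}
#' @return a [Pedigree-class]
#' @export
readPedigree <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  rec <- read.table(path, header = TRUE, sep = if (dialect == "csv") "," else "\t",
                    colClasses = "character", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  need <- c("animal", "sire", "dam", "birth_date", "sex", "breed")
  if (!all(need %in% names(rec)))
    stop("pedigree header must name columns: ", paste(need, collapse = ", "))
  Pedigree(rec[, need])
}

#' Write a pedigree file
#' @param ped a [Pedigree-class]
#' @param path output path
#' @param dialect \code{"csv"} or \code{"tsv"}
#' @return invisibly, \code{path}
#' @export
writePedigree <- function(ped, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  rec <- pedRecords(ped)
  rec$birth_date <- format(rec$birth_date, "%Y-%m-%d")
  write.table(rec, path, sep = if (dialect == "csv") "," else "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a GenotypeMatrix
#'
#' Drops non-autosomal markers (with a message), sorts markers by
#' (chromosome, bp) and validates call values.
#'
#' @param calls numeric/integer matrix animals x markers (rownames = animal
#'   ids); values 0/1/2/NA counting allele B.
#' @param map data.frame with snp_id, chrom, bp, alleleA, alleleB.
#' @return a [GenotypeMatrix-class]
#' @export
GenotypeMatrix <- function(calls, map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- suppressWarnings(as.integer(map$chrom))
  map$bp <- as.integer(map$bp)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  keep <- !is.na(map$chrom) & map$chrom >= 1L & map$chrom <= 31L
  if (any(!keep)) {
    message(sum(!keep), " non-autosomal marker(s) dropped")
    map <- map[keep, , drop = FALSE]
    calls <- calls[, keep, drop = FALSE]
  }
  o <- order(map$chrom, map$bp)
  map <- map[o, , drop = FALSE]
  calls <- calls[, o, drop = FALSE]
  rownames(map) <- NULL
  colnames(calls) <- map$snp_id
  new("GenotypeMatrix", calls = calls, map = map)
}

#' Read PLINK genotypes
#'
#' Reads either text \code{.ped}/\code{.map} or binary
#' \code{.bed}/\code{.bim}/\code{.fam} (bed v1.00, SNP-major) files. Calls
#' are coded as the count of allele B, the second allele column of the
#' map/bim; \code{0 0} (text) and the 01 bed code are missing. Non-autosomal
#' markers are dropped with a message; markers are returned sorted by
#' (chromosome, bp).
#'
#' @param prefix file prefix (without extension)
#' @param format \code{"ped"} or \code{"bed"}
#' @return a [GenotypeMatrix-class]
#' @export
readGenotypes <- function(prefix, format = c("ped", "bed")) {
  format <- match.arg(format)
  if (format == "ped") readPedMap(prefix) else readBedBimFam(prefix)
}

readMarkerTable <- function(path, has_alleles) {
  cc <- if (has_alleles) c("character", "character", "numeric", "integer",
                           "character", "character")
        else c("character", "character", "numeric", "integer")
  m <- read.table(path, header = FALSE, colClasses = cc,
                  stringsAsFactors = FALSE)
  names(m)[1:4] <- c("chrom", "snp_id", "cm", "bp")
  if (has_alleles) names(m)[5:6] <- c("alleleA", "alleleB")
  m
}

readPedMap <- function(prefix) {
  pedf <- paste0(prefix, ".ped"); mapf <- paste0(prefix, ".map")
  if (!file.exists(pedf) || !file.exists(mapf))
    stop("missing .ped/.map for prefix ", prefix)
  map <- readMarkerTable(mapf, has_alleles = FALSE)
  m <- nrow(map)
  lines <- readLines(pedf)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  if (any(len != 6L + 2L * m))
    stop("ped/map mismatch: expected ", 6L + 2L * m,
         " fields per ped line, found ", paste(unique(len[len != 6L + 2L * m]),
                                               collapse = ","))
  ids <- vapply(fields, `[`, character(1), 2L)
  al <- matrix(unlist(lapply(fields, `[`, -(1:6))), nrow = n, byrow = TRUE)
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  # .map carries no allele columns, so alleleA/alleleB are assigned in
  # lexicographic order (deterministic; round trips are stable when the
  # source map is lexicographically ordered, as this package writes it)
  calls <- matrix(NA_integer_, n, m)
  alleleA <- alleleB <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(rbind(x1, x2))
    seen <- sort(unique(obs[obs != "0"]))
    if (length(seen) > 2L)
      stop("marker ", map$snp_id[j], " has >2 alleles in ", pedf)
    if (length(seen) == 0L) seen <- c("A", "B")
    if (length(seen) == 1L) seen <- c(seen, if (seen == "A") "B" else "A")
    alleleA[j] <- seen[1L]; alleleB[j] <- seen[2L]
    miss <- x1 == "0" | x2 == "0"
    cj <- (x1 == seen[2L]) + (x2 == seen[2L])
    cj[miss] <- NA_integer_
    calls[, j] <- cj
  }
  rownames(calls) <- ids
  GenotypeMatrix(calls, data.frame(snp_id = map$snp_id, chrom = map$chrom,
                                   bp = map$bp, alleleA = alleleA,
                                   alleleB = alleleB,
                                   stringsAsFactors = FALSE))
}

readBedBimFam <- function(prefix) {
  bedf <- paste0(prefix, ".bed"); bimf <- paste0(prefix, ".bim")
  famf <- paste0(prefix, ".fam")
  if (!all(file.exists(c(bedf, bimf, famf))))
    stop("missing .bed/.bim/.fam for prefix ", prefix)
  bim <- readMarkerTable(bimf, has_alleles = TRUE)
  fam <- read.table(famf, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  ids <- fam[[2L]]
  n <- length(ids); m <- nrow(bim)
  raw <- readBin(bedf, "raw", n = file.size(bedf))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK bed file: ", bedf)
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major bed (v1.00) is supported")
  bpl <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3L != bpl * m)
    stop("bed size inconsistent with fam/bim counts (",
         length(raw) - 3L, " data bytes, expected ", bpl * m, ")")
  body <- raw[-(1:3)]
  # decode 2-bit codes: 00->hom A1 (0 B-alleles), 10->het, 11->hom A2, 01->miss
  lut <- c(0L, NA_integer_, 1L, 2L)  # indexed by code+1
  ints <- as.integer(body)
  codes <- matrix(0L, nrow = 4L * bpl, ncol = m)
  shifts <- c(1L, 4L, 16L, 64L)
  im <- matrix(ints, nrow = bpl, ncol = m)
  for (k in 1:4)
    codes[seq(k, 4L * bpl, by = 4L), ] <- (im %/% shifts[k]) %% 4L
  calls <- matrix(lut[codes[seq_len(n), , drop = FALSE] + 1L], nrow = n)
  rownames(calls) <- ids
  GenotypeMatrix(calls, data.frame(snp_id = bim$snp_id, chrom = bim$chrom,
                                   bp = bim$bp, alleleA = bim$alleleA,
                                   alleleB = bim$alleleB,
                                   stringsAsFactors = FALSE))
}

#' Write PLINK genotypes
#'
#' Writes \code{.ped}/\code{.map} or \code{.bed}/\code{.bim}/\code{.fam}
#' (bed v1.00, SNP-major) for a GenotypeMatrix. Allele letters come from the
#' marker map; missing calls become \code{0 0} (text) / code 01 (bed).
#'
#' @param G a [GenotypeMatrix-class]
#' @param prefix output file prefix
#' @param format \code{"ped"} or \code{"bed"}
#' @return invisibly, the prefix
#' @export
writeGenotypes <- function(G, prefix, format = c("ped", "bed")) {
  format <- match.arg(format)
  v <- calls(G); map <- markerMap(G)
  n <- nrow(v); m <- ncol(v)
  if (format == "ped") {
    write.table(data.frame(map$chrom, map$snp_id, 0, map$bp),
                paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    out <- matrix("0", n, 2L * m)
    for (j in seq_len(m)) {
      gj <- v[, j]
      aa <- map$alleleA[j]; bb <- map$alleleB[j]
      c1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1L, bb, aa))
      c2 <- ifelse(is.na(gj), "0", ifelse(gj == 2L, bb, aa))
      out[, 2L * j - 1L] <- c1
      out[, 2L * j] <- c2
    }
    lines <- paste(1L, rownames(v), 0L, 0L, 0L, -9L,
                   apply(out, 1L, paste, collapse = " "))
    writeLines(lines, paste0(prefix, ".ped"))
  } else {
    write.table(data.frame(map$chrom, map$snp_id, 0, map$bp,
                           map$alleleA, map$alleleB),
                paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    write.table(data.frame(1L, rownames(v), 0L, 0L, 0L, -9L),
                paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    code <- matrix(1L, nrow = 4L * ceiling(n / 4), ncol = m)  # pad = missing
    gm <- v
    cmap <- c(`0` = 0L, `1` = 2L, `2` = 3L)  # dosage -> 2-bit code
    cc <- matrix(1L, n, m)
    cc[!is.na(gm)] <- cmap[as.character(gm[!is.na(gm)])]
    code[seq_len(n), ] <- cc
    code[seq_len(nrow(code)) > n, ] <- 0L  # pad bits are zero per spec v1.00
    bpl <- nrow(code) / 4L
    shifts <- c(1L, 4L, 16L, 64L)
    bytes <- matrix(0L, bpl, m)
    for (k in 1:4)
      bytes <- bytes + code[seq(k, nrow(code), by = 4L), , drop = FALSE] * shifts[k]
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(as.vector(bytes)), con)
  }
  invisible(prefix)
}

#' Assign measurement age classes
#'
#' Half-open bins on age in years: [0,3) -> 1, [3,4) -> 2, [4,5) -> 3,
#' [5,6) -> 4, [6, Inf) -> 5.
#'
#' @param age_years numeric vector of ages (fractional years)
#' @return integer vector of classes 1..5
#' @export
ageClass <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) stop("negative age")
  findInterval(age_years, c(0, 3, 4, 5, 6))
}

#' Read a phenotype table
#'
#' Tab-separated with header columns animal_id, height (cm),
#' measurement_date (ISO-8601) and source (SBR or MPT). Ages are computed
#' from the pedigree birth dates in fractional years (365.25-day years) and
#' binned into the five measurement age classes.
#'
#' @param path file path
#' @param pedigree a [Pedigree-class] covering all phenotyped animals
#' @param height_range plausibility bounds for height in cm
#' @return data.frame (animal_id, height, measurement_date, source,
#'   age_years, age_class)
#' @export
readPhenotypes <- function(path, pedigree, height_range = c(100, 200)) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  ph <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("animal_id", "height", "measurement_date", "source")
  if (!all(need %in% names(ph)))
    stop("phenotype header must name columns: ", paste(need, collapse = ", "))
  ph$animal_id <- as.character(ph$animal_id)
  ph$measurement_date <- as.Date(ph$measurement_date)
  rec <- pedRecords(pedigree)
  unknown <- setdiff(ph$animal_id, rec$animal)
  if (length(unknown))
    stop("phenotypes for animals absent from pedigree: ",
         paste(unknown, collapse = ", "))
  bd <- rec$birth_date[match(ph$animal_id, rec$animal)]
  age <- as.numeric(ph$measurement_date - bd) / 365.25
  if (any(is.na(age)))
    stop("birth date missing for phenotyped animal(s): ",
         paste(ph$animal_id[is.na(age)], collapse = ", "))
  if (any(age < 0)) stop("negative age at measurement for: ",
                         paste(ph$animal_id[age < 0], collapse = ", "))
  bad <- ph$height < height_range[1] | ph$height > height_range[2]
  if (any(bad))
    stop("height outside plausible range for: ",
         paste(ph$animal_id[bad], collapse = ", "))
  data.frame(animal_id = ph$animal_id, height = as.numeric(ph$height),
             measurement_date = ph$measurement_date,
             source = as.character(ph$source),
             age_years = age, age_class = ageClass(age),
             stringsAsFactors = FALSE)
}

#' Write a phenotype table
#' @param phenos data.frame as produced by [readPhenotypes()] or
#'   [simulatePhenotypes()]
#' @param path output path (TSV)
#' @return invisibly, \code{path}
#' @export
writePhenotypes <- function(phenos, path) {
  out <- data.frame(animal_id = phenos$animal_id,
                    height = formatC(phenos$height, format = "fg", digits = 6),
                    measurement_date = format(phenos$measurement_date, "%Y-%m-%d"),
                    source = phenos$source)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt6 <- function(x) formatC(x, format = "g", digits = 6)

#' Write model or GWAS results
#'
#' Tab-separated with a stable column order: GWAS results as (chrom, snp_id,
#' bp, alleleB, freq, beta, se, p); breeding values as (animal_id, gebv, pev,
#' reliability). Floats are written at 6 significant digits.
#'
#' @param fit a [ModelFit-class] or [GwasResult-class]
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeResults <- function(fit, path) {
  if (is(fit, "GwasResult")) {
    tb <- gwasTable(fit)
    out <- data.frame(chrom = tb$chrom, snp_id = tb$snp_id, bp = tb$bp,
                      alleleB = tb$alleleB, freq = fmt6(tb$freq),
                      beta = fmt6(tb$beta), se = fmt6(tb$se), p = fmt6(tb$p))
  } else if (is(fit, "ModelFit")) {
    r2 <- reliabilities(fit)
    out <- data.frame(animal_id = animalIds(fit),
                      gebv = fmt6(breedingValues(fit)),
                      pev = fmt6(predictionErrorVariance(fit)),
                      reliability = fmt6(r2))
  } else stop("fit must be a ModelFit or GwasResult")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a relationship matrix in sparse triplet text form
#'
#' Three columns (id_i, id_j, value), lower triangle including the diagonal,
#' zeros omitted; values at 10 significant digits.
#'
#' @param R a [RelationshipMatrix-class]
#' @param path output path
#' @param zero_tol entries with |value| below this are omitted
#' @return invisibly, \code{path}
#' @export
writeRelationshipMatrix <- function(R, path, zero_tol = 1e-12) {
  v <- relValues(R); ids <- animalIds(R)
  lt <- which(lower.tri(v, diag = TRUE) & abs(v) > zero_tol, arr.ind = TRUE)
  out <- data.frame(id_i = ids[lt[, 1]], id_j = ids[lt[, 2]],
                    value = formatC(v[lt], format = "g", digits = 10))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
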