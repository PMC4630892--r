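#' Read and write PLINK text genotypes
#'
#' `read_plink_ped()` reads a `.ped`/`.map` pair into a `genotype_matrix`
#' with codes counting copies of the second allele of each marker (the
#' second allele observed in the file, or `allele_2` of a supplied map);
#' `write_plink_ped()` writes one. Missing genotypes are `0 0` in the text
#' and `NA` in the matrix.
#'
#' @param prefix Path prefix (files `<prefix>.ped` and `<prefix>.map`).
#' @return `read_plink_ped()`: a `genotype_matrix`.
#' @export
read_plink_ped <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           col.names = c("chr", "snp_id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    stop_structure(".ped has ", ncol(ped), " columns; expected ",
                   6 + 2 * m, " for ", m, " markers.")
  }
  ids <- ped[[2]]
  a1 <- matrix(as.matrix(ped[, 6 + 2 * seq_len(m) - 1]), ncol = m)
  a2 <- matrix(as.matrix(ped[, 6 + 2 * seq_len(m)]), ncol = m)
  geno <- matrix(NA_integer_, nrow(ped), m, dimnames = list(ids, map$snp_id))
  allele_1 <- allele_2 <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- setdiff(unique(obs), "0")
    if (length(alleles) > 2) {
      stop_structure("marker ", map$snp_id[j], " has more than two alleles.")
    }
    if (length(alleles) == 0) alleles <- c("A", "B")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    allele_1[j] <- alleles[1]; allele_2[j] <- alleles[2]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    cnt <- (a1[, j] == alleles[2]) + (a2[, j] == alleles[2])
    cnt[miss] <- NA_integer_
    geno[, j] <- cnt
  }
  p <- colMeans(geno, na.rm = TRUE) / 2
  new_genotype_matrix(geno, tibble::tibble(
    snp_id = map$snp_id, chr = map$chr, pos = map$pos,
    allele_1 = allele_1, allele_2 = allele_2,
    monomorphic = !is.na(p) & (p == 0 | p == 1)))
}

#' @rdname read_plink_ped
#' @param genotypes A `genotype_matrix`.
#' @param pedigree Optional pedigree tibble supplying sire/dam/sex columns
#'   for the `.ped` family fields.
#' @export
write_plink_ped <- function(genotypes, prefix, pedigree = NULL) {
  map <- genotype_map(genotypes)
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, map$pos),
    paste0(prefix, ".map"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  ids <- rownames(genotypes)
  fam <- plink_family_fields(ids, pedigree)
  x <- unclass(genotypes)
  al <- function(code, first, a1, a2) {
    # first/second written allele for codes 0/1/2 (count of allele_2)
    out <- ifelse(is.na(code), "0",
                  ifelse(code == 0, a1, ifelse(code == 2, a2,
                                               if (first) a1 else a2)))
    out
  }
  cols <- vector("list", 2 * ncol(x))
  for (j in seq_len(ncol(x))) {
    cols[[2 * j - 1]] <- al(x[, j], TRUE, map$allele_1[j], map$allele_2[j])
    cols[[2 * j]] <- al(x[, j], FALSE, map$allele_1[j], map$allele_2[j])
  }
  out <- do.call(cbind, c(list(fam), cols))
  utils::write.table(out, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}

plink_family_fields <- function(ids, pedigree) {
  fam <- data.frame(fid = ids, iid = ids, pat = "0", mat = "0",
                    sex = "0", pheno = "-9")
  if (!is.null(pedigree)) {
    i <- match(ids, pedigree$animal)
    fam$pat <- ifelse(is.na(pedigree$sire[i]), "0", pedigree$sire[i])
    fam$mat <- ifelse(is.na(pedigree$dam[i]), "0", pedigree$dam[i])
    if ("sex" %in% names(pedigree)) {
      fam$sex <- c(M = "1", F = "2")[pedigree$sex[i]]
      fam$sex[is.na(fam$sex)] <- "0"
    }
  }
  as.matrix(fam)
}

#' Read and write PLINK binary genotypes
#'
#' Standard SNP-major `.bed`/`.bim`/`.fam` triple. Codes count copies of the
#' second allele of the `.bim` file (column 6), with the PLINK two-bit
#' encoding honoured including missing genotypes.
#'
#' @param prefix Path prefix for the three files.
#' @return `read_plink_bed()`: a `genotype_matrix`.
#' @export
read_plink_bed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chr", "snp_id", "cm", "pos",
                                         "allele_1", "allele_2"),
                           colClasses = "character")
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bpv <- ceiling(n / 4) # bytes per variant
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + bpv * m)
  if (length(raw) < 3 + bpv * m ||
      !identical(as.integer(raw[1:3]), c(108L, 27L, 1L))) {
    stop_structure("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  }
  bits <- matrix(as.integer(rawToBits(raw[-(1:3)])), nrow = 2)
  val <- bits[1, ] + 2L * bits[2, ] # per-sample 2-bit codes, 4 per byte
  val <- matrix(val, nrow = 4 * bpv)[seq_len(n), , drop = FALSE]
  # 0 = hom allele_1, 1 = missing, 2 = het, 3 = hom allele_2
  geno <- matrix(c(0L, NA_integer_, 1L, 2L)[val + 1L], nrow = n,
                 dimnames = list(fam[[2]], bim$snp_id))
  p <- colMeans(geno, na.rm = TRUE) / 2
  new_genotype_matrix(geno, tibble::tibble(
    snp_id = bim$snp_id, chr = bim$chr, pos = as.integer(bim$pos),
    allele_1 = bim$allele_1, allele_2 = bim$allele_2,
    monomorphic = !is.na(p) & (p == 0 | p == 1)))
}

#' @rdname read_plink_bed
#' @param genotypes A `genotype_matrix`.
#' @param pedigree Optional pedigree for the `.fam` family fields.
#' @export
write_plink_bed <- function(genotypes, prefix, pedigree = NULL) {
  map <- genotype_map(genotypes)
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, map$pos, map$allele_1, map$allele_2),
    paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  utils::write.table(plink_family_fields(rownames(genotypes), pedigree),
                     paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  x <- unclass(genotypes)
  n <- nrow(x); m <- ncol(x)
  code2bits <- function(v) {
    # map 0/1/2/NA -> PLINK 2-bit codes 0/2/3/1
    two <- c(0L, 2L, 3L)[v + 1L]
    two[is.na(v)] <- 1L
    two
  }
  bpv <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bpv - n
  for (j in seq_len(m)) {
    two <- c(code2bits(x[, j]), rep(0L, pad))
    b <- matrix(two, nrow = 4)
    bytes <- as.raw(b[1, ] + 4L * b[2, ] + 16L * b[3, ] + 64L * b[4, ])
    writeBin(bytes, con)
  }
  invisible(prefix)
}

#' Read a headered delimited genotype table
#'
#' Simple dialect: first column animal id, remaining columns one SNP each
#' with codes 0/1/2 (blank or `NA` missing).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A `genotype_matrix` (map positions unknown; filled with index).
#' @export
read_genotype_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  x <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(x) <- "integer"
  if (!all(x %in% c(0L, 1L, 2L) | is.na(x))) {
    stop_structure("genotype codes must be 0, 1, 2 or missing.")
  }
  dimnames(x) <- list(ids, colnames(df)[-1])
  p <- colMeans(x, na.rm = TRUE) / 2
  new_genotype_matrix(x, tibble::tibble(
    snp_id = colnames(x), chr = "0", pos = seq_len(ncol(x)),
    allele_1 = "A", allele_2 = "B",
    monomorphic = !is.na(p) & (p == 0 | p == 1)))
}

#' Write and read a relationship matrix as delimited text
#'
#' Square tab-separated layout with animal ids on both margins plus a header
#' line carrying the kind and blend metadata.
#'
#' @param matrix A `relationship_matrix`.
#' @param path File path.
#' @export
write_relationship_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind=", attr(matrix, "kind"),
                    " blend=", attr(matrix, "blend")), con)
  utils::write.table(as.data.frame(unclass(matrix)), con, quote = FALSE,
                     sep = "\t", col.names = NA)
  invisible(path)
}

#' @rdname write_relationship_matrix
#' @export
read_relationship_matrix <- function(path) {
  header <- readLines(path, n = 1)
  kind <- sub("^#kind=(\\S+).*", "\\1", header)
  blend <- suppressWarnings(as.numeric(sub(".*blend=(\\S+)$", "\\1", header)))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          row.names = 1, check.names = FALSE)
  new_relationship_matrix(as.matrix(df), kind = kind, blend = blend,
                          provenance = list(label = paste("read from", path)))
}

#' Write the tables of a simulated population
#'
#' Pedigree and phenotypes as headered tab-separated text, genotypes as a
#' PLINK `.ped`/`.map` pair (and optionally `.bed`/`.bim`/`.fam`).
#'
#' @param population A [simulate_population()] result.
#' @param dir Output directory (created if needed).
#' @param binary Also write the PLINK binary triple.
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir, binary = FALSE) {
  stopifnot(inherits(population, "sim_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(population$pedigree, file.path(dir, "pedigree.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  utils::write.table(population$phenotypes, file.path(dir, "phenotypes.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  write_plink_ped(population$genotypes, file.path(dir, "genotypes"),
                  pedigree = population$pedigree)
  if (binary) {
    write_plink_bed(population$genotypes, file.path(dir, "genotypes"),
                    pedigree = population$pedigree)
  }
  truth <- population$truth
  utils::write.table(truth$qtl_effects, file.path(dir, "qtl_effects.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  utils::write.table(truth$true_breeding_values,
                     file.path(dir, "true_breeding_values.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(dir)
}
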