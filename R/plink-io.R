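VALID_ALLELES <- c("A", "C", "G", "T", "1", "2")

#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses a PED/MAP pair into a [genotype_dataset()]. Genotypes are recoded
#' to A2-allele dosage. Because the text format records no allele
#' orientation, A2 defaults to the first allele observed at each marker in
#' file order; pass `a2` (e.g. from a BIM file or a previous dataset) to fix
#' the orientation explicitly. The PED family field becomes the population
#' label.
#'
#' @param ped_path,map_path file paths.
#' @param a2 optional character vector (length = markers) of A2 alleles.
#' @return a `genotype_dataset` with `a1`/`a2` recorded in the map.
#' @export
read_plink_text <- function(ped_path, map_path, a2 = NULL) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_df <- utils::read.table(map_path, header = FALSE,
                              colClasses = "character")
  if (ncol(map_df) != 4) stop("MAP file must have 4 columns, found ", ncol(map_df))
  names(map_df) <- c("chrom", "marker_id", "cm", "pos_bp")
  m <- nrow(map_df)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (!n) stop("empty PED file")
  fam <- character(n); iid <- character(n)
  A <- matrix("", n, m); B <- matrix("", n, m)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      stop("ragged PED line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(tok))
    }
    fam[i] <- tok[1]; iid[i] <- tok[2]
    A[i, ] <- tok[seq(7, by = 2, length.out = m)]
    B[i, ] <- tok[seq(8, by = 2, length.out = m)]
  }
  if (anyDuplicated(iid)) stop("duplicate sample id: ", iid[duplicated(iid)][1])
  bad <- !(A %in% c(VALID_ALLELES, "0")) | !(B %in% c(VALID_ALLELES, "0"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid allele code at line ", w[1], ", marker ", map_df$marker_id[w[2]])
  }
  half <- xor(A == "0", B == "0")
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype at line ", w[1], ", marker ",
         map_df$marker_id[w[2]])
  }
  miss <- A == "0"
  a1_obs <- rep(NA_character_, m)
  a2_obs <- if (is.null(a2)) rep(NA_character_, m) else as.character(a2)
  if (length(a2_obs) != m) stop("a2 must have one entry per marker")
  G <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    # alleles in file order: sample 1 first allele, second allele, sample 2 ...
    v <- as.vector(rbind(A[, j], B[, j]))
    v <- v[v != "0"]
    u <- unique(v)
    if (!is.na(a2_obs[j])) u <- unique(c(a2_obs[j], u))
    if (length(u) > 2) stop("more than 2 alleles at marker ", map_df$marker_id[j])
    if (is.na(a2_obs[j]) && length(u)) a2_obs[j] <- u[1]
    if (length(u) == 2) a1_obs[j] <- u[u != a2_obs[j]]
    called <- !miss[, j]
    G[called, j] <- (A[called, j] == a2_obs[j]) + (B[called, j] == a2_obs[j])
  }
  map <- marker_map(map_df$chrom, map_df$marker_id, as.integer(map_df$pos_bp),
                    a1 = a1_obs, a2 = a2_obs)
  # marker_map may reorder; keep genotype columns in step
  ord <- match(map$marker_id, map_df$marker_id)
  genotype_dataset(G[, ord, drop = FALSE], map,
                   data.frame(sample_id = iid, population = fam))
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Inverse of [read_plink_text()]. Missing genotypes are written `0 0`;
#' alleles default to `A` (A1) / `B`-less `G` (A2) where the map records
#' none.
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
write_plink_text <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  map <- dataset$map
  a1 <- if (is.null(map$a1)) rep("A", nrow(map)) else ifelse(is.na(map$a1), "A", map$a1)
  a2 <- if (is.null(map$a2)) rep("G", nrow(map)) else ifelse(is.na(map$a2), "G", map$a2)
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  utils::write.table(
    data.frame(map$chrom, map$marker_id, 0, map$pos_bp),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  G <- dataset$genotypes
  n <- nrow(G); m <- ncol(G)
  al1 <- matrix(a1, n, m, byrow = TRUE)
  al2 <- matrix(a1, n, m, byrow = TRUE)
  A2 <- matrix(a2, n, m, byrow = TRUE)
  hom2 <- !is.na(G) & G == 2
  anyg <- !is.na(G) & G >= 1
  al1[hom2] <- A2[hom2]
  al2[anyg] <- A2[anyg]
  al1[is.na(G)] <- "0"; al2[is.na(G)] <- "0"
  geno_cols <- matrix("", n, 2 * m)
  geno_cols[, seq(1, 2 * m, 2)] <- al1
  geno_cols[, seq(2, 2 * m, 2)] <- al2
  lines <- paste(dataset$samples$population, dataset$samples$sample_id,
                 0, 0, 0, -9,
                 apply(geno_cols, 1, paste, collapse = " "))
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

# PLINK 1.9 .bed 2-bit codes (SNP-major): 00 = hom A1 (dosage 0),
# 01 = missing, 10 = het (dosage 1), 11 = hom A2 (dosage 2).
BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_SNP_MAJOR <- as.raw(0x01)
.bed_code_to_dosage <- c(0L, NA_integer_, 1L, 2L)      # index = code + 1
.bed_dosage_to_code <- function(g) {
  code <- integer(length(g))
  code[is.na(g)] <- 1L
  code[!is.na(g) & g == 1L] <- 2L
  code[!is.na(g) & g == 2L] <- 3L
  code
}

#' Read PLINK binary genotypes (BED/BIM/FAM)
#'
#' Bit-exact reader for the PLINK 1.9 SNP-major binary format. Produces a
#' dataset identical to [read_plink_text()] on equivalent files, with the
#' allele orientation taken from the BIM (dosage counts the BIM A2 allele).
#'
#' @param bed_path,bim_path,fam_path file paths.
#' @return a `genotype_dataset`.
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  stopifnot(file.exists(bed_path), file.exists(bim_path), file.exists(fam_path))
  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character")
  if (ncol(bim) != 6) stop("BIM file must have 6 columns")
  names(bim) <- c("chrom", "marker_id", "cm", "pos_bp", "a1", "a2")
  fam_df <- utils::read.table(fam_path, header = FALSE, colClasses = "character")
  n <- nrow(fam_df); m <- nrow(bim)
  bpm <- ceiling(n / 4)                     # bytes per marker
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:2], BED_MAGIC)) {
    stop("not a PLINK .bed file (bad magic bytes)")
  }
  if (raw[3] != BED_SNP_MAJOR) stop("only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  if (length(body) != bpm * m) {
    stop("truncated .bed: expected ", bpm * m, " data bytes, found ",
         length(body))
  }
  ints <- as.integer(body)
  # unpack 4 samples per byte, low-order bit pair first
  codes <- matrix(0L, nrow = 4 * bpm, ncol = m)
  block <- matrix(ints, nrow = bpm, ncol = m)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bpm, by = 4), ] <- block %% 4L
    block <- block %/% 4L
  }
  G <- matrix(.bed_code_to_dosage[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  map <- marker_map(bim$chrom, bim$marker_id, as.integer(bim$pos_bp),
                    a1 = bim$a1, a2 = bim$a2)
  ord <- match(map$marker_id, bim$marker_id)
  if (anyDuplicated(fam_df[[2]])) stop("duplicate sample id in FAM")
  genotype_dataset(G[, ord, drop = FALSE], map,
                   data.frame(sample_id = fam_df[[2]], population = fam_df[[1]]))
}

#' Write PLINK binary genotypes (BED/BIM/FAM)
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_plink_binary <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  map <- dataset$map
  a1 <- if (is.null(map$a1)) rep("A", nrow(map)) else ifelse(is.na(map$a1), "A", map$a1)
  a2 <- if (is.null(map$a2)) rep("G", nrow(map)) else ifelse(is.na(map$a2), "G", map$a2)
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  bed_path <- paste0(prefix, ".bed")
  utils::write.table(
    data.frame(map$chrom, map$marker_id, 0, map$pos_bp, a1, a2),
    bim_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(dataset$samples$population, dataset$samples$sample_id,
               0, 0, 0, -9),
    fam_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  G <- dataset$genotypes
  n <- nrow(G); m <- ncol(G)
  bpm <- ceiling(n / 4)
  codes <- matrix(0L, nrow = 4 * bpm, ncol = m)
  codes[seq_len(n), ] <- matrix(.bed_dosage_to_code(G), n, m)
  mult <- 4L^(0:3)
  packed <- matrix(0L, bpm, m)
  for (k in 0:3) {
    packed <- packed + codes[seq(k + 1, 4 * bpm, by = 4), , drop = FALSE] * mult[k + 1]
  }
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, BED_SNP_MAJOR, as.raw(packed)), con)
  invisible(c(bed = bed_path, bim = bim_path, fam = fam_path))
}
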