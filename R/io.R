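## Readers and writers: PLINK .bed/.bim/.fam, ADMIXTURE-style .Q/.P files,
## TSV tables for pedigrees, phenotypes, pairs and tracts.

# 2-bit PLINK codes (variant-major): 00 hom A1, 01 missing, 10 het, 11 hom A2.
# Genotypes are stored as the A1-allele dosage (0/1/2).
.bedCodeToGeno <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
.genoToBedCode <- function(g) ifelse(is.na(g), 1L,
                                     ifelse(g == 2L, 0L,
                                            ifelse(g == 1L, 2L, 3L)))

#' Read PLINK binary genotypes
#'
#' Reads a variant-major PLINK `.bed`/`.bim`/`.fam` fileset into a 0/1/2
#' dosage matrix (A1 allele counted), checking the magic bytes, the
#' variant-major flag and the file length.
#'
#' @param prefix path prefix (without extension).
#' @return list with `genotypes` (individuals x loci, `NA` = missing),
#'   `fam` (6-column data.frame) and `bim` (6-column data.frame).
#' @export
readPlink <- function(prefix) {
  bedPath <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("missing file: ", f)
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "father", "mother", "sex",
                                  "pheno"))
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp", "posM", "posBp", "a1",
                                  "a2"))
  n <- nrow(fam)
  L <- nrow(bim)
  raw <- readBin(bedPath, "raw", n = file.size(bedPath))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bedPath)
  if (raw[3] == as.raw(0x00))
    stop("sample-major .bed files are not supported: ", bedPath)
  if (raw[3] != as.raw(0x01))
    stop("unknown .bed mode byte: ", bedPath)
  bytesPer <- ceiling(n / 4)
  if (length(raw) != 3L + bytesPer * L)
    stop(".bed file length (", length(raw), ") does not match ", n,
         " samples x ", L, " variants: ", bedPath)
  bits <- as.integer(rawToBits(raw[-(1:3)]))
  code <- bits[seq(1L, length(bits), by = 2L)] +
    2L * bits[seq(2L, length(bits), by = 2L)]
  gmat <- matrix(.bedCodeToGeno[code + 1L], nrow = 4L * bytesPer, ncol = L)
  gmat <- gmat[seq_len(n), , drop = FALSE]
  dimnames(gmat) <- list(fam$iid, bim$snp)
  list(genotypes = gmat, fam = fam, bim = bim)
}

#' Write PLINK binary genotypes
#'
#' Writes a variant-major `.bed` with companion `.bim` and `.fam` files.
#'
#' @param geno genotype matrix (individuals x loci, 0/1/2/`NA`), rownames =
#'   individual ids.
#' @param prefix output path prefix.
#' @param fam optional 6-column data.frame (`fid, iid, father, mother, sex,
#'   pheno`); defaults built from rownames.
#' @param bim optional 6-column data.frame (`chrom, snp, posM, posBp, a1,
#'   a2`); defaults built from colnames.
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(geno, prefix, fam = NULL, bim = NULL) {
  n <- nrow(geno)
  L <- ncol(geno)
  if (is.null(fam))
    fam <- data.frame(fid = rownames(geno), iid = rownames(geno),
                      father = 0, mother = 0, sex = 0, pheno = -9)
  if (is.null(bim))
    bim <- data.frame(chrom = 1, snp = colnames(geno), posM = 0,
                      posBp = seq_len(L), a1 = "A", a2 = "B")
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  bytesPer <- ceiling(n / 4)
  pad <- 4L * bytesPer - n
  codes <- .genoToBedCode(geno) # n x L
  if (pad > 0L)
    codes <- rbind(codes, matrix(0L, pad, L))
  bits <- rbind(as.vector(codes) %% 2L, as.vector(codes) %/% 2L)
  bed <- c(as.raw(c(0x6c, 0x1b, 0x01)), packBits(as.logical(bits), "raw"))
  writeBin(bed, paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Read an ADMIXTURE-style .Q file
#'
#' Whitespace-separated, two columns (K = 2), one row per individual in the
#' companion `.fam`/pedigree order. Rows are renormalised with a warning if
#' they do not sum to 1 within `1e-4`.
#'
#' @param path file path.
#' @param column which column holds ancestral population 1 (default 1).
#' @param ids optional individual ids to attach as names.
#' @return named numeric vector of ancestry-1 proportions.
#' @export
readQ <- function(path, column = 1L, ids = NULL) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 2L)
    stop(".Q file must have exactly 2 columns, found ", ncol(m))
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-4)) {
    warning("some .Q rows do not sum to 1; renormalising")
    m <- m / rs
  }
  q <- m[, column]
  if (!is.null(ids)) names(q) <- ids
  q
}

#' Write an ADMIXTURE-style .Q file
#' @param q ancestry-1 proportions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQ <- function(q, path) {
  write.table(cbind(q, 1 - q), path, quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an ADMIXTURE-style .P frequency file
#'
#' Two whitespace-separated columns (population 1, population 2), one row
#' per locus.
#'
#' @param P two-column matrix of allele frequencies (e.g. the `P` slot of an
#'   [AdmixtureEstimate-class]), or an [AncestralFreqs-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeP <- function(P, path) {
  if (is(P, "AncestralFreqs")) P <- cbind(P@f1, P@f2)
  write.table(P, path, quote = FALSE, sep = " ", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix
#'
#' Dispatches on format: `"plink"` reads a `.bed`/`.bim`/`.fam` fileset via
#' [readPlink()]; `"tsv"` reads a tab-separated dosage matrix with a header
#' of locus names and individual ids in the first column.
#'
#' @param path PLINK prefix or TSV path.
#' @param format `"plink"` or `"tsv"`.
#' @return integer matrix, individuals x loci (`NA` = missing).
#' @export
readGenotypes <- function(path, format = c("plink", "tsv")) {
  format <- match.arg(format)
  if (format == "plink") return(readPlink(path)$genotypes)
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  m
}

#' @rdname readGenotypes
#' @param geno genotype matrix to write (rownames = individual ids).
#' @export
writeGenotypesTSV <- function(geno, path) {
  d <- data.frame(id = rownames(geno), geno, check.names = FALSE)
  write.table(d, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write / read a tab-separated table with header
#' @param x data.frame.
#' @param path file path.
#' @return `writeTSV` returns `path` invisibly; `readTSV` the data.frame.
#' @export
writeTSV <- function(x, path) {
  write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)

#' Write simulated local-ancestry tracts as BED-like TSV
#'
#' One row per tract segment: chromosome, start and end in Morgans (here
#' written as centimorgans/100-free Morgan units), individual id, haplotype
#' (1/2), ancestry label.
#'
#' @param pop an [AdmixPedigree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTracts <- function(pop, path) {
  rows <- list()
  for (id in pop@ped$id) {
    ind <- pop@tracts[[id]]
    for (h in 1:2) {
      hap <- ind[[h]]
      for (k in seq_along(pop@map@chrom)) {
        seg <- hap[[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = pop@map@chrom[k], startM = c(0, head(seg$end, -1)),
          endM = seg$end, id = id, haplotype = h, ancestry = seg$anc)
      }
    }
  }
  writeTSV(do.call(rbind, rows), path)
}
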