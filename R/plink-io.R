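# PLINK1 binary genotype input/output.
# .bed layout: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major), then
# ceil(n/4) bytes per SNP, 4 samples per byte, 2 bits each, LSB first:
# 00 = two copies of allele A1, 10 = heterozygote, 11 = zero copies,
# 01 = missing. We write the counted allele as A1, so the 2-bit code maps
# to minor-allele counts 2 / 1 / 0 / NA.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b))
.BED_SNP_MAJOR <- as.raw(0x01)

# code (0..3) -> genotype; 0b00=2, 0b01=NA, 0b10=1, 0b11=0
.bed_code_to_geno <- c(2L, NA_integer_, 1L, 0L)
.geno_to_bed_code <- function(g) {
    code <- integer(length(g))
    code[is.na(g)] <- 1L
    code[!is.na(g) & g == 2L] <- 0L
    code[!is.na(g) & g == 1L] <- 2L
    code[!is.na(g) & g == 0L] <- 3L
    code
}

# 4 x 256 lookup: genotypes of the 4 samples packed in each byte value
.bed_lookup <- local({
    m <- matrix(NA_integer_, nrow = 4L, ncol = 256L)
    for (b in 0:255) {
        v <- b
        for (s in 1:4) {
            m[s, b + 1L] <- .bed_code_to_geno[(v %% 4L) + 1L]
            v <- v %/% 4L
        }
    }
    m
})

#' Read a PLINK1 binary fileset
#'
#' Decodes a SNP-major PLINK1 \code{.bed}/\code{.bim}/\code{.fam} trio
#' into a \linkS4class{GenotypeData} object. Genotypes are returned as
#' counts of the \code{.bim} A1 allele (column 5), with missing calls
#' preserved as \code{NA}; SNPs keep their \code{.bim} order. The
#' \code{.fam} phenotype column is mapped 1/2 to status 0/1 and 0/-9 to
#' \code{NA}; sex 1/2 maps to \code{"M"}/\code{"F"}.
#'
#' @param prefix path prefix of the fileset (\code{prefix.bed} etc.), or
#'   the path to the \code{.bed} file itself.
#' @param bim,fam optional explicit paths overriding the prefix rule.
#'
#' @return A \linkS4class{GenotypeData}.
#' @seealso [writePlink()]
#' @export
readPlink <- function(prefix, bim = NULL, fam = NULL) {
    bed <- if (grepl("\\.bed$", prefix)) prefix else paste0(prefix, ".bed")
    base <- sub("\\.bed$", "", bed)
    if (is.null(bim)) bim <- paste0(base, ".bim")
    if (is.null(fam)) fam <- paste0(base, ".fam")
    for (f in c(bed, bim, fam))
        if (!file.exists(f)) stop("file not found: ", f)

    bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
        col.names = c("chr", "snp", "cm", "pos", "a1", "a2"),
        colClasses = c("character", "character", "numeric", "integer",
                       "character", "character"))
    fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
        col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))

    n <- nrow(fam_df); m <- nrow(bim_df)
    bps <- (n + 3L) %/% 4L                      # bytes per SNP
    raw <- readBin(bed, what = "raw", n = file.size(bed))
    if (length(raw) < 3L || raw[1L] != .BED_MAGIC[1L] ||
        raw[2L] != .BED_MAGIC[2L])
        stop("not a PLINK1 .bed file (bad magic at byte offset 0): ", bed)
    if (raw[3L] != .BED_SNP_MAJOR)
        stop("unsupported .bed mode at byte offset 2 (expect SNP-major 0x01)")
    if (length(raw) != 3L + bps * m)
        stop(sprintf(
            "truncated .bed: expected %d bytes, found %d (data start offset 3)",
            3L + bps * m, length(raw)))

    body <- as.integer(raw[-(1:3)])             # bps * m byte values
    geno <- .bed_lookup[, body + 1L]            # 4 x (bps*m)
    dim(geno) <- c(4L * bps, m)
    calls <- geno[seq_len(n), , drop = FALSE]   # samples x SNPs
    calls <- t(calls)                           # SNPs x samples

    status <- ifelse(fam_df$pheno %in% c(1L, 2L), fam_df$pheno - 1L,
                     NA_integer_)
    sex <- c("M", "F")[match(fam_df$sex, c(1L, 2L))]
    GenotypeData(calls,
        snpInfo = bim_df[, c("snp", "chr", "pos", "a1", "a2")],
        sampleInfo = data.frame(sample_id = fam_df$iid, status = status,
                                sex = sex, stringsAsFactors = FALSE))
}

#' Write a PLINK1 binary fileset
#'
#' Encodes a \linkS4class{GenotypeData} object as SNP-major
#' \code{.bed}/\code{.bim}/\code{.fam}. The counted allele is written as
#' A1 so that \code{readPlink(writePlink(x))} reproduces the calls
#' exactly.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
writePlink <- function(geno, prefix) {
    stopifnot(methods::is(geno, "GenotypeData"))
    calls <- genoCalls(geno)
    si <- as.data.frame(snpInfo(geno))
    sa <- as.data.frame(sampleInfo(geno))
    n <- ncol(calls); m <- nrow(calls)
    bps <- (n + 3L) %/% 4L

    codes <- matrix(0L, nrow = 4L * bps, ncol = m)
    codes[seq_len(n), ] <- apply(calls, 1L, .geno_to_bed_code)
    dim(codes) <- c(4L, bps * m)
    bytes <- as.raw(codes[1L, ] + 4L * codes[2L, ] + 16L * codes[3L, ] +
                    64L * codes[4L, ])
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(c(.BED_MAGIC, .BED_SNP_MAJOR), con)
    writeBin(bytes, con)

    bim <- data.frame(chr = si$chr, snp = si$snp, cm = 0, pos = si$pos,
                      a1 = si$a1, a2 = si$a2)
    write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    sex <- if ("sex" %in% names(sa))
        ifelse(is.na(sa$sex), 0L, ifelse(sa$sex == "M", 1L, 2L)) else 0L
    pheno <- if ("status" %in% names(sa))
        ifelse(is.na(sa$status), -9L, sa$status + 1L) else -9L
    fam <- data.frame(fid = sa$sample_id, iid = sa$sample_id,
                      pat = 0L, mat = 0L, sex = sex, pheno = pheno)
    write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(prefix)
}

#' Write / read the phenotype-covariate table
#'
#' Plain TSV with header; columns \code{sample_id}, \code{status},
#' \code{sex}, \code{age}, \code{batch} and, when simulated or recorded,
#' \code{onset_age} and \code{censored}.
#'
#' @param geno a \linkS4class{GenotypeData} with populated sample columns.
#' @param path output TSV path.
#' @return \code{writePheno}: the path, invisibly.
#' @export
writePheno <- function(geno, path) {
    sa <- as.data.frame(sampleInfo(geno))
    write.table(sa, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePheno
#' @param pheno path to a phenotype TSV, or a data.frame, keyed by
#'   \code{sample_id}.
#' @return \code{attachPhenotype}: \code{geno} with its \code{colData}
#'   merged with the table (phenotype rows are matched by
#'   \code{sample_id}; samples absent from the table keep \code{NA}).
#' @export
attachPhenotype <- function(geno, pheno) {
    if (is.character(pheno)) {
        if (!file.exists(pheno)) stop("phenotype file not found: ", pheno)
        pheno <- read.table(pheno, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    }
    stopifnot("sample_id" %in% names(pheno))
    sa <- as.data.frame(sampleInfo(geno))
    idx <- match(sa$sample_id, pheno$sample_id)
    for (col in setdiff(names(pheno), "sample_id"))
        sa[[col]] <- pheno[[col]][idx]
    sampleInfo(geno) <- sa
    geno
}
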