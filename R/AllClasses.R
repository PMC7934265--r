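#' GenotypeData: genotype calls with SNP and sample annotation
#'
#' Container for biallelic genotype data. Extends
#' \linkS4class{SummarizedExperiment}: rows are SNPs, columns are samples,
#' and the single assay \code{"calls"} holds minor-allele counts (integer
#' 0/1/2, \code{NA} = missing). \code{rowData} carries per-SNP metadata
#' (\code{snp}, \code{chr}, \code{pos}, \code{a1} = counted/minor allele,
#' \code{a2} = other allele); \code{colData} carries per-sample phenotype
#' and covariate columns (\code{sample_id} and, when available,
#' \code{status}, \code{sex}, \code{age}, \code{batch}, \code{onset_age},
#' \code{censored}, principal-component columns \code{PC1}, ...).
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @seealso [GenotypeData()], [readPlink()], [simulateGenotypes()]
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- NULL
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'calls' is required")
    else {
        g <- SummarizedExperiment::assay(object, "calls")
        if (!is.integer(g) && !is.numeric(g))
            msg <- c(msg, "'calls' must be numeric")
        bad <- g[!is.na(g)]
        if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
            msg <- c(msg, "'calls' must lie in {0, 1, 2, NA}")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("snp", "chr", "pos", "a1", "a2")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if ("pos" %in% colnames(rd) && nrow(rd) && any(rd$pos <= 0))
        msg <- c(msg, "SNP positions must be positive")
    if (all(c("a1", "a2") %in% colnames(rd)) && nrow(rd) &&
        any(rd$a1 == rd$a2))
        msg <- c(msg, "allele pairs must be distinct")
    if (!"sample_id" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData lacks 'sample_id'")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param calls integer matrix of minor-allele counts, SNPs in rows and
#'   samples in columns; values 0/1/2 or \code{NA} for missing.
#' @param snpInfo data.frame or DataFrame with columns \code{snp},
#'   \code{chr}, \code{pos} (1-based), \code{a1} (counted allele),
#'   \code{a2}; one row per SNP.
#' @param sampleInfo data.frame or DataFrame with a \code{sample_id}
#'   column and optional phenotype/covariate columns; one row per sample.
#'
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 2,
#'             dimnames = list(NULL, NULL))
#' snps <- data.frame(snp = c("rs1", "rs2"), chr = c("1", "1"),
#'                    pos = c(100L, 200L), a1 = c("A", "C"),
#'                    a2 = c("G", "T"))
#' gd <- GenotypeData(g, snps, data.frame(sample_id = paste0("s", 1:3)))
#' nSnps(gd)
#' @export
GenotypeData <- function(calls, snpInfo, sampleInfo) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    snpInfo <- S4Vectors::DataFrame(snpInfo)
    sampleInfo <- S4Vectors::DataFrame(sampleInfo)
    rownames(calls) <- snpInfo$snp
    colnames(calls) <- sampleInfo$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls),
        rowData = snpInfo, colData = sampleInfo)
    methods::new("GenotypeData", se)
}

#' JointTable: 3x3x2 genotype-by-status contingency table for a SNP pair
#'
#' Counts of pairwise-complete samples cross-classified by the genotypes
#' of two SNPs (0/1/2 minor-allele counts) and case-control status.
#' Dimension order is (genotype of SNP A, genotype of SNP B, status) with
#' status slice 1 = controls, slice 2 = cases.
#'
#' @slot counts 3x3x2 non-negative integer array.
#' @slot snpA,snpB SNP identifiers.
#' @seealso [buildJointTable()]
#' @export
setClass("JointTable",
    representation(counts = "array", snpA = "character", snpB = "character"))

setValidity("JointTable", function(object) {
    d <- dim(object@counts)
    if (length(d) != 3L || !all(d == c(3L, 3L, 2L)))
        return("'counts' must be a 3x3x2 array")
    if (any(object@counts < 0) || any(is.na(object@counts)))
        return("'counts' must be non-negative and complete")
    TRUE
})

#' Construct a JointTable
#'
#' @param counts 3x3x2 array (or 18-vector, genotype-of-A fastest,
#'   status slowest) of non-negative counts.
#' @param snpA,snpB SNP identifiers.
#' @return A \linkS4class{JointTable}.
#' @examples
#' JointTable(array(5L, c(3, 3, 2)), "rs1", "rs2")
#' @export
JointTable <- function(counts, snpA = "A", snpB = "B") {
    counts <- array(as.integer(round(counts)), dim = c(3L, 3L, 2L),
                    dimnames = list(g1 = 0:2, g2 = 0:2,
                                    status = c("control", "case")))
    methods::new("JointTable", counts = counts,
                 snpA = as.character(snpA), snpB = as.character(snpB))
}

#' EffectTable: per-cell effects and MDR labels for one interaction
#'
#' For a SNP pair, the 3x3 matrix of per-cell effect sizes (natural-log
#' odds ratios of each joint-genotype cell against the rest of the table)
#' together with the multifactor-dimensionality-reduction (MDR) high/low
#' risk label of each cell and the case:control threshold ratio used for
#' labelling.
#'
#' @slot snpA,snpB SNP identifiers.
#' @slot logOR 3x3 numeric matrix of per-cell ln(OR); \code{NA} where a
#'   cell has no cases or no controls.
#' @slot highRisk 3x3 logical matrix; \code{TRUE} marks high-risk cells.
#' @slot threshold overall case:control ratio used as the MDR label
#'   threshold.
#' @seealso [estimateEffectTable()], [mdrPredict()], [computeERS()]
#' @export
setClass("EffectTable",
    representation(snpA = "character", snpB = "character",
                   logOR = "matrix", highRisk = "matrix",
                   threshold = "numeric"))

setValidity("EffectTable", function(object) {
    if (!all(dim(object@logOR) == c(3L, 3L)))
        return("'logOR' must be 3x3")
    if (!all(dim(object@highRisk) == c(3L, 3L)))
        return("'highRisk' must be 3x3")
    if (!is.logical(object@highRisk))
        return("'highRisk' must be logical")
    TRUE
})
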