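#' @rdname GenotypeData-class
#' @export
setMethod("genoCalls", "GenotypeData", function(x)
    SummarizedExperiment::assay(x, "calls"))

#' @rdname GenotypeData-class
#' @export
setMethod("snpInfo", "GenotypeData", function(x)
    SummarizedExperiment::rowData(x))

#' @rdname GenotypeData-class
#' @export
setMethod("sampleInfo", "GenotypeData", function(x)
    SummarizedExperiment::colData(x))

#' @rdname GenotypeData-class
#' @export
setReplaceMethod("sampleInfo", "GenotypeData", function(x, value) {
    SummarizedExperiment::colData(x) <- S4Vectors::DataFrame(value)
    methods::validObject(x)
    x
})

#' @rdname GenotypeData-class
#' @export
setMethod("nSnps", "GenotypeData", function(x) nrow(x))

#' @rdname GenotypeData-class
#' @export
setMethod("nSamples", "GenotypeData", function(x) ncol(x))

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object), "SNPs x", ncol(object), "samples\n")
    g <- SummarizedExperiment::assay(object, "calls")
    cat(sprintf("  missing calls: %.3f%%\n", 100 * mean(is.na(g))))
    cd <- SummarizedExperiment::colData(object)
    if ("status" %in% colnames(cd) && !all(is.na(cd$status)))
        cat(sprintf("  cases: %d  controls: %d\n",
                    sum(cd$status == 1L, na.rm = TRUE),
                    sum(cd$status == 0L, na.rm = TRUE)))
    extra <- setdiff(colnames(cd), "sample_id")
    if (length(extra))
        cat("  sample columns:", paste(extra, collapse = ", "), "\n")
})

#' @rdname JointTable-class
#' @export
setMethod("jointCounts", "JointTable", function(x) x@counts)

setMethod("show", "JointTable", function(object) {
    cat("JointTable:", object@snpA, "x", object@snpB,
        " (n =", sum(object@counts), ")\n")
    cat("controls:\n"); print(object@counts[, , 1L])
    cat("cases:\n");    print(object@counts[, , 2L])
})

#' @rdname EffectTable-class
#' @export
setMethod("cellLogOR", "EffectTable", function(x) x@logOR)

#' @rdname EffectTable-class
#' @export
setMethod("highRiskCells", "EffectTable", function(x) x@highRisk)

setMethod("show", "EffectTable", function(object) {
    cat("EffectTable:", object@snpA, "x", object@snpB,
        sprintf(" (threshold case:control = %.3f)\n", object@threshold))
    m <- round(object@logOR, 3)
    lab <- ifelse(object@highRisk, "H", "L")
    out <- matrix(paste0(m, " (", lab, ")"), 3, 3,
                  dimnames = list(g1 = 0:2, g2 = 0:2))
    print(out, quote = FALSE)
})
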