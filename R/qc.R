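# SNP- and sample-level quality control, HWE exact test, LD, PCA.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the allele counts: the p-value is
#' the sum of the probabilities of all heterozygote counts (with the same
#' parity as the observed minor-allele count) whose conditional
#' probability does not exceed that of the observed table.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (order of the two homozygote
#'   classes does not matter).
#' @return The exact two-sided p-value.
#' @examples
#' hweExactTest(25, 50, 25)   # perfect HWE: p = 1
#' hweExactTest(50, 0, 50)    # extreme heterozygote deficit
#' @export
hweExactTest <- function(n_AA, n_Aa, n_aa) {
    counts <- c(n_AA, n_Aa, n_aa)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("genotype counts must be non-negative integers")
    n <- sum(counts)
    if (n == 0L) stop("all-zero genotype counts")
    n_a <- 2L * min(n_AA, n_aa) + n_Aa          # rarer-allele count
    # het counts share the parity of the minor-allele count
    h <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
    hom_a <- (n_a - h) %/% 2L
    hom_A <- n - hom_a - h
    logp <- lgamma(n + 1) - lgamma(hom_A + 1) - lgamma(h + 1) -
        lgamma(hom_a + 1) + h * log(2) +
        lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
    prob <- exp(logp - max(logp))
    prob <- prob / sum(prob)
    obs <- prob[match(n_Aa, h)]
    sum(prob[prob <= obs * (1 + 1e-10)])
}

.snp_stats <- function(calls, status = NULL) {
    miss <- rowMeans(is.na(calls))
    mean_g <- rowMeans(calls, na.rm = TRUE)
    maf <- pmin(mean_g / 2, 1 - mean_g / 2)
    maf[is.nan(maf)] <- 0
    list(miss = miss, maf = maf)
}

#' SNP-level quality-control filter
#'
#' Removes SNPs with missing rate above \code{max_missing}, minor-allele
#' frequency below \code{min_maf}, or Hardy-Weinberg exact-test p-value
#' below \code{hwe_alpha} (defaults 0.1 / 0.05 / 1e-6). The HWE test is
#' computed on controls only when status is available (set
#' \code{hwe_controls_only = FALSE} to use all samples). A removal report
#' is stored in \code{metadata(x)$snp_filter}.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param max_missing maximum tolerated per-SNP missing rate.
#' @param min_maf minimum minor-allele frequency (computed over observed
#'   calls, after any re-orientation of the counted allele).
#' @param hwe_alpha HWE exact-test significance cutoff.
#' @param hwe_controls_only compute the HWE test on controls only.
#' @return The filtered \linkS4class{GenotypeData}.
#' @export
filterSnps <- function(geno, max_missing = 0.1, min_maf = 0.05,
                       hwe_alpha = 1e-6, hwe_controls_only = TRUE) {
    stopifnot(max_missing > 0, max_missing < 1, min_maf > 0, min_maf < 1,
              hwe_alpha > 0, hwe_alpha < 1)
    calls <- genoCalls(geno)
    st <- .snp_stats(calls)
    status <- sampleInfo(geno)$status
    hwe_calls <- calls
    if (hwe_controls_only && !is.null(status) && any(status == 0L,
                                                     na.rm = TRUE))
        hwe_calls <- calls[, which(status == 0L), drop = FALSE]
    hwe_p <- vapply(seq_len(nrow(calls)), function(i) {
        g <- hwe_calls[i, ]
        g <- g[!is.na(g)]
        if (!length(g)) return(1)
        hweExactTest(sum(g == 0L), sum(g == 1L), sum(g == 2L))
    }, numeric(1))

    fail_miss <- st$miss > max_missing
    fail_maf <- st$maf < min_maf
    fail_hwe <- hwe_p < hwe_alpha
    keep <- !(fail_miss | fail_maf | fail_hwe)
    if (!any(keep)) warning("no SNPs pass the filters")
    out <- geno[keep, ]
    metadata(out)$snp_filter <- list(
        n_input = nrow(calls), n_kept = sum(keep),
        n_fail_missing = sum(fail_miss), n_fail_maf = sum(fail_maf),
        n_fail_hwe = sum(fail_hwe),
        thresholds = c(max_missing = max_missing, min_maf = min_maf,
                       hwe_alpha = hwe_alpha))
    out
}

#' Sample-level quality-control filter
#'
#' Removes samples with genotype missing rate above \code{max_missing}
#' (default 0.2) or heterozygosity rate more than \code{het_sd} standard
#' deviations (default 3) from the mean rate. Heterozygosity rate is the
#' fraction of heterozygous calls among non-missing calls. If the
#' heterozygosity SD is zero the z-scores are undefined and no sample is
#' removed on that rule.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param max_missing maximum per-sample missing rate.
#' @param het_sd heterozygosity z-score cutoff (> 0).
#' @return The filtered \linkS4class{GenotypeData}; removal counts in
#'   \code{metadata(x)$sample_filter}.
#' @export
filterSamples <- function(geno, max_missing = 0.2, het_sd = 3) {
    stopifnot(het_sd > 0)
    calls <- genoCalls(geno)
    miss <- colMeans(is.na(calls))
    het <- colSums(calls == 1L, na.rm = TRUE) / colSums(!is.na(calls))
    s <- sd(het)
    fail_het <- if (is.na(s) || s == 0) rep(FALSE, length(het)) else
        abs(het - mean(het)) > het_sd * s
    fail_miss <- miss > max_missing
    keep <- !(fail_miss | fail_het)
    out <- geno[, keep]
    metadata(out)$sample_filter <- list(
        n_input = ncol(calls), n_kept = sum(keep),
        n_fail_missing = sum(fail_miss), n_fail_het = sum(fail_het))
    out
}

#' Select SNPs by deleteriousness annotation
#'
#' Keeps SNPs annotated within \code{max_gene_distance} of a
#' protein-coding gene and with deleteriousness score at least
#' \code{min_score} (defaults 5 kb / 15, CADD-like). SNPs absent from
#' the annotation table are dropped.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param annot data.frame with columns \code{snp_id},
#'   \code{nearest_gene}, \code{gene_distance} (bp, >= 0) and
#'   \code{deleteriousness_score}.
#' @param min_score minimum score to keep a SNP.
#' @param max_gene_distance maximum distance to the nearest gene (bp).
#' @return The filtered \linkS4class{GenotypeData}.
#' @export
selectByAnnotation <- function(geno, annot, min_score = 15,
                               max_gene_distance = 5000) {
    stopifnot(all(c("snp_id", "gene_distance",
                    "deleteriousness_score") %in% names(annot)))
    if (nrow(annot) && any(annot$gene_distance < 0))
        stop("gene distances must be non-negative")
    ok <- annot$deleteriousness_score >= min_score &
        annot$gene_distance <= max_gene_distance
    keep_ids <- annot$snp_id[ok]
    keep <- snpInfo(geno)$snp %in% keep_ids
    if (!any(keep))
        warning("no SNPs retained by annotation selection")
    geno[keep, ]
}

#' Composite LD between two SNPs
#'
#' Squared Pearson correlation of genotype dosages over
#' pairwise-complete samples.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param snp_a,snp_b SNP identifiers or row indices.
#' @return r-squared, or \code{NA} (with a warning) when fewer than two
#'   complete pairs exist or either dosage is constant.
#' @export
ldR2 <- function(geno, snp_a, snp_b) {
    calls <- genoCalls(geno)
    ia <- if (is.character(snp_a)) match(snp_a, snpInfo(geno)$snp) else snp_a
    ib <- if (is.character(snp_b)) match(snp_b, snpInfo(geno)$snp) else snp_b
    if (is.na(ia) || is.na(ib)) stop("SNP not found")
    x <- calls[ia, ]; y <- calls[ib, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) {
        warning("fewer than 2 complete pairs; LD undefined")
        return(NA_real_)
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        warning("constant genotype; LD undefined")
        return(NA_real_)
    }
    cor(x[ok], y[ok])^2
}

#' Principal components of the genotype matrix
#'
#' Top-k principal components of the mean-imputed, standardized
#' (unit-variance) genotype matrix, as used for ancestry covariates.
#' The sign of each axis is fixed so its largest-magnitude SNP loading
#' is positive.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param k number of components.
#' @return samples x k matrix of coordinates (columns \code{PC1}, ...);
#'   \code{k = 0} returns a zero-column matrix.
#' @export
genotypePca <- function(geno, k = 3L) {
    calls <- genoCalls(geno)
    n <- ncol(calls)
    if (k == 0L)
        return(matrix(numeric(0), nrow = n, ncol = 0L,
                      dimnames = list(colnames(calls), NULL)))
    X <- t(calls)                               # samples x SNPs
    mu <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
    s <- apply(X, 2L, sd)
    X <- sweep(sweep(X, 2L, mu), 2L, pmax(s, 1e-12), "/")
    keep <- s > 0
    X <- X[, keep, drop = FALSE]
    if (k > min(dim(X))) stop("k exceeds the rank of the genotype matrix")
    pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
    flip <- vapply(seq_len(k), function(j) {
        l <- pc$rotation[, j]
        sign(l[which.max(abs(l))])
    }, numeric(1))
    out <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
    colnames(out) <- paste0("PC", seq_len(k))
    rownames(out) <- colnames(calls)
    out
}

#' Attach genotype principal components as sample covariates
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param k number of components (default 3).
#' @return \code{geno} with \code{PC1..PCk} columns in its sample table.
#' @export
addPcaCovariates <- function(geno, k = 3L) {
    pcs <- genotypePca(geno, k)
    sa <- as.data.frame(sampleInfo(geno))
    for (j in seq_len(k)) sa[[paste0("PC", j)]] <- pcs[, j]
    sampleInfo(geno) <- sa
    geno
}
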