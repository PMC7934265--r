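# Main-effect scan and exhaustive pairwise epistasis screening.

.resolve_snp <- function(geno, snp) {
    i <- if (is.character(snp)) match(snp, snpInfo(geno)$snp) else as.integer(snp)
    if (is.na(i) || i < 1L || i > nSnps(geno)) stop("SNP not found: ", snp)
    i
}

.status_vector <- function(geno) {
    st <- sampleInfo(geno)$status
    if (is.null(st)) stop("sample table has no 'status' column")
    as.integer(st)
}

#' Build the 3x3x2 genotype-by-status table for a SNP pair
#'
#' Counts pairwise-complete samples (both genotypes observed, status
#' known) into the 18 cells of a \linkS4class{JointTable}. The default
#' engine encodes each genotype class as a 64-bit-word bit-plane and
#' counts cells as popcounts of plane conjunctions; \code{method =
#' "naive"} tallies sample-by-sample in R. The two engines agree exactly.
#'
#' @param geno a \linkS4class{GenotypeData} with a \code{status} column.
#' @param snp_a,snp_b SNP identifiers or row indices.
#' @param method counting engine.
#' @return A \linkS4class{JointTable}.
#' @export
buildJointTable <- function(geno, snp_a, snp_b,
                            method = c("bitwise", "naive")) {
    method <- match.arg(method)
    ia <- .resolve_snp(geno, snp_a); ib <- .resolve_snp(geno, snp_b)
    calls <- genoCalls(geno)
    status <- .status_vector(geno)
    ids <- snpInfo(geno)$snp
    if (method == "bitwise") {
        cnt <- .joint_table_cpp(calls, status, ia, ib)
    } else {
        g1 <- calls[ia, ]; g2 <- calls[ib, ]
        ok <- !is.na(g1) & !is.na(g2) & !is.na(status)
        cnt <- numeric(18)
        for (j in which(ok)) {
            k <- g1[j] + 3L * g2[j] + 9L * status[j] + 1L
            cnt[k] <- cnt[k] + 1
        }
    }
    JointTable(array(cnt, dim = c(3L, 3L, 2L)), ids[ia], ids[ib])
}

#' Minimum-cell-count filter for a SNP pair
#'
#' A pair is excluded when any of the 18 cells of its 3x3x2
#' genotype-by-status table holds fewer than \code{min_cell}
#' observations (default 3).
#'
#' @param table a \linkS4class{JointTable}.
#' @param min_cell minimum per-cell count.
#' @return \code{TRUE} if the pair is excluded.
#' @export
cellFilter <- function(table, min_cell = 3L) {
    stopifnot(min_cell >= 0)
    any(jointCounts(table) < min_cell)
}

#' BOOST interaction test
#'
#' Likelihood-ratio statistic 2*(l_sat - l_hom) comparing the saturated
#' log-linear model of the 3x3x2 table against the homogeneous-
#' association model (all two-way terms, no three-way term), the latter
#' maximized by iterative proportional fitting; p-value from chi-square
#' with 4 df.
#'
#' @param table a \linkS4class{JointTable} (should pass [cellFilter()]).
#' @param tol IPF convergence tolerance on cell changes.
#' @param max_sweeps IPF sweep limit; non-convergence is an error that
#'   echoes the table.
#' @return list with \code{stat}, \code{p}, \code{df}.
#' @export
boostTest <- function(table, tol = 1e-8, max_sweeps = 10000L) {
    r <- .boost_stat_cpp(as.numeric(jointCounts(table)), tol, max_sweeps)
    if (!r$converged)
        stop("IPF did not converge in ", max_sweeps, " sweeps; counts: ",
             paste(as.numeric(jointCounts(table)), collapse = ","))
    list(stat = r$stat, p = pchisq(r$stat, df = 4, lower.tail = FALSE),
         df = 4L)
}

#' Additive logistic-regression interaction test
#'
#' Fits \code{logit(status) ~ g_a + g_b + g_a:g_b} with additive dosage
#' coding (no covariates at the screening stage) and returns the 1-df
#' likelihood-ratio p for the product term. The fit uses the 18 cell
#' counts, which carry the full likelihood for this model.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param snp_a,snp_b SNP identifiers or row indices.
#' @param table optionally, a precomputed \linkS4class{JointTable}
#'   (overrides \code{geno}/\code{snp_a}/\code{snp_b}).
#' @return list with \code{stat}, \code{p} (NA with a \code{reason} on
#'   non-convergence), \code{df}, \code{beta_int}.
#' @export
logisticInteractionTest <- function(geno = NULL, snp_a = NULL, snp_b = NULL,
                                    table = NULL) {
    if (is.null(table)) table <- buildJointTable(geno, snp_a, snp_b)
    r <- .logistic_lrt_cpp(as.numeric(jointCounts(table)))
    if (!isTRUE(r$converged))
        return(list(stat = NA_real_, p = NA_real_, df = 1L,
                    beta_int = NA_real_, reason = "non-convergence"))
    list(stat = r$stat, p = pchisq(r$stat, df = 1, lower.tail = FALSE),
         df = 1L, beta_int = r$beta_int, reason = NULL)
}

#' Joint-effects interaction test
#'
#' Compares the case and control vectors of the four log odds ratios of
#' the 2x2 subtables anchored at genotype cell (0,0) with a delta-method
#' covariance; the quadratic form is referred to chi-square with 4 df.
#' With the default cell filter (min 3) all anchored cells are positive;
#' \code{haldane = TRUE} adds 0.5 to every cell for use below that
#' threshold.
#'
#' @param table a \linkS4class{JointTable}.
#' @param haldane apply the Haldane-Anscombe +0.5 correction.
#' @return list with \code{stat}, \code{p} (NA with \code{reason} when a
#'   needed cell is empty or the covariance is singular), \code{df}.
#' @export
jointEffectsTest <- function(table, haldane = FALSE) {
    r <- .joint_stat_cpp(as.numeric(jointCounts(table)), haldane)
    if (!isTRUE(r$ok))
        return(list(stat = NA_real_, p = NA_real_, df = 4L,
                    reason = r$reason))
    list(stat = r$stat, p = pchisq(r$stat, df = 4, lower.tail = FALSE),
         df = 4L, reason = NULL)
}

.covariate_matrix <- function(geno, covariates) {
    sa <- as.data.frame(sampleInfo(geno))
    if (is.null(covariates))
        covariates <- intersect(c("sex", "age", "batch", "PC1", "PC2", "PC3"),
                                names(sa))
    covariates <- covariates[covariates %in% names(sa)]
    if (!length(covariates))
        return(matrix(1, nrow = nrow(sa), ncol = 1,
                      dimnames = list(NULL, "(Intercept)")))
    df <- sa[, covariates, drop = FALSE]
    for (v in intersect(c("sex", "batch"), covariates))
        df[[v]] <- factor(df[[v]])
    stats::model.matrix(~ ., data = df)
}

#' Per-SNP main-effect association scan
#'
#' Covariate-adjusted logistic regression of status on each SNP's
#' minor-allele dosage (1-df Wald test). Covariates default to whichever
#' of sex, age, batch and the first three principal components are
#' present in the sample table. Genomic inflation lambda
#' (median Wald chi-square / 0.456) is attached as an attribute.
#'
#' @param geno a \linkS4class{GenotypeData} with \code{status}.
#' @param covariates character vector of sample-table columns, or
#'   \code{NULL} for the default set.
#' @return data.frame with \code{snp}, \code{beta}, \code{se},
#'   \code{stat} (Wald chi-square), \code{p}, and \code{flag}
#'   (\code{"ok"}, \code{"constant"}, or \code{"unreliable"} under
#'   separation); attribute \code{lambda}.
#' @export
mainEffectScan <- function(geno, covariates = NULL) {
    calls <- genoCalls(geno)
    status <- .status_vector(geno)
    if (sum(status == 0L, na.rm = TRUE) < 2L ||
        sum(status == 1L, na.rm = TRUE) < 2L)
        stop("need at least 2 samples of each status")
    C <- .covariate_matrix(geno, covariates)
    m <- nrow(calls)
    out <- data.frame(snp = snpInfo(geno)$snp, beta = NA_real_,
                      se = NA_real_, stat = NA_real_, p = NA_real_,
                      flag = "ok", stringsAsFactors = FALSE)
    for (i in seq_len(m)) {
        g <- calls[i, ]
        ok <- !is.na(g) & !is.na(status) & stats::complete.cases(C)
        if (length(unique(g[ok])) < 2L) {
            out$flag[i] <- "constant"
            next
        }
        X <- cbind(C[ok, , drop = FALSE], g = g[ok])
        fit <- suppressWarnings(
            stats::glm.fit(X, status[ok], family = binomial()))
        p <- fit$rank
        R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
        R[lower.tri(R)] <- 0
        covmat <- tryCatch(chol2inv(R), error = function(e) NULL)
        j <- ncol(X)                            # dosage is the last column
        pos <- which(fit$qr$pivot[seq_len(p)] == j)
        if (is.null(covmat) || !length(pos)) {
            out$flag[i] <- "unreliable"
            next
        }
        beta <- fit$coefficients[j]
        se <- sqrt(covmat[pos, pos])
        out$beta[i] <- beta
        out$se[i] <- se
        out$stat[i] <- (beta / se)^2
        out$p[i] <- pchisq(out$stat[i], 1, lower.tail = FALSE)
        if (!fit$converged || abs(beta) > 15 || se > 100)
            out$flag[i] <- "unreliable"
    }
    attr(out, "lambda") <- median(out$stat[out$flag == "ok"],
                                  na.rm = TRUE) / 0.456
    out
}

#' Exhaustive pairwise epistasis screen
#'
#' Iterates all C(m, 2) SNP pairs: builds each 3x3x2 table by bit-plane
#' counting, applies the minimum-cell filter, computes the requested
#' interaction statistics, converts them to p-values, and
#' Benjamini-Hochberg-adjusts over the pooled family of all valid
#' (pair, method) tests (per-method families via
#' \code{fdr_pooled = FALSE}). Rows with p above \code{p_report} are
#' dropped from the returned table, but the FDR adjustment always uses
#' the full family.
#'
#' @param geno a post-QC \linkS4class{GenotypeData} with \code{status}.
#' @param methods subset of \code{c("logistic", "boost", "joint")}.
#' @param min_cell minimum cell count (default 3).
#' @param p_report only pairs with p <= this are returned (default 1:
#'   everything).
#' @param fdr_pooled pool the three methods into one BH family.
#' @return \code{DataFrame} with columns \code{snp_a}, \code{chr_a},
#'   \code{pos_a}, \code{snp_b}, \code{chr_b}, \code{pos_b},
#'   \code{method}, \code{stat}, \code{p}, \code{fdr}, sorted by p
#'   (ties stable by snp_a, snp_b, method); \code{metadata()} holds
#'   \code{n_pairs}, \code{n_cell_filtered} and \code{n_valid_tests}.
#' @export
screenAllPairs <- function(geno, methods = c("logistic", "boost", "joint"),
                           min_cell = 3L, p_report = 1, fdr_pooled = TRUE) {
    methods <- match.arg(methods, several.ok = TRUE)
    calls <- genoCalls(geno)
    status <- .status_vector(geno)
    raw <- .screen_pairs_cpp(calls, status, as.integer(min_cell),
                             "logistic" %in% methods,
                             "boost" %in% methods,
                             "joint" %in% methods)
    si <- as.data.frame(snpInfo(geno))
    cell_ok <- raw[, "min_cell"] >= min_cell
    dfs <- list(logistic = 1, boost = 4, joint = 4)
    pieces <- lapply(methods, function(mth) {
        stat <- raw[, paste0("stat_", mth)]
        data.frame(a = raw[, "a"], b = raw[, "b"], method = mth,
                   stat = stat,
                   p = pchisq(stat, df = dfs[[mth]], lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, pieces)
    valid <- !is.na(res$p)
    res$fdr <- NA_real_
    if (fdr_pooled) {
        res$fdr[valid] <- p.adjust(res$p[valid], method = "BH")
    } else {
        for (mth in methods) {
            sel <- valid & res$method == mth
            res$fdr[sel] <- p.adjust(res$p[sel], method = "BH")
        }
    }
    n_valid <- sum(valid)
    res <- res[valid & res$p <= p_report, , drop = FALSE]
    out <- S4Vectors::DataFrame(
        snp_a = si$snp[res$a], chr_a = si$chr[res$a], pos_a = si$pos[res$a],
        snp_b = si$snp[res$b], chr_b = si$chr[res$b], pos_b = si$pos[res$b],
        method = res$method, stat = res$stat, p = res$p, fdr = res$fdr)
    ord <- order(out$p, out$snp_a, out$snp_b, out$method)
    out <- out[ord, ]
    S4Vectors::metadata(out) <- list(
        n_pairs = nrow(raw), n_cell_filtered = sum(!cell_ok),
        n_valid_tests = n_valid, min_cell = min_cell,
        methods = methods, fdr_pooled = fdr_pooled)
    out
}

#' Benjamini-Hochberg adjustment over a screening result
#'
#' Recomputes the \code{fdr} column of a results table by BH step-up
#' over its p-values. \code{n_tests} overrides the family size when the
#' table is a subset of a larger valid-test family (tests removed by the
#' cell filter are never part of the family).
#'
#' @param results data.frame/DataFrame with a \code{p} column.
#' @param n_tests total valid tests in the family (default:
#'   \code{nrow(results)}).
#' @return \code{results} with its \code{fdr} column replaced.
#' @export
fdrAdjust <- function(results, n_tests = NULL) {
    if (is.null(n_tests)) n_tests <- sum(!is.na(results$p))
    results$fdr <- p.adjust(results$p, method = "BH", n = n_tests)
    results
}

#' Prune screened pairs by linkage disequilibrium
#'
#' Drops rows whose SNP pair has dosage r-squared above \code{max_r2}
#' (default 0.2). Pairs with undefined LD are kept with a warning. The
#' computed r-squared is recorded in an \code{ld_r2} column.
#'
#' @param results output of [screenAllPairs()].
#' @param geno the \linkS4class{GenotypeData} the screen was run on.
#' @param max_r2 LD threshold.
#' @return The pruned results table.
#' @export
prunePairsByLd <- function(results, geno, max_r2 = 0.2) {
    if (!nrow(results)) { results$ld_r2 <- numeric(0); return(results) }
    key <- paste(results$snp_a, results$snp_b)
    uk <- unique(key)
    r2 <- setNames(vapply(uk, function(k) {
        ab <- strsplit(k, " ", fixed = TRUE)[[1]]
        suppressWarnings(ldR2(geno, ab[1], ab[2]))
    }, numeric(1)), uk)
    results$ld_r2 <- unname(r2[key])
    undef <- is.na(results$ld_r2)
    if (any(undef))
        warning(sum(undef), " pair(s) with undefined LD retained")
    keep <- undef | results$ld_r2 <= max_r2
    out <- results[keep, ]
    S4Vectors::metadata(out) <- c(S4Vectors::metadata(results),
                                  list(n_ld_pruned = sum(!keep)))
    out
}

#' Post-hoc covariate-adjusted genotypic test
#'
#' Likelihood-ratio test of the logistic model with indicator terms for
#' the joint-genotype cells (reference cell (0,0)) plus covariates
#' against the covariates-only model. Cells absent from the data
#' collapse out of the model and the df is reduced accordingly.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param snp_a,snp_b SNP identifiers or row indices.
#' @param covariates sample-table columns to adjust for (\code{NULL} =
#'   the default set of [mainEffectScan()]; \code{character(0)} = none).
#' @return list with \code{stat}, \code{df}, \code{p} and
#'   \code{n_cells_observed}.
#' @export
posthocGenotypicTest <- function(geno, snp_a, snp_b, covariates = NULL) {
    ia <- .resolve_snp(geno, snp_a); ib <- .resolve_snp(geno, snp_b)
    calls <- genoCalls(geno)
    status <- .status_vector(geno)
    C <- .covariate_matrix(geno, covariates)
    g1 <- calls[ia, ]; g2 <- calls[ib, ]
    ok <- !is.na(g1) & !is.na(g2) & !is.na(status) & stats::complete.cases(C)
    cell <- factor(paste0(g1[ok], ":", g2[ok]),
                   levels = as.vector(outer(0:2, 0:2,
                                            function(a, b) paste0(a, ":", b))))
    cell <- droplevels(cell)
    Xc <- C[ok, , drop = FALSE]
    Xf <- cbind(Xc, stats::model.matrix(~ cell)[, -1, drop = FALSE])
    y <- status[ok]
    f0 <- suppressWarnings(stats::glm.fit(Xc, y, family = binomial()))
    f1 <- suppressWarnings(stats::glm.fit(Xf, y, family = binomial()))
    df <- f1$rank - f0$rank
    stat <- f0$deviance - f1$deviance
    list(stat = stat, df = df,
         p = pchisq(stat, df = df, lower.tail = FALSE),
         n_cells_observed = nlevels(cell))
}
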