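# Risk-score layer: MDR effect tables, PRS / ERS / CRS, permutation
# selection of predictive interactions.

#' Per-cell effect sizes and MDR labels for an interaction
#'
#' For each of the 9 joint-genotype cells, the effect size is the
#' natural-log odds ratio of the 2x2 table (cell cases, cell controls)
#' vs (cases in all other cells, controls in all other cells). A cell is
#' labelled high-risk when its case:control ratio exceeds the overall
#' case:control ratio of the table (the MDR threshold T). With
#' \code{or_type = "cell_vs_reference"} the odds ratio is instead taken
#' against the (0,0) reference cell.
#'
#' @param table a \linkS4class{JointTable}, normally one that passes
#'   [cellFilter()] so that every cell has cases and controls.
#' @param or_type odds-ratio definition.
#' @return An \linkS4class{EffectTable}.
#' @export
estimateEffectTable <- function(table,
                                or_type = c("cell_vs_rest",
                                            "cell_vs_reference")) {
    or_type <- match.arg(or_type)
    cnt <- jointCounts(table)
    ctrl <- cnt[, , 1L]; case <- cnt[, , 2L]
    tot_case <- sum(case); tot_ctrl <- sum(ctrl)
    logOR <- matrix(NA_real_, 3L, 3L)
    for (a in 1:3) for (b in 1:3) {
        if (or_type == "cell_vs_rest") {
            rc <- tot_case - case[a, b]; rr <- tot_ctrl - ctrl[a, b]
            if (case[a, b] > 0 && ctrl[a, b] > 0 && rc > 0 && rr > 0)
                logOR[a, b] <- log((case[a, b] / ctrl[a, b]) / (rc / rr))
        } else {
            if (case[a, b] > 0 && ctrl[a, b] > 0 &&
                case[1, 1] > 0 && ctrl[1, 1] > 0)
                logOR[a, b] <- log((case[a, b] / ctrl[a, b]) /
                                   (case[1, 1] / ctrl[1, 1]))
        }
    }
    threshold <- tot_case / tot_ctrl
    ratio <- case / ctrl                         # Inf where ctrl = 0
    high <- ratio > threshold
    high[is.na(high)] <- FALSE                   # 0/0 cells: low risk
    methods::new("EffectTable", snpA = table@snpA, snpB = table@snpB,
                 logOR = logOR, highRisk = high, threshold = threshold)
}

.orient_dosage <- function(geno, snp_idx, effect_allele) {
    si <- snpInfo(geno)
    g <- genoCalls(geno)[snp_idx, ]
    if (effect_allele == si$a1[snp_idx]) return(g)
    if (effect_allele == si$a2[snp_idx]) return(2L - g)
    NULL
}

#' Polygenic risk score
#'
#' PRS_j = sum_i G_ij * E_i / N_j, where G_ij counts the effect allele,
#' E_i is the per-allele log odds ratio, and N_j is the number of weight
#' SNPs with an observed genotype for sample j (per-sample denominator).
#' Effect alleles are resolved against the counted/other alleles of the
#' genotype data; weights whose effect allele matches neither are
#' skipped with a warning.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param weights data.frame with columns \code{snp_id},
#'   \code{effect_allele}, \code{effect_size}.
#' @return named numeric vector of per-sample scores (\code{NA} for
#'   samples missing every weight SNP), with attribute \code{n_snps_used}
#'   giving the per-sample N_j.
#' @export
computePRS <- function(geno, weights) {
    stopifnot(all(c("snp_id", "effect_allele", "effect_size") %in%
                  names(weights)))
    si <- snpInfo(geno)
    idx <- match(weights$snp_id, si$snp)
    if (all(is.na(idx))) stop("no weight SNPs found in the genotype data")
    n <- nSamples(geno)
    num <- rep(0, n); denom <- rep(0L, n)
    skipped <- character(0)
    for (w in which(!is.na(idx))) {
        g <- .orient_dosage(geno, idx[w], weights$effect_allele[w])
        if (is.null(g)) { skipped <- c(skipped, weights$snp_id[w]); next }
        ok <- !is.na(g)
        num[ok] <- num[ok] + g[ok] * weights$effect_size[w]
        denom[ok] <- denom[ok] + 1L
    }
    if (length(skipped))
        warning("effect allele matches neither allele for: ",
                paste(skipped, collapse = ", "))
    prs <- ifelse(denom > 0L, num / denom, NA_real_)
    names(prs) <- sampleInfo(geno)$sample_id
    attr(prs, "n_snps_used") <- denom
    prs
}

.cell_index <- function(geno, et) {
    ia <- match(et@snpA, snpInfo(geno)$snp)
    ib <- match(et@snpB, snpInfo(geno)$snp)
    if (is.na(ia) || is.na(ib)) return(NULL)
    calls <- genoCalls(geno)
    cbind(calls[ia, ] + 1L, calls[ib, ] + 1L)   # NA rows where missing
}

#' Epistasis risk score
#'
#' ERS_j = sum_i E_i[cell_ij] / N_j over interactions i: each sample
#' contributes exactly one cell per interaction (the cell its joint
#' genotype falls in), and N_j counts the interactions for which both
#' genotypes are observed and the cell effect is defined. Effect tables
#' must be estimated on data disjoint from the samples being scored.
#' Duplicate interactions (unordered pair identity) are dropped, first
#' occurrence kept.
#'
#' @param geno a \linkS4class{GenotypeData} to score.
#' @param effect_tables list of \linkS4class{EffectTable} objects.
#' @return named numeric vector of per-sample scores (\code{NA} where
#'   N_j = 0), with attribute \code{n_interactions_used}.
#' @export
computeERS <- function(geno, effect_tables) {
    if (!length(effect_tables)) stop("no effect tables supplied")
    key <- vapply(effect_tables, function(et)
        paste(sort(c(et@snpA, et@snpB)), collapse = "|"), character(1))
    effect_tables <- effect_tables[!duplicated(key)]
    n <- nSamples(geno)
    num <- rep(0, n); denom <- rep(0L, n)
    for (et in effect_tables) {
        ci <- .cell_index(geno, et)
        if (is.null(ci)) next
        e <- et@logOR[ci]                       # NA where genotype missing
        ok <- !is.na(e)
        num[ok] <- num[ok] + e[ok]
        denom[ok] <- denom[ok] + 1L
    }
    ers <- ifelse(denom > 0L, num / denom, NA_real_)
    names(ers) <- sampleInfo(geno)$sample_id
    attr(ers, "n_interactions_used") <- denom
    ers
}

#' Combined risk score
#'
#' CRS_j = w * PRS_j + (1 - w) * ERS_j; absent when either score is
#' absent.
#'
#' @param prs,ers per-sample score vectors (aligned).
#' @param w weight in [0, 1].
#' @return numeric vector of combined scores.
#' @export
computeCRS <- function(prs, ers, w) {
    stopifnot(w >= 0, w <= 1, length(prs) == length(ers))
    w * as.numeric(prs) + (1 - w) * as.numeric(ers)
}

#' Select the PRS/ERS mixing weight on a selection dataset
#'
#' Grid search over w in {0, step, ..., 1} maximizing the AUC of
#' CRS = w*PRS + (1-w)*ERS against status on the selection dataset
#' (which must be distinct from any dataset the chosen w is evaluated
#' on). Ties take the smallest w.
#'
#' @param prs,ers,status aligned per-sample vectors from the selection
#'   dataset.
#' @param step grid step (default 0.01).
#' @return list with \code{w}, \code{auc}, and the searched \code{grid}.
#' @export
selectW <- function(prs, ers, status, step = 0.01) {
    status <- as.integer(status)
    ok <- !is.na(prs) & !is.na(ers) & !is.na(status)
    if (length(unique(status[ok])) < 2L)
        stop("status is degenerate (single class)")
    grid <- seq(0, 1, by = step)
    aucs <- vapply(grid, function(w)
        rocAuc(computeCRS(prs[ok], ers[ok], w), status[ok]), numeric(1))
    best <- which(aucs >= max(aucs) - 1e-12)[1L]  # ties -> smallest w
    list(w = grid[best], auc = aucs[best],
         grid = data.frame(w = grid, auc = aucs))
}

#' MDR prediction from an effect table
#'
#' Predicts case (1) for samples whose joint-genotype cell carries the
#' high-risk MDR label, control (0) otherwise; depends only on cell
#' membership.
#'
#' @param effect_table an \linkS4class{EffectTable} trained on discovery
#'   data.
#' @param g1,g2 genotype vectors (0/1/2, \code{NA} allowed) at the two
#'   SNPs.
#' @return integer vector of predicted status (\code{NA} where either
#'   genotype is missing).
#' @export
mdrPredict <- function(effect_table, g1, g2) {
    stopifnot(length(g1) == length(g2))
    out <- rep(NA_integer_, length(g1))
    ok <- !is.na(g1) & !is.na(g2)
    out[ok] <- as.integer(effect_table@highRisk[cbind(g1[ok] + 1L,
                                                      g2[ok] + 1L)])
    out
}

.balanced_accuracy <- function(pred, status) {
    ok <- !is.na(pred) & !is.na(status)
    pred <- pred[ok]; status <- status[ok]
    n1 <- sum(status == 1L); n0 <- sum(status == 0L)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    sens <- sum(pred == 1L & status == 1L) / n1
    spec <- sum(pred == 0L & status == 0L) / n0
    (sens + spec) / 2
}

#' Permutation-based selection of predictive interactions
#'
#' For each candidate interaction an MDR model (an
#' \linkS4class{EffectTable}) is trained on the training dataset and its
#' predictions are evaluated by balanced accuracy on every test dataset.
#' A null distribution is obtained by permuting the prediction vector
#' \code{n_perm} times against the fixed labels; because a permuted
#' binary prediction only enters balanced accuracy through the number of
#' predicted positives landing on cases, the permuted metric is drawn
#' directly from that count's hypergeometric law. The permutation
#' p-value uses the add-one estimator (1 + #{null >= observed}) /
#' (1 + n_perm); an interaction is selected when p < \code{alpha} in
#' every test dataset.
#'
#' @param pairs two-column matrix/data.frame of SNP ids (or a screening
#'   result with \code{snp_a}/\code{snp_b} columns).
#' @param train \linkS4class{GenotypeData} used to fit the MDR models.
#' @param test_sets list of at least two \linkS4class{GenotypeData}
#'   objects with status.
#' @param n_perm permutations per test set (>= 100).
#' @param alpha per-test-set selection level.
#' @param seed integer seed; results are deterministic given it.
#' @return data.frame with one row per interaction: ids, observed
#'   balanced accuracy and permutation p per test set, and
#'   \code{selected}; interactions whose metric is undefined in some
#'   test set carry \code{NA} there and are not selected (reason in the
#'   \code{skipped} column).
#' @export
permutationSelect <- function(pairs, train, test_sets, n_perm = 10000L,
                              alpha = 0.05, seed = 1L) {
    stopifnot(length(test_sets) >= 2L, n_perm >= 100L)
    if (is(pairs, "DataFrame") || is.data.frame(pairs)) {
        if (all(c("snp_a", "snp_b") %in% colnames(pairs)))
            pairs <- cbind(as.character(pairs$snp_a),
                           as.character(pairs$snp_b))
        else pairs <- as.matrix(pairs)
    }
    key <- apply(pairs, 1L, function(r) paste(sort(r), collapse = "|"))
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    set.seed(seed)
    nt <- length(test_sets)
    tn <- if (!is.null(names(test_sets))) names(test_sets) else
        paste0("test", seq_len(nt))
    # hoist matrices out of the per-pair loop
    tr_calls <- genoCalls(train)
    tr_status <- .status_vector(train)
    tr_ids <- snpInfo(train)$snp
    ts_calls <- lapply(test_sets, genoCalls)
    ts_status <- lapply(test_sets, function(x) sampleInfo(x)$status)
    ts_ids <- lapply(test_sets, function(x) snpInfo(x)$snp)
    res <- data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2],
                      stringsAsFactors = FALSE)
    for (t in tn) {
        res[[paste0("ba_", t)]] <- NA_real_
        res[[paste0("p_", t)]] <- NA_real_
    }
    res$skipped <- ""
    for (i in seq_len(nrow(pairs))) {
        ia <- match(pairs[i, 1], tr_ids); ib <- match(pairs[i, 2], tr_ids)
        if (is.na(ia) || is.na(ib)) { res$skipped[i] <- "SNP absent"; next }
        g1 <- tr_calls[ia, ]; g2 <- tr_calls[ib, ]
        okr <- !is.na(g1) & !is.na(g2) & !is.na(tr_status)
        cnt <- tabulate(g1[okr] + 3L * g2[okr] + 9L * tr_status[okr] + 1L,
                        18L)
        et <- estimateEffectTable(JointTable(array(cnt, c(3L, 3L, 2L)),
                                             pairs[i, 1], pairs[i, 2]))
        for (t in seq_len(nt)) {
            ja <- match(pairs[i, 1], ts_ids[[t]])
            jb <- match(pairs[i, 2], ts_ids[[t]])
            if (is.na(ja) || is.na(jb)) {
                res$skipped[i] <- "SNP absent"
                next
            }
            status <- ts_status[[t]]
            h1 <- ts_calls[[t]][ja, ]; h2 <- ts_calls[[t]][jb, ]
            pred <- rep(NA_integer_, length(h1))
            use <- !is.na(h1) & !is.na(h2)
            pred[use] <- as.integer(et@highRisk[cbind(h1[use] + 1L,
                                                      h2[use] + 1L)])
            obs <- .balanced_accuracy(pred, status)
            if (is.na(obs)) {
                res$skipped[i] <- "metric undefined (single class)"
                next
            }
            keep <- !is.na(pred) & !is.na(status)
            n1 <- sum(status[keep] == 1L); n0 <- sum(status[keep] == 0L)
            m1 <- sum(pred[keep] == 1L)
            # permuted predictions: k = #(pred==1 landing on cases)
            k <- rhyper(n_perm, m1, n0 + n1 - m1, n1)
            null_ba <- (k / n1 + (n0 - (m1 - k)) / n0) / 2
            p <- (1 + sum(null_ba >= obs)) / (1 + n_perm)
            res[[paste0("ba_", tn[t])]][i] <- obs
            res[[paste0("p_", tn[t])]][i] <- p
        }
    }
    pcols <- paste0("p_", tn)
    res$selected <- Reduce(`&`, lapply(pcols, function(cc)
        !is.na(res[[cc]]) & res[[cc]] < alpha))
    res
}
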