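# Survival stratification, ROC/AUC, correlations, and summary-statistic
# tests for cohort tables.

#' Assign samples to risk-score quantile groups
#'
#' Splits samples into \code{q} near-equal groups by score rank (group 1
#' = lowest scores). Ties are broken by stable input order; group sizes
#' differ by at most one. All-tied scores still yield size-balanced
#' groups, with a warning.
#'
#' @param scores finite numeric vector.
#' @param q number of groups (>= 2).
#' @return integer vector of group labels 1..q.
#' @export
assignQuantiles <- function(scores, q = 4L) {
    stopifnot(q >= 2L)
    n <- length(scores)
    if (n < q) stop("fewer samples than groups")
    if (any(!is.finite(scores))) stop("scores must be finite")
    if (length(unique(scores)) == 1L)
        warning("all scores tied; groups assigned by input order")
    ord <- order(scores)                        # stable for ties
    sizes <- rep(n %/% q, q)
    extra <- n %% q
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    labels <- integer(n)
    labels[ord] <- rep(seq_len(q), times = sizes)
    labels
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right censoring (backed by
#' \code{survival::survfit}); the returned curve starts at S(0) = 1.
#'
#' @param time follow-up times (onset age for events, last-record age
#'   for censored subjects); must be positive.
#' @param event 1 = event observed, 0 = censored.
#' @return data.frame with \code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv}.
#' @export
kaplanMeier <- function(time, event) {
    stopifnot(length(time) == length(event), all(time > 0, na.rm = TRUE))
    if (!any(event == 1, na.rm = TRUE)) {
        ut <- sort(unique(time))
        return(data.frame(time = ut,
                          n_risk = vapply(ut, function(t) sum(time >= t),
                                          numeric(1)),
                          n_event = 0, surv = 1))
    }
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv)
}

#' K-group log-rank test
#'
#' @param time,event as in [kaplanMeier()].
#' @param group group labels (>= 2 distinct values).
#' @return list with \code{chi2}, \code{df} (k - 1), \code{p}.
#' @export
logrankTest <- function(time, event, group) {
    group <- as.factor(group)
    if (nlevels(droplevels(group)) < 2L) stop("need at least two groups")
    if (!any(event == 1, na.rm = TRUE)) stop("need at least one event")
    fit <- survival::survdiff(survival::Surv(time, event) ~ group)
    df <- length(fit$n) - 1L
    list(chi2 = fit$chisq, df = df,
         p = pchisq(fit$chisq, df = df, lower.tail = FALSE))
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: AUC = U / (n1 * n0), ties counted one half — the
#' probability that a random case outscores a random control.
#'
#' @param scores numeric risk scores.
#' @param status binary status (1 = case).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, status) {
    status <- as.integer(status)
    ok <- !is.na(scores) & !is.na(status)
    scores <- scores[ok]; status <- status[ok]
    n1 <- sum(status == 1L); n0 <- sum(status == 0L)
    if (n1 == 0L || n0 == 0L) stop("both classes must be present")
    r <- rank(scores, ties.method = "average")
    (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson correlation on pairwise-complete data
#'
#' @param x,y numeric vectors.
#' @return list with \code{r}, \code{p} (two-sided t-based), \code{n};
#'   \code{r = NA} with a warning when either variable has zero
#'   variance.
#' @export
pearsonCorr <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) stop("need at least 3 complete pairs")
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        warning("zero variance; correlation undefined")
        return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' p = sum of hypergeometric probabilities of tables (at fixed margins)
#' whose probability does not exceed the observed table's. The table is
#' \code{rbind(c(a, b), c(c, d))}. A zero margin returns p = 1 with a
#' warning.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return the two-sided p-value.
#' @examples
#' fisherExact2x2(388, 176, 1060, 455)   # ~0.63
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    cnt <- c(a, b, c, d)
    if (any(cnt < 0) || any(cnt != round(cnt)))
        stop("counts must be non-negative integers")
    tab <- matrix(cnt, nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("zero margin; p = 1 by convention")
        return(1)
    }
    fisher.test(tab)$p.value
}

#' Group summary (n, mean, sd)
#'
#' @param n group size (>= 2 unless sd is 0 information is degenerate).
#' @param mean,sd group mean and standard deviation (sd >= 0).
#' @return list of class \code{"GroupSummary"}.
#' @export
groupSummary <- function(n, mean, sd) {
    stopifnot(n >= 1, sd >= 0)
    structure(list(n = n, mean = mean, sd = sd), class = "GroupSummary")
}

#' Two-sample t-test from group summaries
#'
#' Welch (default) or pooled-variance two-sided t-test computed from
#' (n, mean, sd) only, as used to compare cohort characteristics.
#'
#' @param g1,g2 [groupSummary()] objects (or lists with n/mean/sd).
#' @param variant \code{"welch"} or \code{"pooled"}.
#' @return list with \code{stat}, \code{df}, \code{p}.
#' @examples
#' tTestFromSummaries(groupSummary(564, 90.92, 5.88),
#'                    groupSummary(1515, 88.10, 6.73))$p
#' @export
tTestFromSummaries <- function(g1, g2, variant = c("welch", "pooled")) {
    variant <- match.arg(variant)
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    if (variant == "welch") {
        se <- sqrt(v1 + v2)
        df <- (v1 + v2)^2 /
            (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
    } else {
        sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) /
            (g1$n + g2$n - 2)
        se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
        df <- g1$n + g2$n - 2
    }
    if (se == 0) return(list(stat = 0, df = df, p = 1))
    stat <- (g1$mean - g2$mean) / se
    list(stat = stat, df = df, p = 2 * pt(-abs(stat), df))
}

#' Pool group summaries
#'
#' Pooled n, weighted mean, and pooled SD combining within-group and
#' between-group variance:
#' s^2 = [sum (n_i - 1) s_i^2 + sum n_i (m_i - m)^2] / (N - 1).
#'
#' @param groups list of [groupSummary()] objects, or a data.frame with
#'   columns \code{n}, \code{mean}, \code{sd}.
#' @return a [groupSummary()] for the pooled sample.
#' @export
poolGroupSummaries <- function(groups) {
    if (is.data.frame(groups)) {
        n <- groups$n; m <- groups$mean; s <- groups$sd
    } else {
        n <- vapply(groups, `[[`, numeric(1), "n")
        m <- vapply(groups, `[[`, numeric(1), "mean")
        s <- vapply(groups, `[[`, numeric(1), "sd")
    }
    stopifnot(length(n) >= 1)
    N <- sum(n)
    if (length(n) == 1L) return(groupSummary(n, m, s))
    mbar <- sum(n * m) / N
    v <- (sum((n - 1) * s^2) + sum(n * (m - mbar)^2)) / (N - 1)
    groupSummary(N, mbar, sqrt(v))
}

#' Quantile-stratified survival evaluation of a risk score
#'
#' Convenience wrapper reproducing the risk-stratification design:
#' samples are split into \code{q} score quantiles, onset is compared
#' across quantiles by the log-rank test, and the score's AUC against
#' status is computed.
#'
#' @param scores per-sample risk scores.
#' @param status binary status.
#' @param time,event survival follow-up (see [kaplanMeier()]).
#' @param q number of quantile groups (default 4).
#' @return list with \code{group} labels, per-group KM curves
#'   (\code{km}), \code{logrank}, and \code{auc}.
#' @export
evaluateRiskScore <- function(scores, status, time, event, q = 4L) {
    ok <- !is.na(scores) & !is.na(time) & !is.na(event)
    grp <- rep(NA_integer_, length(scores))
    grp[ok] <- assignQuantiles(scores[ok], q)
    km <- lapply(seq_len(q), function(g)
        kaplanMeier(time[ok][grp[ok] == g], event[ok][grp[ok] == g]))
    names(km) <- paste0("Q", seq_len(q))
    lr <- logrankTest(time[ok], event[ok], grp[ok])
    auc <- rocAuc(scores[!is.na(scores) & !is.na(status)],
                  status[!is.na(scores) & !is.na(status)])
    list(group = grp, km = km, logrank = lr, auc = auc)
}
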