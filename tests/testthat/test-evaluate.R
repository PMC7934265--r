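test_that("quantile assignment balances group sizes with stable ties", {
    g <- assignQuantiles(c(5, 1, 3, 7, 2, 8, 4, 6), 4)
    expect_equal(as.integer(table(g)), rep(2L, 4))
    expect_equal(g[order(c(5, 1, 3, 7, 2, 8, 4, 6))], rep(1:4, each = 2))
    expect_warning(gt <- assignQuantiles(rep(1, 9), 3), "tied")
    expect_equal(as.integer(table(gt)), rep(3L, 3))
    # group means monotone in group index
    set.seed(48)
    x <- rnorm(101)
    gq <- assignQuantiles(x, 4)
    expect_true(all(diff(tapply(x, gq, mean)) > 0))
    expect_true(max(table(gq)) - min(table(gq)) <= 1)
    expect_error(assignQuantiles(c(1, 2), 4), "fewer samples")
})

test_that("Kaplan-Meier matches hand-computed product-limit values", {
    # classic 10-subject worked example: events at 6, 6, 6, 10, 13;
    # censored at 7, 9, 11, 15, 16
    time <- c(6, 6, 6, 7, 9, 10, 11, 13, 15, 16)
    event <- c(1, 1, 1, 0, 0, 1, 0, 1, 0, 0)
    km <- kaplanMeier(time, event)
    hand <- c(7 / 10, 7 / 10 * 4 / 5, 7 / 10 * 4 / 5 * 2 / 3)
    expect_equal(km$surv[km$n_event > 0], hand, tolerance = 1e-12)
    # no censoring: empirical survival function
    t2 <- c(1, 2, 3, 4, 5)
    km2 <- kaplanMeier(t2, rep(1, 5))
    expect_equal(km2$surv, 1 - (1:5) / 5, tolerance = 1e-12)
    # all censored: flat at 1
    km3 <- kaplanMeier(t2, rep(0, 5))
    expect_true(all(km3$surv == 1))
})

test_that("log-rank test matches the 2-group O-E form and detects hazard ratios", {
    # 6-subject hand computation, distinct event times
    time <- c(1, 2, 3, 4, 5, 6)
    event <- c(1, 1, 1, 1, 1, 1)
    grp <- c(1, 2, 1, 2, 1, 2)
    o_minus_e <- 0; v <- 0
    for (t_ in time[event == 1]) {
        at <- time >= t_
        n1 <- sum(at & grp == 1); n <- sum(at)
        d <- sum(time == t_ & event == 1)
        o1 <- sum(time == t_ & event == 1 & grp == 1)
        o_minus_e <- o_minus_e + (o1 - d * n1 / n)
        if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    hand <- o_minus_e^2 / v
    lr <- logrankTest(time, event, grp)
    expect_equal(lr$chi2, hand, tolerance = 1e-9)
    expect_equal(lr$df, 1L)
    # power under hazard ratio 2
    set.seed(49)
    hits <- 0L
    for (r in 1:10) {
        t1 <- rexp(200, 1); t2 <- rexp(200, 2)
        cens <- rexp(400, 0.2)
        tt <- pmin(c(t1, t2), cens); ev <- as.integer(c(t1, t2) <= cens)
        p <- logrankTest(tt, ev, rep(1:2, each = 200))$p
        hits <- hits + (p < 0.01)
    }
    expect_gte(hits, 9L)
    expect_error(logrankTest(time, event, rep(1, 6)), "two groups")
})

test_that("AUC equals the pairwise Mann-Whitney oracle with half ties", {
    set.seed(50)
    scores <- round(rnorm(50), 1)               # induce ties
    status <- rbinom(50, 1, 0.5)
    cases <- scores[status == 1]; ctrls <- scores[status == 0]
    oracle <- mean(outer(cases, ctrls, function(a, b)
        (a > b) + 0.5 * (a == b)))
    expect_equal(rocAuc(scores, status), oracle, tolerance = 1e-12)
    expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
    # invariance under strictly monotone transform
    expect_equal(rocAuc(exp(scores), status), oracle, tolerance = 1e-12)
    expect_error(rocAuc(scores, rep(1, 50)), "both classes")
    skip_if_not_installed("pROC")
    expect_equal(rocAuc(scores, status),
                 as.numeric(pROC::auc(pROC::roc(status, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
})

test_that("Pearson correlation recovers planted effects and flags degeneracy", {
    x <- c(1, 2, 3, 4)
    expect_equal(pearsonCorr(x, -x)$r, -1)
    set.seed(51)
    a <- rnorm(1e4); b <- rnorm(1e4)
    expect_lt(abs(pearsonCorr(a, b)$r), 0.05)
    # planted r = -0.4 at the CSF-study sample size
    n <- 1043; r <- -0.4
    z <- rnorm(n)
    y <- r * z + sqrt(1 - r^2) * rnorm(n)
    est <- pearsonCorr(z, y)
    expect_lt(abs(est$r - r), 0.06)
    expect_lt(est$p, 1e-10)
    expect_warning(pc <- pearsonCorr(rep(1, 10), rnorm(10)), "variance")
    expect_true(is.na(pc$r))
})

test_that("Fisher exact test reproduces cohort-table p-values and enumeration", {
    expect_equal(round(fisherExact2x2(388, 176, 1060, 455), 2), 0.63)
    expect_equal(round(fisherExact2x2(231, 324, 372, 492), 2), 0.62)
    expect_lt(fisherExact2x2(378, 186, 1226, 289), 1e-4)
    expect_lt(fisherExact2x2(201, 354, 568, 296), 1e-4)
    # enumeration oracle: sum of hypergeometric masses <= observed
    fisher_oracle <- function(a, b, c, d) {
        m <- a + b; n <- c + d; k <- a + c
        xs <- max(0, k - n):min(k, m)
        pr <- dhyper(xs, m, n, k)
        sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
    }
    set.seed(52)
    for (i in 1:25) {
        cnt <- sample(0:40, 4, replace = TRUE)
        if (sum(cnt[1:2]) == 0 || sum(cnt[3:4]) == 0 ||
            cnt[1] + cnt[3] == 0 || cnt[2] + cnt[4] == 0) next
        expect_equal(fisherExact2x2(cnt[1], cnt[2], cnt[3], cnt[4]),
                     fisher_oracle(cnt[1], cnt[2], cnt[3], cnt[4]),
                     tolerance = 1e-9)
    }
    expect_warning(p0 <- fisherExact2x2(0, 0, 5, 5), "zero margin")
    expect_equal(p0, 1)
})

test_that("summary t-tests match raw-data t-tests and print bounds", {
    expect_equal(tTestFromSummaries(groupSummary(10, 5, 2),
                                    groupSummary(10, 5, 2))$p, 1)
    expect_lt(tTestFromSummaries(groupSummary(564, 90.92, 5.88),
                                 groupSummary(1515, 88.10, 6.73))$p,
              0.0001)
    expect_lt(tTestFromSummaries(groupSummary(555, 74.78, 8.11),
                                 groupSummary(864, 77.49, 7.33))$p,
              0.0001)
    # construct raw samples hitting given summaries exactly
    set.seed(53)
    raw <- function(n, m, s) {
        x <- rnorm(n)
        m + s * (x - mean(x)) / sd(x)
    }
    x1 <- raw(40, 3.2, 1.1); x2 <- raw(55, 2.7, 1.6)
    ref <- t.test(x1, x2)                       # Welch
    got <- tTestFromSummaries(groupSummary(40, 3.2, 1.1),
                              groupSummary(55, 2.7, 1.6))
    expect_equal(got$stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    refp <- t.test(x1, x2, var.equal = TRUE)
    gotp <- tTestFromSummaries(groupSummary(40, 3.2, 1.1),
                               groupSummary(55, 2.7, 1.6), "pooled")
    expect_equal(gotp$p, refp$p.value, tolerance = 1e-10)
})

test_that("pooled summaries combine within- and between-group variance", {
    # identity on a single group; equal groups keep the common SD
    expect_equal(poolGroupSummaries(list(groupSummary(12, 3, 2)))$sd, 2)
    # equal groups, equal means: pooled SD ~ the common SD (exact up to
    # the (n-1)-denominator convention: sqrt(2(n-1)/(2n-1)) factor)
    two <- poolGroupSummaries(data.frame(n = c(30, 30), mean = c(5, 5),
                                         sd = c(1.5, 1.5)))
    expect_equal(two$sd, 1.5 * sqrt(2 * 29 / 59), tolerance = 1e-12)
    # oracle: pooling recomputed from raw data
    set.seed(54)
    g1 <- rnorm(40, 10, 2); g2 <- rnorm(60, 12, 3)
    pooled <- poolGroupSummaries(data.frame(
        n = c(40, 60), mean = c(mean(g1), mean(g2)),
        sd = c(sd(g1), sd(g2))))
    expect_equal(pooled$mean, mean(c(g1, g2)), tolerance = 1e-12)
    expect_equal(pooled$sd, sd(c(g1, g2)), tolerance = 1e-12)
})
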