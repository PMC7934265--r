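sim_pair_data <- function(n = 600, seed = 1, maf = c(0.3, 0.4)) {
    set.seed(seed)
    calls <- rbind(rbinom(n, 2, maf[1]), rbinom(n, 2, maf[2]),
                   rbinom(n, 2, 0.25))
    gd_from_calls(calls, status = rbinom(n, 1, 0.5))
}

test_that("bitwise contingency counting equals the naive tally exactly", {
    cfg <- simConfig(400, 30, missing_rate = 0.05, seed = 17)
    gd <- simulateDataset(cfg)
    set.seed(18)
    for (k in 1:60) {
        ab <- sample(30, 2)
        bw <- buildJointTable(gd, ab[1], ab[2])
        nv <- buildJointTable(gd, ab[1], ab[2], method = "naive")
        expect_identical(jointCounts(bw), jointCounts(nv))
    }
    # conservation: total = pairwise-complete sample count
    jt <- buildJointTable(gd, 1, 2)
    calls <- genoCalls(gd)
    expect_equal(sum(jointCounts(jt)),
                 sum(!is.na(calls[1, ]) & !is.na(calls[2, ])))
})

test_that("cell filter flags pairs with any sparse cell", {
    cnt <- array(5L, c(3, 3, 2))
    expect_false(cellFilter(JointTable(cnt), 3))
    cnt[2, 3, 1] <- 2L
    expect_true(cellFilter(JointTable(cnt), 3))
    expect_false(cellFilter(JointTable(cnt), 0))
    expect_false(cellFilter(JointTable(array(3L, c(3, 3, 2))), 3))
})

test_that("logistic interaction LRT matches the glm oracle", {
    set.seed(21)
    for (k in 1:40) {
        jt <- random_joint_table()
        cnt <- jointCounts(jt)
        d <- expand.grid(g1 = 0:2, g2 = 0:2)
        d$case <- as.vector(cnt[, , 2]); d$ctrl <- as.vector(cnt[, , 1])
        f1 <- glm(cbind(case, ctrl) ~ g1 * g2, binomial(), data = d)
        f0 <- glm(cbind(case, ctrl) ~ g1 + g2, binomial(), data = d)
        oracle <- f0$deviance - f1$deviance
        expect_equal(logisticInteractionTest(table = jt)$stat, oracle,
                     tolerance = 1e-6)
    }
})

test_that("BOOST statistic matches the log-linear glm oracle", {
    set.seed(22)
    for (k in 1:60) {
        jt <- random_joint_table()
        expect_equal(boostTest(jt)$stat,
                     boost_oracle(as.numeric(jointCounts(jt))),
                     tolerance = 1e-6)
    }
    # a table with purely multiplicative margins has zero statistic
    r <- c(2, 3, 4); s <- c(5, 2, 1); t_ <- c(1, 2)
    prod_tab <- outer(outer(r, s), t_) * 4
    bt <- boostTest(JointTable(prod_tab))
    expect_lt(bt$stat, 1e-6)
    expect_gt(bt$p, 0.999)
})

test_that("joint-effects statistic matches the delta-method oracle", {
    set.seed(23)
    for (k in 1:40) {
        jt <- random_joint_table()
        expect_equal(jointEffectsTest(jt)$stat,
                     joint_oracle(as.numeric(jointCounts(jt))),
                     tolerance = 1e-9)
    }
    # proportional case and control tables -> all log-ORs equal -> stat 0
    base <- matrix(c(40, 20, 10, 25, 30, 12, 9, 14, 22), 3, 3)
    jt0 <- JointTable(array(c(base, base * 2), c(3, 3, 2)))
    expect_lt(jointEffectsTest(jt0)$stat, 1e-9)
    # empty anchored cell without Haldane -> undefined with a reason
    cnt <- array(10L, c(3, 3, 2)); cnt[1, 1, 1] <- 0L
    bad <- jointEffectsTest(JointTable(cnt))
    expect_true(is.na(bad$p))
    expect_match(bad$reason, "zero")
    expect_false(is.na(jointEffectsTest(JointTable(cnt),
                                        haldane = TRUE)$p))
})

test_that("main-effect scan is calibrated and powered", {
    # 2000 null SNPs keep the sampling noise of the median chi-square
    # small enough for a 0.9-1.1 lambda window
    cfg <- simConfig(600, 2000, maf_range = c(0.1, 0.5),
                     baseline_logit = 0, seed = 25)
    gd <- simulateDataset(cfg)
    scan <- mainEffectScan(gd, covariates = character(0))
    lam <- attr(scan, "lambda")
    expect_gt(lam, 0.9); expect_lt(lam, 1.1)
    expect_gt(stats::ks.test(scan$p[scan$flag == "ok"], "punif")$p.value,
              0.01)
    # planted additive effect is detected
    cfg2 <- simConfig(4000, 10, main_effects = list(list(snp = 4L,
                                                         beta = 0.5)),
                      maf_range = c(0.3, 0.3), baseline_logit = 0,
                      seed = 26)
    gd2 <- simulateDataset(cfg2)
    scan2 <- mainEffectScan(gd2, covariates = character(0))
    expect_lt(scan2$p[4], 1e-4)
    # constant SNP is flagged, not silently dropped
    calls <- genoCalls(gd2); calls[1, ] <- 1L
    gd3 <- gd_from_calls(calls, status = sampleInfo(gd2)$status)
    scan3 <- mainEffectScan(gd3, covariates = character(0))
    expect_identical(scan3$flag[1], "constant")
    expect_true(is.na(scan3$p[1]))
})

test_that("screenAllPairs enumerates pairs, reports and pools FDR", {
    cfg <- simConfig(500, 10, maf_range = c(0.2, 0.5), seed = 27)
    gd <- simulateDataset(cfg)
    res <- screenAllPairs(gd, p_report = 1)
    md <- S4Vectors::metadata(res)
    expect_equal(md$n_pairs, choose(10, 2))
    expect_equal(md$n_valid_tests,
                 sum(!is.na(res$p)))
    expect_true(all(res$fdr >= res$p))          # BH never shrinks
    # input order invariance up to row order
    perm <- sample(10)
    res2 <- screenAllPairs(gd[perm, ], p_report = 1)
    key <- function(r) {
        k <- paste(pmin(r$snp_a, r$snp_b), pmax(r$snp_a, r$snp_b),
                   r$method)
        data.frame(k, p = r$p)[order(k), ]
    }
    expect_equal(key(as.data.frame(res))$p, key(as.data.frame(res2))$p,
                 tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
    expect_equal(fdrAdjust(data.frame(p = c(0.01, 0.02, 0.03)))$fdr,
                 c(0.03, 0.03, 0.03))
    expect_equal(fdrAdjust(data.frame(p = 0.2))$fdr, 0.2)
    set.seed(28)
    p <- runif(1000)
    expect_equal(fdrAdjust(data.frame(p = p))$fdr, bh_oracle(p),
                 tolerance = 1e-14)
    adj <- fdrAdjust(data.frame(p = p))$fdr
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("LD pruning removes redundant pairs and keeps undefined ones", {
    set.seed(29)
    x <- rbinom(300, 2, 0.4)
    calls <- rbind(x, x, rbinom(300, 2, 0.4))
    gd <- gd_from_calls(calls, status = rbinom(300, 1, 0.5))
    res <- data.frame(snp_a = c("s001", "s001"), snp_b = c("s002", "s003"),
                      p = c(0.01, 0.02), fdr = NA)
    out <- prunePairsByLd(S4Vectors::DataFrame(res), gd, max_r2 = 0.2)
    expect_identical(as.character(out$snp_b), "s003")
    expect_lt(out$ld_r2[1], 0.2)
})

test_that("post-hoc genotypic test equals the direct 8-df oracle without covariates", {
    gd <- sim_pair_data(n = 800, seed = 30)
    ph <- posthocGenotypicTest(gd, 1, 2, covariates = character(0))
    # oracle: direct factor fit
    calls <- genoCalls(gd); st <- sampleInfo(gd)$status
    cell <- factor(paste0(calls[1, ], calls[2, ]))
    f1 <- glm(st ~ cell, binomial())
    f0 <- glm(st ~ 1, binomial())
    expect_equal(ph$stat, f0$deviance - f1$deviance, tolerance = 1e-8)
    expect_equal(ph$df, nlevels(cell) - 1L)
    expect_gt(ph$p, 0.001)                      # null pair
})

test_that("covariate adjustment attenuates batch-confounded association", {
    set.seed(31)
    n <- 2000
    batch <- rbinom(n, 1, 0.5)
    # batch drives both status and the genotype of SNP 1 (no real effect)
    g1 <- rbinom(n, 2, ifelse(batch == 1, 0.45, 0.15))
    g2 <- rbinom(n, 2, 0.3)
    status <- rbinom(n, 1, plogis(-0.8 + 1.6 * batch))
    gd <- gd_from_calls(rbind(g1, g2), status = status)
    sa <- as.data.frame(sampleInfo(gd)); sa$batch <- batch
    sampleInfo(gd) <- sa
    un <- posthocGenotypicTest(gd, 1, 2, covariates = character(0))
    ad <- posthocGenotypicTest(gd, 1, 2, covariates = "batch")
    expect_lt(un$p, 0.05)                       # spurious signal
    expect_gt(ad$stat / ad$df, 0)               # defined
    expect_gt(ad$p, un$p)                       # attenuated
})
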