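test_that("effect table ORs match the 2x2 cell-vs-rest oracle", {
    set.seed(33)
    jt <- random_joint_table(5, 60)
    et <- estimateEffectTable(jt)
    cnt <- jointCounts(jt)
    for (a in 1:3) for (b in 1:3) {
        ca <- cnt[a, b, 2]; co <- cnt[a, b, 1]
        ra <- sum(cnt[, , 2]) - ca; ro <- sum(cnt[, , 1]) - co
        expect_equal(cellLogOR(et)[a, b],
                     log((ca / co) / (ra / ro)), tolerance = 1e-12)
        expect_identical(highRiskCells(et)[a, b],
                         ca / co > sum(cnt[, , 2]) / sum(cnt[, , 1]))
    }
    # uniform case:control ratio -> all zero effects, no high-risk cells
    flat <- JointTable(array(rep(c(10, 20), each = 9), c(3, 3, 2)))
    expect_true(all(abs(cellLogOR(estimateEffectTable(flat))) < 1e-12))
    expect_false(any(highRiskCells(estimateEffectTable(flat))))
    # reference-cell variant
    etr <- estimateEffectTable(jt, or_type = "cell_vs_reference")
    expect_equal(cellLogOR(etr)[1, 1], 0)
})

test_that("PRS follows the printed per-sample-denominator formula", {
    calls <- rbind(c(2L, 0L, NA), c(1L, 2L, NA))
    gd <- gd_from_calls(calls)
    w <- data.frame(snp_id = c("s001", "s002"), effect_allele = "A",
                    effect_size = c(0.5, -0.2))
    prs <- computePRS(gd, w)
    expect_equal(unname(prs[1]), (2 * 0.5 + 1 * -0.2) / 2)
    expect_equal(unname(prs[2]), (0 * 0.5 + 2 * -0.2) / 2)
    expect_true(is.na(prs[3]))                  # missing every weight SNP
    # one-SNP case: G = 2, E = 0.5 -> PRS = 1
    one <- computePRS(gd, w[1, ])
    expect_equal(unname(one[1]), 1.0)
    # effect allele given as the other allele flips the dosage
    w2 <- data.frame(snp_id = "s001", effect_allele = "G",
                     effect_size = 0.5)
    expect_equal(unname(computePRS(gd, w2)[2]), 1.0)   # 2 - 0 = 2 copies
    expect_warning(computePRS(gd, data.frame(snp_id = "s001",
                                             effect_allele = "T",
                                             effect_size = 1)),
                   "neither allele")
})

test_that("ERS averages one cell effect per interaction with per-sample N", {
    calls <- rbind(c(0L, 2L), c(0L, 2L), c(1L, NA), c(1L, 1L))
    gd <- gd_from_calls(calls)
    mk_et <- function(a, b, val) {
        lo <- matrix(val, 3, 3)
        methods::new("EffectTable", snpA = a, snpB = b, logOR = lo,
                     highRisk = matrix(FALSE, 3, 3), threshold = 1)
    }
    e1 <- mk_et("s001", "s002", 0.5)
    e2 <- mk_et("s003", "s004", -0.1)
    ers <- computeERS(gd, list(e1, e2))
    expect_equal(unname(ers[1]), (0.5 - 0.1) / 2)
    expect_equal(unname(ers[2]), 0.5)           # SNP3 missing -> N_j = 1
    # single interaction with cell effect 0.7
    et7 <- mk_et("s001", "s002", 0.7)
    expect_equal(unname(computeERS(gd, list(et7))[1]), 0.7)
    # all-zero tables give zero scores; linearity in the effects
    expect_equal(as.numeric(computeERS(gd, list(mk_et("s001", "s002", 0)))),
                 c(0, 0))
    double <- computeERS(gd, list(mk_et("s001", "s002", 1.0)))
    expect_equal(as.numeric(double), 2 * as.numeric(computeERS(
        gd, list(mk_et("s001", "s002", 0.5)))))
    # duplicated interactions are de-duplicated (first kept)
    dup <- computeERS(gd, list(e1, mk_et("s002", "s001", 9)))
    expect_equal(as.numeric(dup), as.numeric(computeERS(gd, list(e1))))
})

test_that("zero-effect interactions shrink ERS but preserve ranking", {
    set.seed(35)
    cfg <- simConfig(400, 6, seed = 36)
    gd <- simulateGenotypes(cfg)
    jt <- buildJointTable(simulateDataset(cfg), 1, 2)
    et <- estimateEffectTable(jt)
    zero <- methods::new("EffectTable", snpA = "snp0003", snpB = "snp0004",
                         logOR = matrix(0, 3, 3),
                         highRisk = matrix(FALSE, 3, 3), threshold = 1)
    e_base <- computeERS(gd, list(et))
    e_aug <- computeERS(gd, list(et, zero))
    ok <- !is.na(e_base) & !is.na(e_aug)
    expect_equal(cor(rank(e_base[ok]), rank(e_aug[ok])), 1)
    expect_true(all(abs(e_aug[ok]) <= abs(e_base[ok]) + 1e-12))
})

test_that("CRS is the w-mixture of PRS and ERS", {
    prs <- c(0.4, 1); ers <- c(0.2, NA)
    expect_equal(computeCRS(prs, ers, 1)[1], 0.4)
    expect_equal(computeCRS(prs, ers, 0)[1], 0.2)
    expect_equal(computeCRS(prs, ers, 0.5)[1], 0.3)
    expect_true(is.na(computeCRS(prs, ers, 0.5)[2]))
})

test_that("w selection maximizes AUC with the smallest-w tie rule", {
    set.seed(37)
    n <- 4000
    status <- rbinom(n, 1, 0.5)
    prs <- status + rnorm(n, 0, 1)              # informative
    noise <- rnorm(n)                           # pure noise ERS
    sel <- selectW(prs, noise, status, step = 0.05)
    expect_equal(sel$w, 1)
    # identical scores: AUC flat, tie -> w = 0
    expect_equal(selectW(prs, prs, status)$w, 0)
    expect_error(selectW(prs, noise, rep(1, n)), "degenerate")
})

test_that("MDR prediction depends only on cell membership", {
    hi <- matrix(c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                   FALSE, FALSE, TRUE), 3, 3)
    et <- methods::new("EffectTable", snpA = "a", snpB = "b",
                       logOR = matrix(0, 3, 3), highRisk = hi,
                       threshold = 1)
    expect_identical(mdrPredict(et, c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 1L)),
                     c(1L, 1L, 1L, 0L))
    all_hi <- methods::new("EffectTable", snpA = "a", snpB = "b",
                           logOR = matrix(0, 3, 3),
                           highRisk = matrix(TRUE, 3, 3), threshold = 1)
    expect_identical(mdrPredict(all_hi, c(0L, 2L), c(1L, NA)),
                     c(1L, NA_integer_))
    # balanced accuracy on a strongly planted interaction beats chance
    pen <- matrix(0.25, 3, 3); pen[2:3, 2:3] <- 0.7
    cfg <- simConfig(4000, 2, planted_pairs = list(
        list(snp_a = 1L, snp_b = 2L, pen = penetranceTable(pen),
             maf_a = 0.45, maf_b = 0.45)),
        baseline_logit = qlogis(0.25), seed = 39)
    gd <- simulateDataset(cfg)
    et2 <- estimateEffectTable(buildJointTable(gd, 1, 2))
    calls <- genoCalls(gd)
    pred <- mdrPredict(et2, calls[1, ], calls[2, ])
    st <- sampleInfo(gd)$status
    ba <- (mean(pred[st == 1] == 1) + mean(pred[st == 0] == 0)) / 2
    expect_gt(ba, 0.55)
})

test_that("permutation selection separates signal from noise", {
    pen <- matrix(0.2, 3, 3); pen[2:3, 2:3] <- 0.75
    mk <- function(seed, n = 1500) simulateDataset(simConfig(
        n, 4, planted_pairs = list(list(snp_a = 1L, snp_b = 2L,
                                        pen = penetranceTable(pen),
                                        maf_a = 0.45, maf_b = 0.45)),
        baseline_logit = qlogis(0.2), seed = seed))
    train <- mk(41); t1 <- mk(42); t2 <- mk(43)
    pairs <- rbind(c("snp0001", "snp0002"), c("snp0003", "snp0004"))
    res <- permutationSelect(pairs, train, list(A = t1, B = t2),
                             n_perm = 1000L, alpha = 0.05, seed = 44)
    expect_true(res$selected[1])                # planted
    expect_false(res$selected[2])               # noise (overwhelmingly)
    expect_lt(res$p_A[1], 0.05)
    # deterministic under seed
    res2 <- permutationSelect(pairs, train, list(A = t1, B = t2),
                              n_perm = 1000L, alpha = 0.05, seed = 44)
    expect_identical(res, res2)
})

test_that("a perfectly predictive interaction attains the add-one floor", {
    set.seed(45)
    mk <- function(n, seed_shift) {
        set.seed(45 + seed_shift)
        g1 <- rep(0:2, length.out = n)
        g2 <- rbinom(n, 2, 0.4)
        # status is a near-deterministic function of g1 == 2 in training,
        # exactly deterministic in the test sets
        gd_from_calls(rbind(g1, g2), status = as.integer(g1 == 2L))
    }
    train <- mk(900, 0)
    t1 <- mk(400, 1); t2 <- mk(500, 2)
    res <- permutationSelect(rbind(c("s001", "s002")), train,
                             list(A = t1, B = t2), n_perm = 1000L,
                             alpha = 0.05, seed = 47)
    expect_equal(res$ba_A, 1)
    expect_equal(res$p_A, 1 / 1001)
    expect_equal(res$p_B, 1 / 1001)
    expect_true(res$selected)
})
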