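# Shared fixtures: tiny GenotypeData builders and random joint tables.

# GenotypeData from a SNPs x samples matrix, with optional status.
gd_from_calls <- function(calls, status = NULL) {
    m <- nrow(calls); n <- ncol(calls)
    si <- data.frame(snp = sprintf("s%03d", seq_len(m)), chr = "1",
                     pos = seq_len(m) * 100L, a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
    sa <- data.frame(sample_id = sprintf("i%04d", seq_len(n)),
                     stringsAsFactors = FALSE)
    if (!is.null(status)) sa$status <- as.integer(status)
    GenotypeData(calls, si, sa)
}

# random 3x3x2 table with all cells in [lo, hi]
random_joint_table <- function(lo = 3L, hi = 50L) {
    JointTable(array(sample(lo:hi, 18, replace = TRUE), c(3, 3, 2)))
}

# independent oracle: BOOST homogeneous-association statistic via a
# Poisson log-linear glm with all two-way terms
boost_oracle <- function(counts18) {
    d <- expand.grid(g1 = factor(0:2), g2 = factor(0:2),
                     st = factor(0:1))
    d$n <- as.numeric(counts18)
    fit <- glm(n ~ g1 * g2 + g1 * st + g2 * st, family = poisson(), data = d)
    mu <- fitted(fit)
    2 * sum(ifelse(d$n > 0, d$n * log(d$n / mu), 0))
}

# independent oracle: joint-effects statistic assembled cell by cell
joint_oracle <- function(counts18) {
    n <- array(counts18, c(3, 3, 2))
    lam <- function(s) {
        c0 <- n[, , s]
        v <- numeric(4); k <- 0
        for (a in 2:3) for (b in 2:3) {
            k <- k + 1
            v[k] <- log(c0[a, b]) - log(c0[a, 1]) - log(c0[1, b]) +
                log(c0[1, 1])
        }
        v
    }
    Vmat <- function(s) {
        c0 <- n[, , s]
        ab <- expand.grid(a = 2:3, b = 2:3)
        ab <- ab[order(ab$a, ab$b), ]           # match lam() loop order
        V <- matrix(0, 4, 4)
        for (i in 1:4) for (j in 1:4) {
            v <- 1 / c0[1, 1]
            if (ab$a[i] == ab$a[j]) v <- v + 1 / c0[ab$a[i], 1]
            if (ab$b[i] == ab$b[j]) v <- v + 1 / c0[1, ab$b[i]]
            if (ab$a[i] == ab$a[j] && ab$b[i] == ab$b[j])
                v <- v + 1 / c0[ab$a[i], ab$b[i]]
            V[i, j] <- v
        }
        V
    }
    d <- lam(2) - lam(1)
    V <- Vmat(1) + Vmat(2)
    drop(t(d) %*% solve(V) %*% d)
}

# independent oracle: BH step-up, textbook form
bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

# independent oracle: HWE exact test by enumeration with choose()
hwe_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    na <- 2 * min(nAA, naa) + nAa
    hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    # P(h het | n genotypes, na minor alleles) =
    #   choose(n, homa) * choose(n - homa, h) * 2^h / choose(2n, na)
    pr <- vapply(hs, function(h) {
        homa <- (na - h) / 2
        exp(lchoose(n, homa) + lchoose(n - homa, h) + h * log(2) -
            lchoose(2 * n, na))
    }, numeric(1))
    obs <- pr[match(nAa, hs)]
    sum(pr[pr <= obs * (1 + 1e-10)])
}
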