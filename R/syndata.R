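# Synthetic case-control genotype/phenotype generator with planted
# penetrance-table epistasis. Draw order is fixed and documented so a
# single integer seed reproduces a dataset exactly:
#   1. genotypes, SNP by SNP in index order (planted-pair members last
#      within their own column draw, but column order is still index
#      order); 2. missingness mask; 3. covariates (sex, age, batch);
#   4. disease status; 5. onset/censoring ages.

#' Penetrance table for a planted SNP-SNP interaction
#'
#' A 3x3 matrix of disease probabilities indexed by the minor-allele
#' counts of the two interacting SNPs. When planted, each pair
#' contributes \code{qlogis(p[g1 + 1, g2 + 1]) - baseline_logit} to the
#' sample's liability so that pair effects and main effects combine
#' additively on the logit scale.
#'
#' @param p 3x3 numeric matrix of probabilities in [0, 1].
#' @return The validated matrix with class \code{"PenetranceTable"}.
#' @export
penetranceTable <- function(p) {
    p <- as.matrix(p)
    if (!all(dim(p) == c(3L, 3L))) stop("penetrance table must be 3x3")
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("penetrance entries must lie in [0, 1]")
    structure(p, class = c("PenetranceTable", class(p)))
}

#' Simulation configuration
#'
#' Validated parameter bundle for [simulateGenotypes()] and
#' [simulatePhenotype()]. Non-planted SNPs are drawn independently per
#' sample under Hardy-Weinberg proportions with minor-allele frequencies
#' uniform over \code{maf_range}; planted interactions are specified as
#' 3x3 penetrance tables and their member SNPs are exempt from simulated
#' missingness.
#'
#' @param n_samples,n_snps dataset dimensions.
#' @param maf_range length-2 numeric in (0, 0.5]: range of minor-allele
#'   frequencies.
#' @param planted_pairs list of \code{list(snp_a =, snp_b =, pen =)} with
#'   distinct in-range SNP indices and a [penetranceTable()]; an optional
#'   \code{maf_a}/\code{maf_b} fixes the MAF of the member SNPs.
#' @param main_effects list of \code{list(snp =, beta =)} per-allele
#'   log-odds-ratio main effects.
#' @param baseline_logit intercept of the liability (log-odds of disease
#'   for a genotype- and covariate-neutral sample).
#' @param covariate_spec list with elements \code{sex_prob},
#'   \code{age_mean}, \code{age_sd}, \code{n_batches}, \code{beta_sex},
#'   \code{beta_age} (per year, age centred at its mean),
#'   \code{beta_batch}.
#' @param missing_rate uniform per-call missingness probability.
#' @param onset_base_age,onset_max_age age window (years) for the
#'   synthetic age-at-onset model; onset is \code{onset_base_age} plus an
#'   exponential waiting time whose rate increases with the liability,
#'   censored at \code{onset_max_age}.
#' @param seed integer seed governing all draws.
#' @return A validated list with class \code{"SimConfig"}.
#' @export
simConfig <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                      planted_pairs = list(), main_effects = list(),
                      baseline_logit = 0,
                      covariate_spec = list(sex_prob = 0.5, age_mean = 75,
                                            age_sd = 8, n_batches = 2L,
                                            beta_sex = 0, beta_age = 0,
                                            beta_batch = 0),
                      missing_rate = 0, onset_base_age = 60,
                      onset_max_age = 100, seed = 1L) {
    stopifnot(n_samples >= 1, n_snps >= 1)
    if (length(maf_range) != 2L || any(maf_range <= 0) ||
        any(maf_range > 0.5) || maf_range[1] > maf_range[2])
        stop("maf_range must lie within (0, 0.5]")
    if (missing_rate < 0 || missing_rate >= 1)
        stop("missing_rate must lie in [0, 1)")
    used <- integer(0)
    for (pp in planted_pairs) {
        if (!all(c("snp_a", "snp_b", "pen") %in% names(pp)))
            stop("each planted pair needs snp_a, snp_b and pen")
        if (pp$snp_a == pp$snp_b)
            stop("planted pair indices must be distinct")
        if (max(pp$snp_a, pp$snp_b) > n_snps || min(pp$snp_a, pp$snp_b) < 1)
            stop("planted pair index out of range")
        if (!inherits(pp$pen, "PenetranceTable"))
            stop("pen must be a penetranceTable()")
        used <- c(used, pp$snp_a, pp$snp_b)
    }
    for (me in main_effects) {
        if (!all(c("snp", "beta") %in% names(me)))
            stop("each main effect needs snp and beta")
        if (me$snp > n_snps || me$snp < 1)
            stop("main-effect SNP index out of range")
    }
    cs <- covariate_spec
    defaults <- list(sex_prob = 0.5, age_mean = 75, age_sd = 8,
                     n_batches = 2L, beta_sex = 0, beta_age = 0,
                     beta_batch = 0)
    for (nm in names(defaults))
        if (is.null(cs[[nm]])) cs[[nm]] <- defaults[[nm]]
    structure(list(n_samples = as.integer(n_samples),
                   n_snps = as.integer(n_snps),
                   maf_range = as.numeric(maf_range),
                   planted_pairs = planted_pairs,
                   main_effects = main_effects,
                   baseline_logit = baseline_logit,
                   covariate_spec = cs,
                   missing_rate = missing_rate,
                   onset_base_age = onset_base_age,
                   onset_max_age = onset_max_age,
                   seed = as.integer(seed),
                   planted_snps = unique(used)),
              class = "SimConfig")
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP is assigned a minor-allele frequency q drawn uniformly from
#' \code{maf_range} (or fixed by the planted-pair spec) and genotypes are
#' drawn independently per sample with probabilities (1-q)^2, 2q(1-q),
#' q^2. Missingness is applied uniformly at \code{missing_rate}, except
#' at planted-pair SNPs, which stay fully observed so that planted
#' effects are recovered unconfounded.
#'
#' @param config a [simConfig()].
#' @return A \linkS4class{GenotypeData}; the per-SNP true MAF is kept in
#'   \code{rowData} column \code{maf_true}.
#' @examples
#' gd <- simulateGenotypes(simConfig(100, 10, seed = 42))
#' table(genoCalls(gd)[1, ], useNA = "ifany")
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    n <- config$n_samples; m <- config$n_snps
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    for (pp in config$planted_pairs) {
        if (!is.null(pp$maf_a)) maf[pp$snp_a] <- pp$maf_a
        if (!is.null(pp$maf_b)) maf[pp$snp_b] <- pp$maf_b
    }
    calls <- matrix(0L, nrow = m, ncol = n)
    for (s in seq_len(m)) {
        q <- maf[s]
        calls[s, ] <- sample(0:2, n, replace = TRUE,
                             prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    }
    if (config$missing_rate > 0) {
        mask <- matrix(runif(m * n) < config$missing_rate, nrow = m)
        mask[config$planted_snps, ] <- FALSE
        calls[mask] <- NA_integer_
    }
    snp_meta <- data.frame(
        snp = sprintf("snp%04d", seq_len(m)),
        chr = "1", pos = seq_len(m) * 10000L,
        a1 = "A", a2 = "G", maf_true = maf,
        stringsAsFactors = FALSE)
    GenotypeData(calls, snp_meta,
                 data.frame(sample_id = sprintf("samp%05d", seq_len(n))))
}

#' Simulate phenotype, covariates and age at onset
#'
#' The disease liability of sample j is
#' \code{baseline_logit + covariate terms + sum(main effects) +
#' sum(qlogis(pen[g1, g2]) - baseline_logit)} over planted pairs, and
#' status is Bernoulli(plogis(liability)). Age at onset for cases is
#' \code{onset_base_age} plus an exponential waiting time with rate
#' increasing in the liability; onsets beyond \code{onset_max_age} and
#' all controls are right-censored at their last-record age.
#'
#' @param geno a \linkS4class{GenotypeData} from [simulateGenotypes()].
#' @param config the same [simConfig()] used to generate \code{geno}.
#' @return \code{geno} with \code{colData} columns \code{status},
#'   \code{sex}, \code{age}, \code{batch}, \code{onset_age},
#'   \code{censored} and \code{liability} filled in.
#' @export
simulatePhenotype <- function(geno, config) {
    stopifnot(inherits(config, "SimConfig"))
    calls <- genoCalls(geno)
    n <- ncol(calls)
    for (pp in config$planted_pairs)
        if (anyNA(calls[pp$snp_a, ]) || anyNA(calls[pp$snp_b, ]))
            stop("planted SNPs must be fully observed")
    # phenotype stream is decoupled from the genotype stream
    set.seed(config$seed + 1L)
    cs <- config$covariate_spec
    sex <- ifelse(runif(n) < cs$sex_prob, "F", "M")
    age <- rnorm(n, cs$age_mean, cs$age_sd)
    batch <- sample(seq_len(cs$n_batches), n, replace = TRUE)

    eta <- rep(config$baseline_logit, n)
    eta <- eta + cs$beta_sex * (sex == "F") +
        cs$beta_age * (age - cs$age_mean) +
        cs$beta_batch * (batch - 1L)
    for (me in config$main_effects) {
        g <- calls[me$snp, ]
        g[is.na(g)] <- 0L                       # missing contributes nothing
        eta <- eta + me$beta * g
    }
    for (pp in config$planted_pairs) {
        p <- pmin(pmax(unclass(pp$pen), 1e-12), 1 - 1e-12)
        cell <- qlogis(p) - config$baseline_logit
        eta <- eta + cell[cbind(calls[pp$snp_a, ] + 1L,
                                calls[pp$snp_b, ] + 1L)]
    }
    status <- rbinom(n, 1L, plogis(eta))

    # age at onset: exponential waiting time, hazard scaled by liability
    base_rate <- 0.05
    onset <- config$onset_base_age +
        rexp(n, rate = base_rate * exp(0.5 * (eta - mean(eta))))
    last_record <- runif(n, config$onset_base_age + 5, config$onset_max_age)
    censored <- ifelse(status == 1L & onset <= last_record, 0L, 1L)
    onset_age <- ifelse(censored == 0L, onset, last_record)

    sa <- as.data.frame(sampleInfo(geno))
    sa$status <- status
    sa$sex <- sex
    sa$age <- age
    sa$batch <- batch
    sa$onset_age <- onset_age
    sa$censored <- censored
    sa$liability <- eta
    sampleInfo(geno) <- sa
    geno
}

#' One-call synthetic dataset
#'
#' @param config a [simConfig()].
#' @return A \linkS4class{GenotypeData} with genotypes and phenotype.
#' @export
simulateDataset <- function(config) {
    simulatePhenotype(simulateGenotypes(config), config)
}

#' Write a simulation configuration as YAML
#'
#' @param config a [simConfig()].
#' @param path output YAML path.
#' @export
writeSimConfig <- function(config, path) {
    x <- unclass(config)
    x$planted_pairs <- lapply(x$planted_pairs, function(pp) {
        pp$pen <- as.vector(unclass(pp$pen))    # column-major 9-vector
        pp
    })
    yaml::write_yaml(x, path)
    invisible(path)
}
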