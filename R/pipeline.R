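# End-to-end workflow: QC -> pairwise screen -> FDR/LD prune -> risk
# scores -> survival/ROC evaluation, with a run manifest and a
# one-command synthetic demo.

#' Pipeline run configuration
#'
#' Assembles and validates all pipeline thresholds with the workflow
#' defaults (SNP missing 0.1, MAF 0.05, HWE 1e-6, sample missing 0.2,
#' heterozygosity 3 SD, cell minimum 3, report threshold 1e-5, pair LD
#' 0.2, ERS p-value tiers 1e-7/1e-6/1e-5). Either \code{bfile} (a PLINK
#' prefix, with optional \code{pheno} TSV) or \code{sim} (a
#' [simConfig()]) supplies the genotypes.
#'
#' @param bfile PLINK1 prefix, or \code{NULL} when simulating.
#' @param pheno phenotype TSV path (optional).
#' @param sim a [simConfig()] used when \code{bfile} is \code{NULL}.
#' @param annot SNP annotation TSV path (optional; columns as in
#'   [selectByAnnotation()]).
#' @param weights PRS weight TSV path (optional; columns as in
#'   [computePRS()]).
#' @param max_snp_missing,min_maf,hwe_alpha SNP-QC thresholds.
#' @param max_sample_missing,het_sd sample-QC thresholds.
#' @param min_score,max_gene_distance annotation-selection thresholds.
#' @param min_cell,p_report,max_pair_ld screening thresholds.
#' @param tiers ERS p-value tiers (most to least stringent).
#' @param n_perm,w_grid,quantiles scoring/evaluation parameters.
#' @param split_fraction fraction of samples used as the discovery half
#'   for effect-table training; the rest are scored and evaluated.
#' @param n_pcs principal components used as covariates.
#' @param seed integer seed.
#' @return validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(bfile = NULL, pheno = NULL, sim = NULL, annot = NULL,
                      weights = NULL, max_snp_missing = 0.1, min_maf = 0.05,
                      hwe_alpha = 1e-6, max_sample_missing = 0.2,
                      het_sd = 3, min_score = 15, max_gene_distance = 5000,
                      min_cell = 3L, p_report = 1e-5, max_pair_ld = 0.2,
                      tiers = c(1e-7, 1e-6, 1e-5), n_perm = 10000L,
                      w_grid = 0.01, quantiles = 4L, split_fraction = 0.5,
                      n_pcs = 3L, seed = 1L) {
    if (is.null(bfile) && is.null(sim))
        stop("either 'bfile' or 'sim' must be given")
    for (th in c(max_snp_missing, min_maf, hwe_alpha, max_sample_missing,
                 p_report, max_pair_ld, split_fraction))
        if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
    stopifnot(min_cell >= 0, het_sd > 0, n_perm >= 100, w_grid > 0,
              quantiles >= 2, all(diff(tiers) > 0))
    structure(as.list(environment()), class = "RunConfig")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with [runConfig()] fields.
#' @return a \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    x <- yaml::read_yaml(path)
    do.call(runConfig, x)
}

.stage_log <- function(manifest, stage, ...) {
    entry <- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(entry), unlist(entry), sep = "=",
                          collapse = "  ")))
    manifest$stages[[stage]] <- entry
    manifest
}

#' Run the full epistasis pipeline
#'
#' Executes the stages in order — input, sample QC, SNP QC (plus
#' optional annotation selection), PCA covariates, main-effect scan,
#' pairwise screen with cell filter and pooled FDR, LD pruning,
#' effect-table training on the discovery half, ERS (and PRS/CRS when
#' weights are supplied) on the held-out half, and quantile/KM/AUC
#' evaluation — writing each stage's output plus a machine-readable
#' \code{manifest.json} (package version, seed, thresholds, and the
#' retained/removed counts of every filter) into \code{out_dir}. With
#' \code{resume = TRUE}, stages whose output files already exist are
#' skipped.
#'
#' @param config a [runConfig()].
#' @param out_dir output directory (created if needed).
#' @param resume skip stages with existing outputs.
#' @return the manifest list, invisibly; files under \code{out_dir}.
#' @export
runPipeline <- function(config, out_dir, resume = FALSE) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "episcore",
                     version = as.character(utils::packageVersion("episcore")),
                     seed = config$seed,
                     thresholds = list(
                         max_snp_missing = config$max_snp_missing,
                         min_maf = config$min_maf,
                         hwe_alpha = config$hwe_alpha,
                         max_sample_missing = config$max_sample_missing,
                         het_sd = config$het_sd,
                         min_cell = config$min_cell,
                         p_report = config$p_report,
                         max_pair_ld = config$max_pair_ld,
                         tiers = config$tiers),
                     stages = list())
    cfg_out <- config
    cfg_out$sim <- NULL                          # not YAML-serializable
    yaml::write_yaml(lapply(unclass(cfg_out), function(x)
        if (is.null(x)) NA else x), file.path(out_dir, "config_resolved.yaml"))

    # -- input ---------------------------------------------------------
    if (!is.null(config$bfile)) {
        for (ext in c(".bed", ".bim", ".fam"))
            if (!file.exists(paste0(config$bfile, ext)))
                stop("input file not found: ", paste0(config$bfile, ext))
        geno <- readPlink(config$bfile)
        if (!is.null(config$pheno)) {
            if (!file.exists(config$pheno))
                stop("phenotype file not found: ", config$pheno)
            geno <- attachPhenotype(geno, config$pheno)
        }
    } else {
        geno <- simulateDataset(config$sim)
    }
    manifest <- .stage_log(manifest, "input", n_samples = nSamples(geno),
                           n_snps = nSnps(geno))

    # -- QC: samples first, then SNPs ----------------------------------
    geno <- filterSamples(geno, config$max_sample_missing, config$het_sd)
    sf <- metadata(geno)$sample_filter
    manifest <- .stage_log(manifest, "sample_qc", n_input = sf$n_input,
                           n_kept = sf$n_kept,
                           n_removed = sf$n_input - sf$n_kept)
    geno <- filterSnps(geno, config$max_snp_missing, config$min_maf,
                       config$hwe_alpha)
    kf <- metadata(geno)$snp_filter
    manifest <- .stage_log(manifest, "snp_qc", n_input = kf$n_input,
                           n_kept = kf$n_kept,
                           n_removed = kf$n_input - kf$n_kept)
    if (!is.null(config$annot)) {
        annot <- read.table(config$annot, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
        n0 <- nSnps(geno)
        geno <- selectByAnnotation(geno, annot, config$min_score,
                                   config$max_gene_distance)
        manifest <- .stage_log(manifest, "annotation", n_input = n0,
                               n_kept = nSnps(geno))
    }
    if (config$n_pcs > 0) geno <- addPcaCovariates(geno, config$n_pcs)

    # -- main-effect scan ----------------------------------------------
    scan_path <- file.path(out_dir, "main_effects.tsv")
    scan <- mainEffectScan(geno)
    write.table(scan, scan_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- .stage_log(manifest, "main_effects", n_snps = nrow(scan),
                           lambda = round(attr(scan, "lambda"), 3))

    # -- pairwise screen ------------------------------------------------
    res_path <- file.path(out_dir, "interactions.tsv")
    if (resume && file.exists(res_path)) {
        res <- S4Vectors::DataFrame(read.table(res_path, header = TRUE,
                                               sep = "\t"))
        manifest <- .stage_log(manifest, "screen", resumed = TRUE,
                               n_reported = nrow(res))
    } else {
        res <- screenAllPairs(geno, min_cell = config$min_cell,
                              p_report = max(config$p_report,
                                             max(config$tiers)))
        md <- metadata(res)
        res <- prunePairsByLd(res, geno, config$max_pair_ld)
        write.table(as.data.frame(res), res_path, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        manifest <- .stage_log(manifest, "screen", n_pairs = md$n_pairs,
                               n_cell_filtered = md$n_cell_filtered,
                               n_valid_tests = md$n_valid_tests,
                               n_reported = nrow(res),
                               n_ld_pruned = metadata(res)$n_ld_pruned)
    }

    # -- risk scores: train on the discovery half, score the rest ------
    set.seed(config$seed)
    n <- nSamples(geno)
    disc <- sort(sample(n, round(config$split_fraction * n)))
    test <- setdiff(seq_len(n), disc)
    train_geno <- geno[, disc]; test_geno <- geno[, test]
    tier_sets <- lapply(config$tiers, function(th) {
        sub <- res[res$p < th, , drop = FALSE]
        unique(paste(sub$snp_a, sub$snp_b))
    })
    names(tier_sets) <- paste0("tier_", format(config$tiers,
                                               scientific = TRUE))
    top_tier <- tier_sets[[length(tier_sets)]]   # least stringent
    scores <- data.frame(sample_id = sampleInfo(test_geno)$sample_id,
                         stringsAsFactors = FALSE)
    if (length(top_tier)) {
        ets <- lapply(strsplit(top_tier, " ", fixed = TRUE), function(ab)
            estimateEffectTable(buildJointTable(train_geno, ab[1], ab[2])))
        scores$ers <- as.numeric(computeERS(test_geno, ets))
    } else {
        scores$ers <- NA_real_
    }
    if (!is.null(config$weights)) {
        wtab <- read.table(config$weights, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
        scores$prs <- as.numeric(computePRS(test_geno, wtab))
        if (length(top_tier)) {
            tr_ets <- lapply(strsplit(top_tier, " ", fixed = TRUE),
                             function(ab) estimateEffectTable(
                                 buildJointTable(train_geno, ab[1], ab[2])))
            prs_tr <- computePRS(train_geno, wtab)
            ers_tr <- computeERS(train_geno, tr_ets)
            sel <- selectW(prs_tr, ers_tr, sampleInfo(train_geno)$status,
                           step = config$w_grid)
            scores$crs <- computeCRS(scores$prs, scores$ers, sel$w)
            manifest$stages$w_selection <- list(w = sel$w,
                                                auc_train = sel$auc)
        }
    }
    write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- .stage_log(manifest, "scores",
                           n_train = length(disc), n_test = length(test),
                           n_interactions = length(top_tier))

    # -- evaluation -----------------------------------------------------
    sa <- as.data.frame(sampleInfo(test_geno))
    eval_out <- list()
    if (!all(is.na(scores$ers)) &&
        all(c("onset_age", "censored", "status") %in% names(sa))) {
        ev <- evaluateRiskScore(scores$ers, sa$status, sa$onset_age,
                                1L - sa$censored, q = config$quantiles)
        eval_out$ers <- list(auc = ev$auc, logrank_chi2 = ev$logrank$chi2,
                             logrank_p = ev$logrank$p)
    }
    for (sc in intersect(c("prs", "crs"), names(scores)))
        if (!all(is.na(scores[[sc]])))
            eval_out[[sc] ] <- list(auc = rocAuc(scores[[sc]], sa$status))
    jsonlite::write_json(eval_out, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- .stage_log(manifest, "evaluate",
                           n_scores = length(eval_out))

    manifest$outputs <- as.list(tools::md5sum(
        list.files(out_dir, pattern = "\\.(tsv|json|yaml)$",
                   full.names = TRUE)))
    names(manifest$outputs) <- basename(names(manifest$outputs))
    manifest$outputs[["manifest.json"]] <- NULL
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

#' Write the synthetic demo dataset
#'
#' A 2000-sample, 300-SNP dataset with two planted penetrance-table
#' interactions and two additive main-effect SNPs, written as PLINK1
#' binary plus phenotype TSV and YAML config, together with a text
#' summary of what the pipeline should find.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param n_samples,n_snps override the demo dimensions.
#' @return list with the file paths, the [simConfig()] used, and the
#'   planted truth.
#' @export
makeDemo <- function(seed = 1L, dir = tempfile("episcore_demo"),
                     n_samples = 2000L, n_snps = 300L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    stopifnot(n_snps >= 10L)
    pen_hi <- matrix(0.35, 3, 3); pen_hi[3, 3] <- 0.80; pen_hi[2, 3] <- 0.55
    pen_th <- matrix(0.35, 3, 3); pen_th[3, 1] <- 0.70; pen_th[1, 3] <- 0.70
    # planted indices spread across the panel, scaled to its size
    at <- function(f) max(1L, min(n_snps, as.integer(round(f * n_snps))))
    idx <- c(a1 = at(1 / 30), b1 = at(6 / 30), a2 = at(12 / 30),
             b2 = at(20 / 30), m1 = at(3 / 30), m2 = at(25 / 30))
    while (anyDuplicated(idx)) {                # tiny panels: nudge clashes
        d <- which(duplicated(idx))[1L]
        idx[d] <- min(n_snps, max(idx) + 1L)
    }
    cfg <- simConfig(
        n_samples = n_samples, n_snps = n_snps,
        maf_range = c(0.1, 0.5),
        planted_pairs = list(
            list(snp_a = idx[["a1"]], snp_b = idx[["b1"]],
                 pen = penetranceTable(pen_hi), maf_a = 0.4, maf_b = 0.4),
            list(snp_a = idx[["a2"]], snp_b = idx[["b2"]],
                 pen = penetranceTable(pen_th), maf_a = 0.35, maf_b = 0.35)),
        main_effects = list(list(snp = idx[["m1"]], beta = 0.35),
                            list(snp = idx[["m2"]], beta = -0.30)),
        baseline_logit = qlogis(0.35), missing_rate = 0.01, seed = seed)
    geno <- simulateDataset(cfg)
    prefix <- file.path(dir, "demo")
    writePlink(geno, prefix)
    writePheno(geno, paste0(prefix, ".pheno.tsv"))
    writeSimConfig(cfg, paste0(prefix, ".config.yaml"))
    nm <- function(i) sprintf("snp%04d", i)
    truth <- c(
        "Synthetic demo dataset — planted truth",
        sprintf("samples: %d  SNPs: %d  seed: %d", n_samples, n_snps, seed),
        "planted interactions (expected near the top of the screen):",
        sprintf("  %s x %s (risk concentrated in minor-homozygote cells)",
                nm(idx[["a1"]]), nm(idx[["b1"]])),
        sprintf("  %s x %s (threshold pattern on opposite corners)",
                nm(idx[["a2"]]), nm(idx[["b2"]])),
        "main-effect SNPs (expected in the main-effect scan):",
        sprintf("  %s (log-OR +0.35/allele), %s (log-OR -0.30/allele)",
                nm(idx[["m1"]]), nm(idx[["m2"]])),
        "ERS built from the true pairs should stratify onset age",
        "(top vs bottom quantile) and give held-out AUC > 0.5.")
    writeLines(truth, file.path(dir, "EXPECTED.txt"))
    list(dir = dir, prefix = prefix, pheno = paste0(prefix, ".pheno.tsv"),
         config = cfg,
         truth_pairs = list(c(nm(idx[["a1"]]), nm(idx[["b1"]])),
                            c(nm(idx[["a2"]]), nm(idx[["b2"]]))),
         main_effect_snps = c(nm(idx[["m1"]]), nm(idx[["m2"]])))
}
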