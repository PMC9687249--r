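## Synthetic multi-cohort dataset generator.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: bulk beta-values as cell-type mixtures plus batch shifts, SNP
## (mQTL) effects, planted phenotype effects and Gaussian noise; memory test
## scores as loadings on a latent memory factor with a correlated latent
## longitudinal decline factor; a toy multi-tissue clock; paired brain
## methylation/expression samples. Every planted quantity is recorded in a
## truth channel for parameter-recovery tests.

# Approximate autosome lengths (bp, GRCh37), used to place CpGs and SNPs.
AUTOSOME_LENGTHS <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
  59128983, 63025520, 48129895, 51304566)

GEN_CHUNK <- 25000L  # CpG rows per assembly chunk (memory bound, fixed)

rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Draw sample cell-type fractions from a symmetric Dirichlet
#'
#' @param n_samples number of samples (rows).
#' @param n_cell_types number of cell types (>= 2).
#' @param concentration positive Dirichlet concentration per component;
#'   large values concentrate all fractions near 1/n_cell_types.
#' @param seed integer seed.
#' @return `n_samples` x `n_cell_types` matrix; rows are nonnegative and
#'   sum to one.
#' @export
generate_cell_fractions <- function(n_samples, n_cell_types, concentration,
                                    seed = 1L) {
  assert_number(n_samples, "n_samples", min = 1)
  if (n_cell_types < 2L) stopf("n_cell_types must be >= 2")
  if (!is.numeric(concentration) || concentration <= 0)
    stopf("domain error: concentration must be > 0")
  with_seed(seed, rdirichlet_rows(n_samples, rep(concentration, n_cell_types)))
}

## CpG/SNP/gene coordinate annotation. Genes are runs of up to 10
## consecutive CpGs on a chromosome with the TSS placed 500 bp upstream of
## the first member.
make_annotation <- function(n_cpgs) {
  chrom <- sample(seq_along(AUTOSOME_LENGTHS), n_cpgs, replace = TRUE,
                  prob = AUTOSOME_LENGTHS / sum(AUTOSOME_LENGTHS))
  pos <- floor(runif(n_cpgs, 1, AUTOSOME_LENGTHS[chrom])) + 0
  cpg_id <- sprintf("cg%08d", seq_len(n_cpgs))
  ord <- order(chrom, pos)
  grp <- integer(n_cpgs)
  gi <- 0L
  last_chrom <- -1L
  run <- 0L
  for (i in ord) {
    if (chrom[i] != last_chrom || run >= 10L) {
      gi <- gi + 1L
      run <- 0L
      last_chrom <- chrom[i]
    }
    run <- run + 1L
    grp[i] <- gi
  }
  gene <- sprintf("GENE%05d", grp)
  tss <- tapply(pos, grp, min) - 500L
  gene_tab <- data.frame(
    gene = sprintf("GENE%05d", as.integer(names(tss))),
    chrom = tapply(chrom, grp, `[`, 1L),
    tss = pmax(1, as.numeric(tss)))
  list(cpg = data.frame(cpg_id = cpg_id, chrom = chrom, pos = pos,
                        gene = gene, stringsAsFactors = FALSE),
       gene = gene_tab[order(gene_tab$gene), ])
}

## Toy multi-tissue clock: K CpGs whose betas move linearly with the
## transformed age; coefficients chosen so the clock inverts the generator
## exactly in expectation (sum(coef * slope) = 1, intercept cancels bases).
make_toy_clock <- function(k, adult_age) {
  base <- runif(k, 0.25, 0.55)
  slope <- rep(0.04, k)
  coefs <- rep(1 / (k * 0.04), k)
  data.frame(cpg_id = sprintf("cgclk%04d", seq_len(k)),
             coefficient = coefs, base = base, slope = slope)
}

#' Generate a complete synthetic dataset
#'
#' Produces per-cohort beta matrices (CpGs x samples), sample sheets with
#' memory test scores at up to two timepoints, genotype dosages, CpG/SNP/
#' gene annotation, a cell-type reference, external summary statistics, a
#' toy clock, paired brain methylation and expression matrices, and a truth
#' channel recording every planted quantity. Deterministic for a fixed
#' seed.
#'
#' @param config a [generator_config()].
#' @return a `mem_dataset` list; see the package vignette for the layout.
#' @export
generate_dataset <- function(config) {
  config <- validate_generator_config(config)
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n_cpgs <- cfg$n_cpgs
  K <- length(cfg$cell_types)
  ann <- make_annotation(n_cpgs)
  cpg_ids <- ann$cpg$cpg_id

  ## Cell-type reference: a shared methylation level per CpG plus
  ## cell-type-specific offsets; means kept away from the [0,1] boundary.
  shared_mu <- runif(n_cpgs, 0.10, 0.90)
  ref <- shared_mu + matrix(rnorm(n_cpgs * K, sd = cfg$ref_between_sd),
                            ncol = K)
  ref <- pmin(pmax(ref, 0.05), 0.95)
  dimnames(ref) <- list(cpg_ids, cfg$cell_types)

  ## Special CpG sets.
  pe <- cfg$planted_effects
  planted_idx <- if (is.null(pe)) integer() else pe$cpg_index
  n_mqtl <- floor(cfg$mqtl_fraction * n_cpgs)
  mqtl_idx <- if (n_mqtl > 0) sort(sample(n_cpgs, n_mqtl)) else integer()
  pes_pool <- setdiff(seq_len(n_cpgs), union(planted_idx, mqtl_idx))
  pes_idx <- sort(sample(pes_pool, min(cfg$pes_n_cpgs, length(pes_pool))))

  ## SNPs: one cis SNP per mQTL CpG plus an equal number of null SNPs.
  n_null_snp <- max(n_mqtl, 10L)
  snp_chrom <- c(ann$cpg$chrom[mqtl_idx],
                 sample(seq_along(AUTOSOME_LENGTHS), n_null_snp,
                        replace = TRUE))
  snp_pos <- c(ann$cpg$pos[mqtl_idx] +
                 round(runif(n_mqtl, -5e5, 5e5)),
               floor(runif(n_null_snp, 1, AUTOSOME_LENGTHS[
                 snp_chrom[n_mqtl + seq_len(n_null_snp)]])))
  snp_pos <- pmax(1, pmin(snp_pos, AUTOSOME_LENGTHS[snp_chrom]))
  n_snps <- n_mqtl + n_null_snp
  snp_ids <- sprintf("rs%07d", seq_len(n_snps))
  maf <- runif(n_snps, cfg$maf_range[1], cfg$maf_range[2])
  snp_annot <- data.frame(snp_id = snp_ids, chrom = snp_chrom,
                          pos = snp_pos, maf = maf)

  ## External summary statistics for the poly-epigenetic score: weights on
  ## the PES CpGs with log-uniform external p-values so that the default
  ## inclusion thresholds select nested subsets.
  pes_w <- rnorm(length(pes_idx))
  summary_stats <- data.frame(cpg_id = cpg_ids[pes_idx], weight = pes_w,
                              p = 10^runif(length(pes_idx), -7, 0))

  clock <- make_toy_clock(cfg$clock_n_cpgs, cfg$clock_adult_age)
  clock_model <- list(
    intercept = -sum(clock$coefficient * clock$base),
    adult_age = cfg$clock_adult_age,
    coefficients = clock[, c("cpg_id", "coefficient")])
  class(clock_model) <- "mem_clock"

  batch_shift_cache <- new.env(parent = emptyenv())
  rho <- cfg$target_phenotype_correlation
  s_m <- cfg$test_scale_mean
  s_s <- cfg$test_scale_sd

  beta_list <- list()
  sheet_list <- list()
  geno_list <- list()
  truth_frac <- list()
  truth_lat <- list()
  truth_age <- list()

  for (co in cfg$cohorts) {
    n <- co$n
    ids <- sprintf("%s_S%04d", co$name, seq_len(n))
    n_f <- round(co$frac_female * n)
    sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
    age <- rtruncnorm(n, co$age_mean, co$age_sd, co$age_min, co$age_max)
    longitudinal <- co$n_longitudinal > 0L
    is_long <- seq_len(n) <= co$n_longitudinal
    interval <- rep(NA_real_, n)
    interval[is_long] <- rtruncnorm(sum(is_long), cfg$follow_up_mean,
                                    cfg$follow_up_sd,
                                    cfg$follow_up_mean - 3 * cfg$follow_up_sd,
                                    cfg$follow_up_mean + 3 * cfg$follow_up_sd)

    ## Latent factors: eta is the age-independent memory level residual,
    ## f_long the longitudinal factor, drawn with the target correlation.
    eta0 <- rnorm(n)
    f_long <- rho * eta0 + sqrt(1 - rho^2) * rnorm(n)

    ## Cell fractions and dosage draws.
    props <- cfg$cell_props[[co$tissue]]
    frac <- rdirichlet_rows(n, cfg$cell_concentration * props * K)
    colnames(frac) <- cfg$cell_types
    geno <- matrix(rbinom(n_snps * n, 2L, rep(maf, n)), nrow = n_snps,
                   dimnames = list(snp_ids, ids))

    ## Batch shift, shared across cohorts with the same batch label.
    if (is.null(batch_shift_cache[[co$batch]]))
      batch_shift_cache[[co$batch]] <-
        rnorm(n_cpgs, sd = cfg$batch_effect_sd)
    shift <- batch_shift_cache[[co$batch]]

    ## Assemble beta in CpG chunks: mixture mean + batch + noise.
    beta <- matrix(NA_real_, n_cpgs + cfg$clock_n_cpgs, n,
                   dimnames = list(c(cpg_ids, clock$cpg_id), ids))
    tf <- t(frac)
    for (ch in chunk_indices(n_cpgs, GEN_CHUNK)) {
      m <- ref[ch, , drop = FALSE] %*% tf + shift[ch]
      beta[ch, ] <- m + rnorm(length(m), sd = cfg$noise_sd)
    }
    if (n_mqtl > 0)
      beta[mqtl_idx, ] <- beta[mqtl_idx, ] +
        cfg$mqtl_effect * geno[seq_len(n_mqtl), , drop = FALSE]

    ## Planted poly-epigenetic score: mix the standardized score into the
    ## latent level so the score explains exactly pes_r2 of its variance.
    if (cfg$pes_r2 > 0 && length(pes_idx) > 0) {
      s <- as.numeric(crossprod(clip01(beta[pes_idx, , drop = FALSE]), pes_w))
      s <- (s - mean(s)) / sd(s)
      eta <- sqrt(1 - cfg$pes_r2) * eta0 + sqrt(cfg$pes_r2) * s
    } else eta <- eta0

    ## Planted phenotype effects: slope chosen so the correlation between
    ## the CpG's residual (noise-scale) methylation and the latent
    ## phenotype equals the configured standardized effect.
    if (length(planted_idx) > 0) {
      sl_c <- pe$rho_cross / sqrt(1 - pe$rho_cross^2) * cfg$noise_sd
      sl_l <- pe$rho_long / sqrt(1 - pe$rho_long^2) * cfg$noise_sd
      beta[planted_idx, ] <- beta[planted_idx, ] +
        outer(sl_c, eta) + outer(sl_l, f_long)
    }

    ## Toy clock CpGs: linear in the transformed (age + acceleration).
    accel <- rnorm(n, sd = cfg$clock_accel_sd)
    x <- horvath_transform(age + accel, cfg$clock_adult_age)
    beta[n_cpgs + seq_len(cfg$clock_n_cpgs), ] <-
      clock$base + outer(clock$slope, x) +
      rnorm(cfg$clock_n_cpgs * n, sd = cfg$clock_noise_sd)
    beta <- clip01(beta)

    ## Memory test scores: follow-up (sampling-visit) scores load on the
    ## level factor; baseline = follow-up + decline, so scores tend to be
    ## lower at follow-up.
    level <- -cfg$age_slope * (age - 70) + eta
    t2 <- sapply(seq_len(cfg$n_tests), function(t)
      s_m + s_s * (cfg$loadings[t] * level +
                     rnorm(n, sd = cfg$test_noise_sd)))
    decl <- sapply(seq_len(cfg$n_tests), function(t)
      s_s * (cfg$decline_means[t] - cfg$decline_loading * f_long +
               rnorm(n, sd = cfg$decline_noise_sd)))
    t1 <- t2 + decl

    sheet <- data.frame(sample_id = ids, cohort = co$name,
                        tissue = co$tissue, batch = co$batch, sex = sex,
                        stringsAsFactors = FALSE)
    if (longitudinal) {
      sheet$age_baseline <- ifelse(is_long, age - interval, NA_real_)
      sheet$age_followup <- age
      for (t in seq_len(cfg$n_tests)) {
        sheet[[sprintf("test%d_t1", t)]] <- ifelse(is_long, t1[, t], NA_real_)
        sheet[[sprintf("test%d_t2", t)]] <- t2[, t]
      }
    } else {
      sheet$age_baseline <- age
      sheet$age_followup <- NA_real_
      for (t in seq_len(cfg$n_tests)) {
        sheet[[sprintf("test%d_t1", t)]] <- t2[, t]
        sheet[[sprintf("test%d_t2", t)]] <- NA_real_
      }
    }

    beta_list[[co$name]] <- beta
    sheet_list[[co$name]] <- sheet
    geno_list[[co$name]] <- geno
    truth_frac[[co$name]] <- data.frame(sample_id = rep(ids, K),
                                        cell_type = rep(cfg$cell_types,
                                                        each = n),
                                        fraction = as.numeric(frac))
    truth_lat[[co$name]] <- data.frame(sample_id = ids, eta = eta,
                                       f_long = f_long)
    truth_age[[co$name]] <- data.frame(sample_id = ids, chron_age = age,
                                       true_dnam_age = age + accel,
                                       accel = accel)
  }

  ## Paired brain samples: taken from the first cohort large enough; at
  ## shared CpGs the brain profile tracks the individual buccal deviation
  ## with correlation brain_shared_r, elsewhere the tissues are independent.
  brain <- NULL
  truth_brain <- NULL
  truth_expr <- NULL
  expression <- NULL
  src <- which(vapply(cfg$cohorts, `[[`, 0L, "n") >= cfg$brain_n)[1]
  if (!is.na(src) && cfg$brain_n >= 3) {
    co_name <- cfg$cohorts[[src]]$name
    b_ids <- colnames(beta_list[[co_name]])[seq_len(cfg$brain_n)]
    bu <- beta_list[[co_name]][seq_len(n_cpgs), b_ids, drop = FALSE]
    shared <- sort(sample(n_cpgs, round(cfg$brain_shared_fraction * n_cpgs)))
    r <- cfg$brain_shared_r
    mu_b <- pmin(pmax(rowMeans(bu) + rnorm(n_cpgs, sd = 0.05), 0.05), 0.95)
    s_b <- pmax(matrixStats::rowSds(bu), 1e-6)
    z <- (bu - rowMeans(bu)) / s_b
    eps <- matrix(rnorm(n_cpgs * cfg$brain_n), n_cpgs)
    rr <- rep(0, n_cpgs)
    rr[shared] <- r
    bb <- mu_b + s_b * (rr * z + sqrt(1 - rr^2) * eps)
    bb <- clip01(bb)
    dimnames(bb) <- list(cpg_ids, b_ids)
    truth_brain <- data.frame(cpg_id = cpg_ids,
                              shared = seq_len(n_cpgs) %in% shared,
                              r_target = rr)

    ## CpG-gene expression pairs: unique genes, the first
    ## `expression_planted` pairs carry a true correlation.
    pool <- setdiff(seq_len(n_cpgs), pes_idx)
    pool <- pool[!duplicated(ann$cpg$gene[pool])]
    n_pairs <- min(cfg$expression_pairs, length(pool))
    pair_idx <- sample(pool, n_pairs)
    genes <- ann$cpg$gene[pair_idx]
    zb <- (bb[pair_idx, , drop = FALSE] -
             rowMeans(bb[pair_idx, , drop = FALSE])) /
      pmax(matrixStats::rowSds(bb[pair_idx, , drop = FALSE]), 1e-6)
    rho_e <- rep(0, n_pairs)
    rho_e[seq_len(min(cfg$expression_planted, n_pairs))] <-
      cfg$expression_rho
    expression <- rho_e * zb +
      sqrt(1 - rho_e^2) * matrix(rnorm(length(zb)), nrow(zb))
    dimnames(expression) <- list(genes, b_ids)
    truth_expr <- data.frame(cpg_id = cpg_ids[pair_idx], gene = genes,
                             rho_planted = rho_e)
    brain <- list(beta = bb, expression = expression, sample_ids = b_ids,
                  source_cohort = co_name)
  }

  truth_planted <- if (length(planted_idx) > 0)
    data.frame(cpg_id = cpg_ids[pe$cpg_index],
               rho_cross = pe$rho_cross, rho_long = pe$rho_long,
               slope_cross = pe$rho_cross / sqrt(1 - pe$rho_cross^2) *
                 cfg$noise_sd,
               slope_long = pe$rho_long / sqrt(1 - pe$rho_long^2) *
                 cfg$noise_sd)
  else data.frame(cpg_id = character(), rho_cross = numeric(),
                  rho_long = numeric(), slope_cross = numeric(),
                  slope_long = numeric())

  truth_mqtl <- data.frame(
    snp_id = snp_ids[seq_len(n_mqtl)],
    cpg_id = cpg_ids[mqtl_idx],
    effect = rep(cfg$mqtl_effect, n_mqtl),
    maf = maf[seq_len(n_mqtl)])

  ## Clock CpG annotation rows (placed on chr1 so every CpG is annotated).
  clk_ann <- data.frame(cpg_id = clock$cpg_id, chrom = 1L,
                        pos = seq_len(cfg$clock_n_cpgs) * 1000L,
                        gene = "CLOCK", stringsAsFactors = FALSE)

  structure(list(
    config = cfg,
    beta = beta_list,
    samples = sheet_list,
    genotypes = do.call(cbind, geno_list),
    annotation = list(cpg = rbind(ann$cpg, clk_ann), snp = snp_annot,
                      gene = ann$gene),
    cell_reference = ref,
    summary_stats = summary_stats,
    clock = clock_model,
    brain = brain,
    truth = list(planted = truth_planted,
                 cell_fractions = do.call(rbind, truth_frac),
                 mqtl = truth_mqtl,
                 dnam_age = do.call(rbind, truth_age),
                 latents = do.call(rbind, truth_lat),
                 expression_pairs = truth_expr,
                 brain_shared = truth_brain,
                 clock = clock)
  ), class = "mem_dataset")
}

#' @export
print.mem_dataset <- function(x, ...) {
  ns <- vapply(x$beta, ncol, 0L)
  cat("Synthetic methylation dataset\n")
  cat(sprintf("  cohorts: %s\n",
              paste(sprintf("%s (n=%d)", names(ns), ns), collapse = ", ")))
  cat(sprintf("  CpGs: %d (+%d clock)\n", x$config$n_cpgs,
              x$config$clock_n_cpgs))
  cat(sprintf("  SNPs: %d, planted effects: %d\n", nrow(x$annotation$snp),
              nrow(x$truth$planted)))
  invisible(x)
}

#' Write a synthetic dataset to tab-delimited files
#'
#' Emits the beta matrices, sample sheets, annotation, genotypes, cell
#' reference, summary statistics, clock, brain matrices and truth tables
#' in the package's text formats (UTF-8 TSV with header; beta matrices have
#' CpGs as rows and samples as columns; coordinates are 1-based). Every
#' file round-trips through the package's readers.
#'
#' @param ds a `mem_dataset`.
#' @param directory output directory, created if missing.
#' @return invisibly, a manifest data.frame (file, bytes, md5).
#' @export
write_dataset <- function(ds, directory) {
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE, showWarnings = FALSE))
      stopf("I/O error: cannot create directory '%s'", directory)
  files <- character()
  wt <- function(df, name) {
    path <- file.path(directory, name)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
    files <<- c(files, path)
  }
  mat_df <- function(m, key) {
    df <- data.table::as.data.table(m, keep.rownames = key)
    df
  }
  for (nm in names(ds$beta))
    wt(mat_df(ds$beta[[nm]], "cpg_id"), sprintf("beta_%s.tsv", nm))
  for (nm in names(ds$samples))
    wt(ds$samples[[nm]], sprintf("samples_%s.tsv", nm))
  wt(ds$annotation$cpg, "cpg_annotation.tsv")
  wt(ds$annotation$snp, "snp_annotation.tsv")
  wt(ds$annotation$gene, "gene_annotation.tsv")
  wt(mat_df(ds$genotypes, "snp_id"), "genotypes.tsv")
  wt(mat_df(ds$cell_reference, "cpg_id"), "cell_reference.tsv")
  wt(ds$summary_stats, "summary_stats.tsv")
  write_clock(ds$clock, file.path(directory, "clock.tsv"))
  files <- c(files, file.path(directory, "clock.tsv"))
  if (!is.null(ds$brain)) {
    wt(mat_df(ds$brain$beta, "cpg_id"), "beta_brain.tsv")
    wt(mat_df(ds$brain$expression, "gene"), "expression_brain.tsv")
  }
  wt(ds$truth$planted, "truth_planted.tsv")
  wt(ds$truth$cell_fractions, "truth_cell_fractions.tsv")
  wt(ds$truth$mqtl, "truth_mqtl.tsv")
  wt(ds$truth$dnam_age, "truth_dnam_age.tsv")
  wt(ds$truth$latents, "truth_latents.tsv")
  if (!is.null(ds$truth$expression_pairs))
    wt(ds$truth$expression_pairs, "truth_expression_pairs.tsv")
  info <- file.info(files)
  manifest <- data.frame(file = basename(files), bytes = info$size,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  invisible(manifest)
}
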