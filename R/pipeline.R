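## One-command end-to-end pipeline: phenotypes -> preprocessing ->
## per-cohort EWAS -> meta-analysis -> reports -> scores -> clock ->
## integration, with a machine-readable run manifest.

#' Build a pipeline configuration
#'
#' @param input_dir dataset directory (layout of [write_dataset()]);
#'   ignored when `dataset` is given.
#' @param out_dir output directory.
#' @param dataset optional in-memory dataset (as from [generate_dataset()]
#'   or [read_dataset()]).
#' @param k_pcs number of methylation PCs per cohort (`NULL` = automatic:
#'   80% of subset variance, capped at `max_k`).
#' @param max_k cap for automatic PC selection.
#' @param top_n_variance,r_threshold uncorrelated-CpG subset parameters.
#' @param suggestive,epigenome_wide significance thresholds.
#' @param pes_thresholds inclusion p-value thresholds for the
#'   poly-epigenetic scores.
#' @param n_bonferroni Bonferroni family size for score tests.
#' @param mqtl_window cis window in bp.
#' @param mqtl_gw_p genome-wide mQTL significance threshold.
#' @param mqtl_fdr FDR level for genetic-control flags.
#' @param meta_tissue tissue whose cohorts enter the meta-analysis.
#' @param residualize_long also age-residualize the longitudinal
#'   phenotype.
#' @param write_corrected also write the cell-type-corrected beta
#'   matrices (large; off by default).
#' @param seed stored in the manifest (the pipeline itself is
#'   deterministic).
#' @return a `mem_pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = "memewas_out",
                            dataset = NULL, k_pcs = NULL, max_k = 12L,
                            top_n_variance = 5000L, r_threshold = 0.2,
                            suggestive = 1e-5, epigenome_wide = 9e-8,
                            pes_thresholds = c(1e-5, 1e-3, 0.01, 0.05,
                                               0.5, 1),
                            n_bonferroni = 10L,
                            mqtl_window = 1e6, mqtl_gw_p = 1e-15,
                            mqtl_fdr = 0.05, meta_tissue = "buccal",
                            residualize_long = FALSE,
                            write_corrected = FALSE, seed = 1L) {
  if (is.null(input_dir) && is.null(dataset))
    stopf("either input_dir or dataset must be given")
  if (any(c(suggestive, epigenome_wide, pes_thresholds, mqtl_window,
            mqtl_fdr) <= 0))
    stopf("all thresholds must be positive")
  structure(as.list(environment()), class = "mem_pipeline_config")
}

#' Run the full pipeline
#'
#' Executes every analysis stage on a dataset directory (or in-memory
#' dataset), writes all result tables plus `manifest.json` and `run.log`
#' under `out_dir`, and returns the manifest. Stage failures abort with
#' the stage name; partial outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  written <- character()
  save_tsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    data.table::fwrite(df, p, sep = "\t", quote = FALSE, na = "NA")
    written <<- c(written, p)
  }
  stage <- "load"
  run_stage <- function(name, code) {
    stage <<- name
    tryCatch(code, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ds <- run_stage("load", {
    if (!is.null(config$dataset)) config$dataset
    else read_dataset(config$input_dir)
  })
  cohorts <- names(ds$beta)
  tiers <- significance_tiers(config$epigenome_wide, config$suggestive)
  ann <- ds$annotation$cpg

  ## Phenotypes -----------------------------------------------------------
  phen <- run_stage("phenotypes", {
    out <- lapply(cohorts, function(co)
      build_phenotypes(ds$samples[[co]],
                       residualize_long = config$residualize_long))
    names(out) <- cohorts
    out
  })
  for (co in cohorts) save_tsv(phen[[co]], sprintf("phenotypes_%s.tsv", co))
  logf("phenotypes: %s",
       paste(sprintf("%s n=%d (long %d)", cohorts,
                     vapply(phen, nrow, 0L),
                     vapply(phen, function(p) sum(is.finite(p$em_long)),
                            0L)), collapse = "; "))

  ## Preprocessing --------------------------------------------------------
  prep <- run_stage("preprocess", {
    out <- lapply(cohorts, function(co)
      preprocess_cohort(ds$beta[[co]], ds$cell_reference,
                        k = config$k_pcs,
                        top_n_variance = min(config$top_n_variance,
                                             nrow(ds$beta[[co]])),
                        r_threshold = config$r_threshold,
                        max_k = config$max_k))
    names(out) <- cohorts
    out
  })
  for (co in cohorts) {
    cov_df <- data.frame(sample_id = rownames(prep[[co]]$pcs),
                         prep[[co]]$pcs,
                         prep[[co]]$fractions, check.names = FALSE)
    save_tsv(cov_df, sprintf("covariates_%s.tsv", co))
    if (config$write_corrected) {
      p <- file.path(config$out_dir, sprintf("beta_corrected_%s.tsv", co))
      write_beta_matrix(prep[[co]]$beta_corrected, p)
      written <- c(written, p)
    }
    logf("preprocess %s: %d CpGs, %d PCs, %d subset CpGs", co,
         nrow(prep[[co]]$beta_corrected), ncol(prep[[co]]$pcs),
         length(prep[[co]]$cpg_subset))
  }

  ## Per-cohort EWAS ------------------------------------------------------
  phenos <- c("em_cross", "em_long")
  ewas <- run_stage("ewas", {
    out <- list()
    for (co in cohorts) {
      for (ph in phenos) {
        y <- setNames(phen[[co]][[ph]], phen[[co]]$sample_id)
        if (sum(is.finite(y)) < ncol(prep[[co]]$pcs) + 10L) next
        r <- run_ewas(prep[[co]]$beta_corrected, y,
                      covariates = prep[[co]]$pcs, cohort = co)
        out[[paste(co, ph, sep = ".")]] <- r
        save_tsv(r, sprintf("ewas_%s_%s.tsv", co, ph))
        logf("ewas %s/%s: n=%d, lambda=%.3f", co, ph, r$n[1],
             genomic_inflation(r$p[!is.na(r$p)],
                               min_p = min(100L, sum(!is.na(r$p)))))
      }
    }
    out
  })

  ## Meta-analysis and reports -------------------------------------------
  meta_cohorts <- cohorts[vapply(ds$samples, function(s)
    s$tissue[1], "") == config$meta_tissue]
  other_cohorts <- setdiff(cohorts, meta_cohorts)
  lambda <- list()
  meta <- run_stage("meta", {
    out <- list()
    for (ph in phenos) {
      keys <- paste(meta_cohorts, ph, sep = ".")
      keys <- keys[keys %in% names(ewas)]
      if (length(keys) >= 1L) {
        m <- fixed_effect_meta(ewas[keys])
        out[[ph]] <- m
        save_tsv(m, sprintf("meta_%s.tsv", ph))
        lambda[[paste0(ph, "_meta")]] <-
          genomic_inflation(m$p[!is.na(m$p)],
                            min_p = min(100L, sum(!is.na(m$p))))
        mt <- manhattan_table(classify_hits(m, tiers), ann, tiers)
        save_tsv(mt, sprintf("manhattan_%s.tsv", ph))
      }
      for (co in other_cohorts) {
        key <- paste(co, ph, sep = ".")
        if (key %in% names(ewas))
          lambda[[paste0(ph, "_", co)]] <-
            genomic_inflation(ewas[[key]]$p[!is.na(ewas[[key]]$p)],
                              min_p = min(100L,
                                          sum(!is.na(ewas[[key]]$p))))
      }
    }
    out
  })
  hits <- character()
  if (!is.null(meta$em_cross) && !is.null(meta$em_long)) {
    t2 <- cross_tabulate_phenotypes(meta$em_cross, meta$em_long, tiers,
                                    annotation = ann)
    save_tsv(t2, "table2_report.tsv")
    hits <- unique(t2$cpg_id)
    logf("meta: %d suggestive CpGs across phenotypes", length(hits))
  }
  ## Cross-tissue test-statistic concordance (meta tissue vs others).
  tissue_cor <- list()
  for (ph in phenos) {
    key_meta <- paste(meta_cohorts[1], ph, sep = ".")
    for (co in other_cohorts) {
      key <- paste(co, ph, sep = ".")
      if (!is.null(meta[[ph]]) && key %in% names(ewas)) {
        mm <- meta[[ph]]
        mm$t <- mm$z
        tc <- suppressWarnings(
          tissue_statistic_correlation(mm, ewas[[key]]))
        tissue_cor[[paste(ph, co, sep = "_")]] <-
          list(r = tc$r, p = tc$p, n_shared = tc$n_shared)
      }
    }
  }

  ## Poly-epigenetic scores ----------------------------------------------
  run_stage("scores", {
    if (!is.null(ds$summary_stats)) {
      rows <- list()
      for (co in cohorts) {
        for (th in config$pes_thresholds) {
          sc <- tryCatch(compute_pes(prep[[co]]$beta_corrected,
                                     ds$summary_stats, th),
                         error = function(e) NULL)
          if (is.null(sc)) next
          for (ph in phenos) {
            y <- setNames(phen[[co]][[ph]], phen[[co]]$sample_id)
            if (sum(is.finite(y)) < 10L) next
            a <- pes_association(sc, y, covariates = prep[[co]]$pcs,
                                 n_tests = config$n_bonferroni)
            a$cohort <- co
            a$phenotype <- ph
            a$threshold <- th
            rows[[length(rows) + 1L]] <- a
          }
        }
      }
      if (length(rows) > 0)
        save_tsv(do.call(rbind, rows), "pes_associations.tsv")
      logf("scores: %d PES association rows", length(rows))
    }
  })

  ## Epigenetic clock -----------------------------------------------------
  run_stage("clock", {
    if (!is.null(ds$clock)) {
      rows <- list()
      for (co in cohorts) {
        agev <- dnam_age(ds$beta[[co]], ds$clock)
        ph_tab <- phen[[co]]
        chron <- setNames(ph_tab$age, ph_tab$sample_id)[names(agev)]
        ok <- is.finite(chron)
        acc <- age_acceleration(agev[ok], chron[ok])
        covs <- data.frame(prep[[co]]$fractions[names(acc), , drop = FALSE],
                           check.names = FALSE)
        for (ph in phenos) {
          y <- setNames(ph_tab[[ph]], ph_tab$sample_id)
          if (sum(is.finite(y[names(acc)])) < 10L) next
          a <- acceleration_association(acc, y, covariates = covs)
          a$cohort <- co
          a$phenotype <- ph
          a$age_cor <- cor(agev[ok], chron[ok])
          rows[[length(rows) + 1L]] <- a
        }
        save_tsv(data.frame(sample_id = names(agev), dnam_age = agev,
                            chron_age = chron,
                            acceleration = acc[names(agev)]),
                 sprintf("clock_%s.tsv", co))
      }
      if (length(rows) > 0)
        save_tsv(do.call(rbind, rows), "clock_associations.tsv")
      logf("clock: %d association rows", length(rows))
    }
  })

  ## Integration ----------------------------------------------------------
  mqtl_summary <- NULL
  run_stage("integrate", {
    if (!is.null(ds$genotypes) && length(hits) > 0) {
      pooled_ids <- unlist(lapply(meta_cohorts, function(co)
        colnames(ds$beta[[co]])))
      bpool <- do.call(cbind, lapply(meta_cohorts, function(co)
        ds$beta[[co]][hits, , drop = FALSE]))
      fpool <- do.call(rbind, lapply(meta_cohorts, function(co)
        prep[[co]]$fractions))
      sexbatch <- do.call(rbind, lapply(meta_cohorts, function(co)
        ds$samples[[co]][c("sample_id", "sex", "batch")]))
      rownames(sexbatch) <- sexbatch$sample_id
      mq <- cis_mqtl_scan(bpool, ds$genotypes[, pooled_ids, drop = FALSE],
                          ds$annotation$cpg, ds$annotation$snp,
                          covariates = sexbatch,
                          window = config$mqtl_window,
                          cell_fractions = fpool)
      mq$genome_wide <- !is.na(mq$p) & mq$p < config$mqtl_gw_p
      save_tsv(mq, "mqtl_pairs.tsv")
      gc_flags <- genetic_control_flags(mq, hits, fdr = config$mqtl_fdr)
      save_tsv(gc_flags, "genetic_control.tsv")
      mqtl_summary <- list(
        n_pairs = nrow(mq),
        n_genome_wide = sum(mq$genome_wide),
        n_genetic_control = sum(gc_flags$status == "genetic_control"))
      logf("mqtl: %d cis pairs, %d CpGs under genetic control",
           nrow(mq), mqtl_summary$n_genetic_control)
    }
    if (!is.null(ds$brain)) {
      expr_genes <- rownames(ds$brain$expression)
      pairs <- ann[ann$gene %in% expr_genes &
                     ann$cpg_id %in% rownames(ds$brain$beta),
                   c("cpg_id", "gene")]
      if (nrow(pairs) > 0) {
        ec <- dnam_mrna_correlation(ds$brain$beta, ds$brain$expression,
                                    pairs)
        save_tsv(ec, "expr_correlation.tsv")
        logf("expr-corr: %d pairs, %d at q < 0.05", nrow(ec),
             sum(ec$q < 0.05, na.rm = TRUE))
      }
      ## locate the cohort the brain-paired individuals came from
      src <- ds$brain$source_cohort %||% cohorts[
        which(vapply(cohorts, function(co)
          all(colnames(ds$brain$beta) %in% colnames(ds$beta[[co]])),
          TRUE))[1]]
      if (!is.na(src) && src %in% cohorts) {
        map <- cross_tissue_map(ds$beta[[src]], ds$brain$beta)
        save_tsv(map[map$cpg_id %in% hits, ], "tissue_map_hits.tsv")
        logf("tissue map: %d CpGs, %.1f%% moderate/high", nrow(map),
             100 * mean(map$class != "low"))
      }
    }
  })

  ## Manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("memewas")),
    seed = config$seed,
    generated = format(t0, "%Y-%m-%d %H:%M:%S"),
    cohorts = lapply(phen, function(p) list(
      n = nrow(p), n_long = sum(is.finite(p$em_long)))),
    lambda = lambda,
    tissue_correlation = tissue_cor,
    n_suggestive = length(hits),
    suggestive_cpgs = hits,
    mqtl = mqtl_summary,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = {
      ck <- tools::md5sum(written)
      mapply(function(f, m) list(md5 = unname(m)), names(ck), ck,
             SIMPLIFY = FALSE, USE.NAMES = TRUE)
    })
  names(manifest$files) <- basename(written)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete in %.1f s", manifest$runtime_sec)
  invisible(manifest)
}
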