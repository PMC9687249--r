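## Readers and writers for the package's tab-delimited text formats.
## All files are UTF-8 TSV with a header row; beta matrices have CpG ids
## in the first column and samples as columns (use `orientation =
## "samples_by_cpgs"` for transposed input); genomic coordinates are
## 1-based inclusive.

#' Read a beta-value matrix
#'
#' @param path tab-delimited file, first column CpG (or sample) ids.
#' @param orientation `"cpgs_by_samples"` (default) or
#'   `"samples_by_cpgs"` (the matrix is transposed after reading).
#' @return CpGs x samples numeric matrix.
#' @export
read_beta_matrix <- function(path, orientation = c("cpgs_by_samples",
                                                   "samples_by_cpgs")) {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stopf("duplicate row ids in '%s' (e.g. '%s')", path,
          ids[duplicated(ids)][1])
  if (anyDuplicated(names(dt)[-1]))
    stopf("duplicate column ids in '%s'", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!is.numeric(m)) stopf("non-numeric values in '%s'", path)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("beta value %.4g outside [0, 1] at row '%s', column '%s' of '%s'",
          m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
          colnames(m)[bad[1, 2]], path)
  if (orientation == "samples_by_cpgs") m <- t(m)
  message(sprintf("read_beta_matrix: %d CpGs x %d samples from %s",
                  nrow(m), ncol(m), basename(path)))
  m
}

#' Write a beta-value matrix
#' @param beta CpGs x samples matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_beta_matrix <- function(beta, path) {
  data.table::fwrite(data.table::as.data.table(beta, keep.rownames = "cpg_id"),
                     path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample sheet
#' @param path tab-delimited sample sheet with a `sample_id` column.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (!"sample_id" %in% names(d))
    stopf("sample sheet '%s' lacks a sample_id column", path)
  if (anyDuplicated(d$sample_id))
    stopf("duplicate sample ids in '%s'", path)
  d
}

#' Read a generic id-keyed numeric matrix (genotypes, expression)
#' @param path tab-delimited file, first column feature ids.
#' @return features x samples numeric matrix.
#' @export
read_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Read a feature annotation table
#' @param path tab-delimited file with an id column plus `chrom`, `pos`.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("chrom", "pos")
  if (!all(need %in% names(d)))
    stopf("annotation '%s' must have columns chrom and pos", path)
  if (any(d$pos < 1)) stopf("positions must be 1-based (>= 1) in '%s'", path)
  d
}

#' Read external EWAS summary statistics for score construction
#' @param path tab-delimited file with `cpg_id`, `weight`, `p`.
#' @return data.frame.
#' @export
read_summary_stats <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("cpg_id", "weight", "p")
  if (!all(need %in% names(d)))
    stopf("summary statistics '%s' must have columns %s", path,
          paste(need, collapse = ", "))
  if (any(d$p <= 0 | d$p > 1, na.rm = TRUE))
    stopf("summary-statistic p-values must lie in (0, 1] in '%s'", path)
  d
}

#' Read a previously written synthetic dataset directory
#'
#' Inverse of [write_dataset()]: reads every cohort's beta matrix and
#' sample sheet plus the shared annotation, genotype, reference, summary
#' statistics, clock, brain, and truth files that are present.
#'
#' @param directory dataset directory.
#' @return list mirroring the in-memory `mem_dataset` layout.
#' @export
read_dataset <- function(directory) {
  lf <- list.files(directory)
  bfiles <- setdiff(grep("^beta_.*\\.tsv$", lf, value = TRUE),
                    "beta_brain.tsv")
  cohorts <- sub("^beta_(.*)\\.tsv$", "\\1", bfiles)
  rd <- function(name) {
    p <- file.path(directory, name)
    if (file.exists(p)) as.data.frame(data.table::fread(p, sep = "\t"))
    else NULL
  }
  beta <- lapply(cohorts, function(co)
    read_matrix(file.path(directory, sprintf("beta_%s.tsv", co))))
  names(beta) <- cohorts
  samples <- lapply(cohorts, function(co)
    read_sample_sheet(file.path(directory, sprintf("samples_%s.tsv", co))))
  names(samples) <- cohorts
  brain <- NULL
  if (file.exists(file.path(directory, "beta_brain.tsv")))
    brain <- list(
      beta = read_matrix(file.path(directory, "beta_brain.tsv")),
      expression = read_matrix(file.path(directory,
                                         "expression_brain.tsv")))
  list(beta = beta, samples = samples,
       annotation = list(cpg = rd("cpg_annotation.tsv"),
                         snp = rd("snp_annotation.tsv"),
                         gene = rd("gene_annotation.tsv")),
       genotypes = if (file.exists(file.path(directory, "genotypes.tsv")))
         read_matrix(file.path(directory, "genotypes.tsv")) else NULL,
       cell_reference = if (file.exists(file.path(directory,
                                                  "cell_reference.tsv")))
         read_matrix(file.path(directory, "cell_reference.tsv")) else NULL,
       summary_stats = rd("summary_stats.tsv"),
       clock = if (file.exists(file.path(directory, "clock.tsv")))
         read_clock(file.path(directory, "clock.tsv")) else NULL,
       brain = brain,
       truth = list(planted = rd("truth_planted.tsv"),
                    cell_fractions = rd("truth_cell_fractions.tsv"),
                    mqtl = rd("truth_mqtl.tsv"),
                    dnam_age = rd("truth_dnam_age.tsv"),
                    latents = rd("truth_latents.tsv"),
                    expression_pairs = rd("truth_expression_pairs.tsv")))
}
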