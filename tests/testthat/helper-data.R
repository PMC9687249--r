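# Shared fixtures, built in code. `small_config()` is a desk-scale version
# of the default study layout; `test_dataset()` caches one generated
# dataset for reuse across test files.

small_config <- function(seed = 42L, brain_n = 30L, ...) {
  args <- list(
    cohorts = list(
      cohort_spec("buccal1", n = 60, n_longitudinal = 50,
                  tissue = "buccal", batch = "b1",
                  age_mean = 76, age_sd = 4, age_min = 65, age_max = 86,
                  frac_female = 0.5),
      cohort_spec("buccal2", n = 45, n_longitudinal = 35,
                  tissue = "buccal", batch = "b2",
                  age_mean = 76, age_sd = 4, age_min = 66, age_max = 90,
                  frac_female = 0.5),
      cohort_spec("bbhi", n = 40, n_longitudinal = 0, tissue = "buccal",
                  batch = "b3", age_mean = 54, age_sd = 7,
                  age_min = 30, age_max = 67, frac_female = 0.46),
      cohort_spec("blood", n = 50, n_longitudinal = 40, tissue = "blood",
                  batch = "b4", age_mean = 76, age_sd = 4,
                  age_min = 65, age_max = 90, frac_female = 0.5)),
    n_cpgs = 400L,
    planted_effects = data.frame(cpg_index = c(11L, 101L, 201L),
                                 rho_cross = c(0.3, 0, 0.25),
                                 rho_long = c(0, 0.3, 0.25)),
    pes_n_cpgs = 50L,
    mqtl_fraction = 0.05,
    brain_n = brain_n,
    expression_pairs = 8L,
    expression_planted = 2L,
    seed = seed)
  args <- utils::modifyList(args, list(...), keep.null = TRUE)
  do.call(generator_config, args)
}

.dataset_cache <- new.env(parent = emptyenv())

test_dataset <- function() {
  if (is.null(.dataset_cache$ds))
    .dataset_cache$ds <- generate_dataset(small_config())
  .dataset_cache$ds
}

# Truth cell fractions in wide matrix form for one cohort.
truth_fraction_matrix <- function(ds, cohort) {
  tr <- ds$truth$cell_fractions
  ids <- colnames(ds$beta[[cohort]])
  tr <- tr[tr$sample_id %in% ids, ]
  m <- matrix(NA_real_, length(ids),
              length(unique(tr$cell_type)),
              dimnames = list(ids, unique(tr$cell_type)))
  m[cbind(match(tr$sample_id, ids), match(tr$cell_type, colnames(m)))] <-
    tr$fraction
  m
}

# Independent brute-force OLS oracle: full normal-equations fit returning
# coefficient table (estimate, se, t, p) for the design [1, predictors].
ols_oracle <- function(y, x) {
  x <- cbind(1, as.matrix(x))
  xtx <- solve(t(x) %*% x)
  bhat <- xtx %*% t(x) %*% y
  res <- y - x %*% bhat
  df <- length(y) - ncol(x)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(xtx) * s2)
  tval <- bhat / se
  list(coef = as.numeric(bhat), se = as.numeric(se), t = as.numeric(tval),
       p = as.numeric(2 * pt(-abs(tval), df)), df = df,
       resid = as.numeric(res))
}

# Brute-force BH step-up oracle (literal definition).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[o][i:m] * m / (i:m)
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}
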