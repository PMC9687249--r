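mk_study <- function(effect, se, cpg = paste0("cg", seq_along(effect)),
                     n = 100) {
  data.frame(cpg_id = cpg, effect = effect, se = se, n = n)
}

test_that("fixed-effect closed forms hold", {
  m <- fixed_effect_meta(list(a = mk_study(1, 1), b = mk_study(3, 1)))
  expect_equal(m$effect, 2)
  expect_equal(m$se, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$direction, "++")
  ## k identical studies: same effect, se / sqrt(k)
  s <- mk_study(c(0.5, -0.2), c(0.1, 0.3))
  m4 <- fixed_effect_meta(list(s, s, s, s))
  expect_equal(m4$effect[match(c("cg1", "cg2"), m4$cpg_id)], c(0.5, -0.2))
  expect_equal(m4$se[match("cg1", m4$cpg_id)], 0.1 / 2, tolerance = 1e-12)
  expect_equal(m4$direction[match("cg2", m4$cpg_id)], "----")
  expect_equal(m4$Q[match("cg1", m4$cpg_id)], 0, tolerance = 1e-12)
})

test_that("random triples match the brute-force formulas", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      eff <- rnorm(3)
      se <- runif(3, 0.5, 2)
      m <- fixed_effect_meta(list(mk_study(eff[1], se[1]),
                                  mk_study(eff[2], se[2]),
                                  mk_study(eff[3], se[3])))
      w <- 1 / se^2
      bhat <- sum(w * eff) / sum(w)
      expect_equal(m$effect, bhat, tolerance = 1e-10)
      expect_equal(m$se, 1 / sqrt(sum(w)), tolerance = 1e-10)
      expect_equal(m$z, bhat * sqrt(sum(w)), tolerance = 1e-10)
      expect_equal(m$p, 2 * pnorm(-abs(m$z)), tolerance = 1e-10)
      q <- sum(w * (eff - bhat)^2)
      expect_equal(m$Q, q, tolerance = 1e-10)
      expect_equal(m$I2, max(0, (q - 2) / q), tolerance = 1e-10)
      ## meta se never exceeds the smallest per-study se
      expect_lte(m$se, min(se))
    }
  })
})

test_that("single-study CpGs pass through flagged and bad se is excluded", {
  a <- mk_study(c(1, 2), c(0.5, 0.5), cpg = c("cg1", "cg2"))
  b <- mk_study(1.5, 0.5, cpg = "cg1")
  m <- fixed_effect_meta(list(a, b))
  expect_equal(m$k_studies[match("cg2", m$cpg_id)], 1L)
  expect_equal(m$effect[match("cg2", m$cpg_id)], 2)
  expect_equal(m$k_studies[match("cg1", m$cpg_id)], 2L)
  ## non-positive se drops that study for the CpG
  c <- mk_study(99, -1, cpg = "cg1")
  m2 <- fixed_effect_meta(list(a, c))
  expect_equal(m2$k_studies[match("cg1", m2$cpg_id)], 1L)
  expect_equal(m2$effect[match("cg1", m2$cpg_id)], 1)
})

test_that("meta of split halves approximates the pooled analysis", {
  ## moderate signal and n large enough that the z-based meta p and the
  ## t-based pooled p agree in the tail (small-sample df differences are
  ## acknowledged by the 10% log-scale tolerance)
  b <- withr::with_seed(42, {
    m <- matrix(runif(40 * 800, 0.2, 0.8), 40, 800,
                dimnames = list(sprintf("cg%03d", 1:40),
                                sprintf("s%03d", 1:800)))
    m
  })
  y <- withr::with_seed(43,
    setNames(0.2 * scale(b[5, ])[, 1] + rnorm(800), colnames(b)))
  pooled <- run_ewas(b, y)
  h1 <- colnames(b)[1:400]
  h2 <- colnames(b)[401:800]
  m <- fixed_effect_meta(list(run_ewas(b[, h1], y[h1]),
                              run_ewas(b[, h2], y[h2])))
  m <- m[match(pooled$cpg_id, m$cpg_id), ]
  ## agreement on the -log10 scale for the non-null CpG
  i <- 5
  expect_lt(abs(log10(m$p[i]) - log10(pooled$p[i])),
            0.1 * abs(log10(pooled$p[i])))
  ## and effects agree closely throughout
  expect_gt(cor(m$effect, pooled$effect), 0.98)
})

test_that("cross_tabulate_phenotypes applies the nominal rule strictly", {
  tiers <- significance_tiers()
  cross <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                      effect = c(1, -1, 2), p = c(1e-6, 5e-6, 0.5))
  long <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                     effect = c(0.5, -2, 1), p = c(0.04, 0.05, 1e-7))
  out <- cross_tabulate_phenotypes(cross, long, tiers)
  cs <- out[out$panel == "cross_sectional", ]
  expect_equal(cs$concordant[match("cg1", cs$cpg_id)], TRUE)
  expect_equal(cs$concordant[match("cg2", cs$cpg_id)], FALSE)  # p = 0.05
  lg <- out[out$panel == "longitudinal", ]
  expect_equal(lg$cpg_id, "cg3")
  ## cg3 is suggestive longitudinally but its cross-sectional p of 0.5 is
  ## not nominal, so it is sign-concordant yet not flagged concordant
  expect_true(lg$sign_concordant)
  expect_false(lg$concordant)
})

test_that("planted shared effects appear in both panels with matched signs", {
  ds <- test_dataset()
  phens <- lapply(c("buccal1", "buccal2"), function(co) {
    ph <- build_phenotypes(ds$samples[[co]])
    pp <- preprocess_cohort(ds$beta[[co]], ds$cell_reference,
                            top_n_variance = 200L)
    list(ph = ph, pp = pp, co = co)
  })
  run_one <- function(outcome) {
    fixed_effect_meta(lapply(phens, function(z) {
      y <- setNames(z$ph[[outcome]], z$ph$sample_id)
      run_ewas(z$pp$beta_corrected, y, covariates = z$pp$pcs,
               cohort = z$co)
    }))
  }
  mc <- run_one("em_cross")
  ml <- run_one("em_long")
  shared <- ds$truth$planted[ds$truth$planted$rho_cross > 0 &
                               ds$truth$planted$rho_long > 0, ]
  i <- match(shared$cpg_id, mc$cpg_id)
  j <- match(shared$cpg_id, ml$cpg_id)
  ## same sign in both phenotypes (planted with positive rho in both)
  expect_true(all(sign(mc$effect[i]) == sign(ml$effect[j])))
  ## and well-ranked in both scans (weak planted effects at small n, so
  ## check enrichment rather than significance)
  expect_lt(median(rank(mc$p)[i]) / nrow(mc), 0.2)
  expect_lt(median(rank(ml$p)[j]) / nrow(ml), 0.2)
})

test_that("tissue statistic correlation behaves across sharing levels", {
  a <- mk_study(rnorm(1500), runif(1500, 0.5, 1),
                cpg = sprintf("cg%04d", 1:1500))
  a$t <- a$effect / a$se
  self <- tissue_statistic_correlation(a, a)
  expect_equal(self$r, 1, tolerance = 1e-12)
  withr::with_seed(44, {
    mk_cor <- function(rho) {
      b <- a
      b$t <- rho * a$t + sqrt(1 - rho^2) * rnorm(1500) * sd(a$t)
      tissue_statistic_correlation(a, b)$r
    }
    r0 <- mk_cor(0)
    r5 <- mk_cor(0.5)
    expect_lt(abs(r0), 0.08)
    expect_true(r0 < r5 && r5 < self$r)
  })
  expect_warning(
    tissue_statistic_correlation(a[1:500, ], a[1:500, ]), "500")
})
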