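test_that("bh_adjust equals the brute-force step-up on random vectors", {
  withr::with_seed(61, {
    for (rep in 1:200) {
      m <- sample(1:50, 1)
      p <- runif(m)^sample(1:3, 1)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
  ## q >= p component-wise and NA passthrough
  p <- c(0.01, NA, 0.5, 0.04)
  q <- bh_adjust(p)
  expect_true(all(q[!is.na(p)] >= p[!is.na(p)]))
  expect_true(is.na(q[2]))
})

mqtl_fixture <- function() {
  withr::with_seed(62, {
    n <- 80
    ids <- paste0("s", 1:n)
    cpg_annot <- data.frame(cpg_id = c("cpgA", "cpgB"),
                            chrom = c(1, 1),
                            pos = c(5e6, 5e6))
    snp_annot <- data.frame(
      snp_id = c("snp_in", "snp_edge", "snp_out", "snp_chr2", "snp_mono"),
      chrom = c(1, 1, 1, 2, 1),
      pos = c(4.1e6, 6e6, 6e6 + 1, 5e6, 5.2e6))
    g <- rbind(snp_in = rbinom(n, 2, 0.3),
               snp_edge = rbinom(n, 2, 0.4),
               snp_out = rbinom(n, 2, 0.3),
               snp_chr2 = rbinom(n, 2, 0.3),
               snp_mono = rep(1, n))
    colnames(g) <- ids
    b <- rbind(cpgA = pmin(pmax(0.4 + 0.05 * g["snp_in", ] +
                                  rnorm(n, sd = 0.02), 0), 1),
               cpgB = runif(n, 0.3, 0.7))
    colnames(b) <- ids
    list(b = b, g = g, ca = cpg_annot, sa = snp_annot, ids = ids)
  })
}

test_that("cis window rules are inclusive at 1 Mb and symmetric", {
  fx <- mqtl_fixture()
  mq <- cis_mqtl_scan(fx$b, fx$g, fx$ca, fx$sa)
  pairs <- paste(mq$snp_id, mq$cpg_id)
  expect_true("snp_in cpgA" %in% pairs)        # 900 kb away
  expect_true("snp_edge cpgA" %in% pairs)      # exactly 1 Mb: inclusive
  expect_false("snp_out cpgA" %in% pairs)      # 1 Mb + 1 bp: excluded
  expect_false("snp_chr2 cpgA" %in% pairs)     # different chromosome
  expect_false(any(mq$snp_id == "snp_mono"))   # monomorphic skipped
  expect_equal(attr(mq, "n_monomorphic"), 1L)
  expect_true(all(abs(mq$distance) <= 1e6))
  ## symmetry: anchoring the window on SNPs instead of CpGs gives the
  ## same tested pair set
  swapped <- expand.grid(snp = fx$sa$snp_id, cpg = fx$ca$cpg_id)
  swapped$keep <- apply(swapped, 1, function(r) {
    s <- fx$sa[fx$sa$snp_id == r[["snp"]], ]
    c <- fx$ca[fx$ca$cpg_id == r[["cpg"]], ]
    s$chrom == c$chrom && abs(c$pos - s$pos) <= 1e6
  })
  manual <- with(swapped[swapped$keep & swapped$snp != "snp_mono", ],
                 sort(paste(snp, cpg)))
  expect_equal(sort(pairs), manual)
})

test_that("cis_mqtl_scan matches the per-pair OLS oracle", {
  fx <- mqtl_fixture()
  covs <- data.frame(sex = rep(c("F", "M"), 40),
                     pc = withr::with_seed(63, rnorm(80)),
                     row.names = fx$ids)
  mq <- cis_mqtl_scan(fx$b, fx$g, fx$ca, fx$sa, covariates = covs)
  i <- which(mq$snp_id == "snp_in" & mq$cpg_id == "cpgA")
  o <- ols_oracle(fx$b["cpgA", ],
                  cbind(fx$g["snp_in", ], covs$sex == "M", covs$pc))
  expect_equal(mq$beta_additive[i], o$coef[2], tolerance = 1e-8)
  expect_equal(mq$se[i], o$se[2], tolerance = 1e-8)
  expect_equal(mq$p[i], o$p[2], tolerance = 1e-8)
  ## the planted 0.05/allele effect is detected
  expect_lt(abs(mq$beta_additive[i] - 0.05), 0.02)
  expect_lt(mq$p[i], 1e-10)
  expect_error(cis_mqtl_scan(fx$b, fx$g * 2, fx$ca, fx$sa), "0, 2")
})

test_that("genetic_control_flags matches a hand BH computation", {
  mq <- data.frame(snp_id = paste0("snp", 1:10),
                   cpg_id = rep(c("cg1", "cg2"), each = 5),
                   p = c(0.001, 0.2, 0.9, 0.04, 0.5,
                         0.6, 0.7, 0.8, 0.9, 0.95))
  fl <- genetic_control_flags(mq, c("cg1", "cg2", "cg3"), fdr = 0.05)
  ## hand BH over the 10 pairs: smallest p = 0.001 -> q = 0.01 < 0.05
  q_hand <- bh_oracle(mq$p)
  expect_lt(min(q_hand[mq$cpg_id == "cg1"]), 0.05)
  expect_gte(min(q_hand[mq$cpg_id == "cg2"]), 0.05)
  expect_equal(fl$status, c("genetic_control", "not_significant",
                            "untestable"))
  expect_equal(fl$min_q[1], min(q_hand[1:5]), tolerance = 1e-12)
  ## all p = 1 -> nothing flagged
  mq1 <- transform(mq, p = 1)
  expect_true(all(genetic_control_flags(mq1, c("cg1", "cg2"))$status ==
                    "not_significant"))
})

test_that("spearman correlation honours monotone invariance", {
  withr::with_seed(64, {
    n <- 40
    ids <- paste0("s", 1:n)
    x <- runif(n, 0.2, 0.8)
    b <- matrix(x, 1, n, dimnames = list("cg1", ids))
    ## strictly increasing transform -> rho exactly 1
    e_up <- matrix(exp(3 * x), 1, n, dimnames = list("g1", ids))
    pairs <- data.frame(cpg_id = "cg1", gene = "g1")
    expect_equal(dnam_mrna_correlation(b, e_up, pairs)$rho, 1)
    ## reversed ranks -> -1
    e_dn <- matrix(-x^3, 1, n, dimnames = list("g1", ids))
    expect_equal(dnam_mrna_correlation(b, e_dn, pairs)$rho, -1)
    ## invariance of rho under monotone transforms of either side
    y <- rnorm(n)
    e1 <- matrix(y, 1, n, dimnames = list("g1", ids))
    e2 <- matrix(qlogis(plogis(y)) * 5 + 2, 1, n,
                 dimnames = list("g1", ids))
    r1 <- dnam_mrna_correlation(b, e1, pairs)$rho
    r2 <- dnam_mrna_correlation(b, e2, pairs)$rho
    expect_equal(r1, r2, tolerance = 1e-12)
    ## zero-variance expression -> NA record
    e0 <- matrix(1, 1, n, dimnames = list("g1", ids))
    expect_true(is.na(dnam_mrna_correlation(b, e0, pairs)$rho))
  })
})

test_that("planted expression pairs are recovered through BH", {
  ## The BH/Spearman machinery is exercised at a clearly detectable
  ## planted correlation (0.6); the default world's 0.34 at n = 120 sits
  ## near the detection boundary and is checked by rank only.
  hits <- vapply(1:10, function(s) {
    ds <- generate_dataset(small_config(seed = 700L + s,
                                        expression_rho = 0.6,
                                        brain_n = 60L))
    ec <- dnam_mrna_correlation(ds$brain$beta, ds$brain$expression,
                                ds$truth$expression_pairs)
    planted <- ds$truth$expression_pairs$rho_planted > 0
    all(ec$q[planted] < 0.05) && !any(ec$q[!planted] < 0.05)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  ## default world: planted pairs rank top-2 by p
  ds <- generate_dataset(generator_config(n_cpgs = 500L, seed = 65L))
  ec <- dnam_mrna_correlation(ds$brain$beta, ds$brain$expression,
                              ds$truth$expression_pairs)
  planted <- ds$truth$expression_pairs$rho_planted > 0
  expect_true(all(rank(ec$p)[planted] <= 2))
})

test_that("cross_tissue_map classifies and recovers shared CpGs", {
  ds <- test_dataset()
  map <- suppressMessages(cross_tissue_map(ds$beta$buccal1,
                                           ds$brain$beta))
  sh <- ds$truth$brain_shared
  shared_ids <- sh$cpg_id[sh$shared]
  sens <- mean(map$class[match(shared_ids, map$cpg_id)] != "low")
  expect_gte(sens, 0.9)
  ## identity map: all r = 1, all high
  m2 <- cross_tissue_map(ds$brain$beta, ds$brain$beta)
  expect_true(all(abs(m2$r - 1) < 1e-12))
  expect_true(all(m2$class == "high"))
  ## independent tissues: small average |r|
  withr::with_seed(66, {
    a <- matrix(runif(1000 * 120), 1000, 120,
                dimnames = list(sprintf("cg%04d", 1:1000),
                                paste0("s", 1:120)))
    b <- matrix(runif(1000 * 120), 1000, 120, dimnames = dimnames(a))
    m3 <- cross_tissue_map(a, b)
    expect_lt(mean(abs(m3$r)), 0.08)
  })
  expect_error(cross_tissue_map(ds$brain$beta[, 1:5],
                                ds$brain$beta[, 1:5]), "matched")
})

test_that("prior_evidence_join annotates hits and checks directions", {
  hits <- data.frame(cpg_id = paste0("cg", 1:5),
                     gene = c("A", "B", "C", "D", "E"),
                     effect = c(1, -1, 2, -2, 0.5))
  ## empty evidence: hits unchanged plus empty columns
  ev0 <- data.frame(cpg_id = character(), source = character(),
                    direction = character())
  j0 <- prior_evidence_join(hits, ev0)
  expect_equal(nrow(j0), 5L)
  expect_true(all(is.na(j0$source)))
  ## gene-keyed evidence matching 2 of 5
  evg <- data.frame(gene = c("B", "D"), source = "study1")
  jg <- prior_evidence_join(hits, evg)
  expect_equal(sum(!is.na(jg$source)), 2L)
  ## sign concordance on a 4-row fixture (hand enumeration)
  ev <- data.frame(cpg_id = paste0("cg", 1:4),
                   direction = c("+", "-", "-", "-"))
  j <- prior_evidence_join(hits, ev)
  j <- j[match(paste0("cg", 1:4), j$cpg_id), ]
  expect_equal(j$direction_concordant, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(prior_evidence_join(hits, data.frame(x = 1)), "schema")
})
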