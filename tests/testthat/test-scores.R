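test_that("compute_pes sums weighted betas over passing CpGs", {
  b <- matrix(c(0.6, 0.2), 2, 3,
              dimnames = list(c("cgA", "cgB"), paste0("s", 1:3)))
  st <- data.frame(cpg_id = c("cgA", "cgB"), weight = c(1, -1),
                   p = c(0.001, 0.002))
  sc <- compute_pes(b, st, p_threshold = 0.01)
  expect_equal(as.numeric(sc), rep(0.4, 3), tolerance = 1e-12)
  expect_equal(attr(sc, "n_cpgs_used"), 2L)
  ## a threshold that excludes nothing equals the all-pass threshold
  expect_equal(compute_pes(b, st, 1.1), compute_pes(b, st, 0.5),
               ignore_attr = TRUE)
  expect_error(compute_pes(b, st, 1e-9), "threshold")
  ## brute-force loop oracle on random input
  withr::with_seed(51, {
    bb <- matrix(runif(50 * 8), 50, 8,
                 dimnames = list(sprintf("cg%03d", 1:50),
                                 paste0("s", 1:8)))
    ss <- data.frame(cpg_id = rownames(bb), weight = rnorm(50),
                     p = runif(50))
    sc2 <- compute_pes(bb, ss, 0.3)
    manual <- sapply(colnames(bb), function(s) {
      tot <- 0
      for (i in seq_len(50))
        if (ss$p[i] < 0.3) tot <- tot + ss$weight[i] * bb[ss$cpg_id[i], s]
      tot
    })
    expect_equal(as.numeric(sc2), unname(manual), tolerance = 1e-12)
  })
})

test_that("PES thresholds are nested", {
  ds <- test_dataset()
  st <- ds$summary_stats
  b <- ds$beta$buccal1
  used <- sapply(c(1e-3, 0.01, 0.05, 0.5, 1.0), function(th) {
    sel <- st$cpg_id[st$p < th]
    sel
  })
  for (i in seq_len(length(used) - 1))
    expect_true(all(used[[i]] %in% used[[i + 1]]))
})

test_that("pes_association reports incremental variance explained", {
  withr::with_seed(52, {
    n <- 120
    ids <- paste0("s", 1:n)
    covs <- data.frame(age = runif(n, 60, 80), row.names = ids)
    sc <- setNames(rnorm(n), ids)
    ## phenotype exactly equal to the score: incremental R^2 = 1
    a1 <- pes_association(sc, sc)
    expect_equal(a1$incremental_r2, 1, tolerance = 1e-10)
    ## null score: tiny incremental R^2
    y <- setNames(rnorm(n), ids)
    a0 <- pes_association(sc, y, covariates = covs)
    expect_lt(a0$incremental_r2, 0.08)
    ## oracle: two explicit lm fits
    y2 <- setNames(0.3 * sc + rnorm(n), ids)
    a <- pes_association(sc, y2, covariates = covs, n_tests = 10)
    f0 <- summary(lm(y2 ~ covs$age))
    f1 <- summary(lm(y2 ~ covs$age + sc))
    expect_equal(a$incremental_r2, f1$r.squared - f0$r.squared,
                 tolerance = 1e-8)
    expect_equal(a$p, coef(f1)["sc", 4], tolerance = 1e-8)
    expect_equal(a$p_adjusted, min(1, 10 * a$p))
    ## constant score -> flagged NA
    ac <- pes_association(setNames(rep(1, n), ids), y)
    expect_true(is.na(ac$p))
    expect_equal(ac$reason, "constant_predictor")
  })
})

test_that("the clock transform has its fixed point and is monotone", {
  expect_identical(horvath_inverse(0), 20)
  ## continuity across the knot and monotonicity
  x <- seq(-3, 3, by = 0.001)
  a <- horvath_inverse(x)
  expect_true(all(diff(a) > 0))
  expect_lt(abs(horvath_inverse(-1e-9) - horvath_inverse(1e-9)), 1e-6)
  ## round trip with the forward transform
  ages <- c(0.5, 5, 19, 20, 21, 50, 90)
  expect_equal(horvath_inverse(horvath_transform(ages)), ages,
               tolerance = 1e-10)
})

test_that("dnam_age inverts the toy clock within 2 years", {
  ds <- test_dataset()
  for (co in c("buccal1", "blood")) {
    est <- dnam_age(ds$beta[[co]], ds$clock)
    tr <- ds$truth$dnam_age
    tr <- tr[match(names(est), tr$sample_id), ]
    expect_lt(mean(abs(est - tr$true_dnam_age)), 2)
    expect_gt(cor(est, tr$chron_age), 0.5)
  }
})

test_that("dnam_age enforces coverage and imputes missing CpGs", {
  ds <- test_dataset()
  b <- ds$beta$buccal1
  clk <- ds$clock
  ## drop one clock CpG (90% coverage): imputed with a message
  b1 <- b[setdiff(rownames(b), clk$coefficients$cpg_id[1]), ]
  expect_message(est <- dnam_age(b1, clk), "imputing 1")
  expect_true(all(is.finite(est)))
  ## drop three (70% coverage): error
  b3 <- b[setdiff(rownames(b), clk$coefficients$cpg_id[1:3]), ]
  expect_error(dnam_age(b3, clk), "coverage")
})

test_that("age_acceleration is the hat-matrix residual", {
  withr::with_seed(53, {
    n <- 60
    age <- runif(n, 60, 85)
    da <- setNames(age + rnorm(n, sd = 2), paste0("s", 1:n))
    acc <- age_acceleration(da, age)
    expect_lt(abs(sum(acc * age)), 1e-6)
    expect_lt(abs(sum(acc)), 1e-8)
    expect_equal(unname(age_acceleration(setNames(age, names(da)), age)),
                 rep(0, n), tolerance = 1e-10)
    ## shifting one observation by +5 moves its residual by 5(1 - h_ii)
    x <- cbind(1, age)
    h <- x %*% solve(crossprod(x)) %*% t(x)
    da2 <- da
    da2[7] <- da2[7] + 5
    acc2 <- age_acceleration(da2, age)
    expect_equal(unname(acc2[7] - acc[7]), 5 * (1 - h[7, 7]),
                 tolerance = 1e-8)
  })
})

test_that("acceleration_association matches lm and detects real signal", {
  withr::with_seed(54, {
    n <- 100
    ids <- paste0("s", 1:n)
    acc <- setNames(rnorm(n, sd = 3), ids)
    covs <- data.frame(f1 = runif(n), row.names = ids)
    y <- setNames(0.2 * acc + rnorm(n, sd = 0.2), ids)
    a <- acceleration_association(acc, y, covariates = covs)
    f <- summary(lm(y ~ covs$f1 + acc))
    expect_equal(a$effect, coef(f)["acc", 1], tolerance = 1e-8)
    expect_equal(a$p, coef(f)["acc", 4], tolerance = 1e-8)
    expect_lt(a$p, 1e-6)
  })
})

test_that("null acceleration associations are calibrated", {
  ## 200 null trials: the rate of p < 0.005 stays at its nominal level
  withr::with_seed(55, {
    n <- 80
    ids <- paste0("s", 1:n)
    hits <- vapply(1:200, function(i) {
      acc <- setNames(rnorm(n), ids)
      y <- setNames(rnorm(n), ids)
      acceleration_association(acc, y)$p < 0.005
    }, TRUE)
    expect_lte(mean(hits), 0.02)
  })
})
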