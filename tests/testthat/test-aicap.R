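test_that("FOT conversion rescales each sample to parts-per-million", {
  qt <- qt_from_matrix(matrix(c(2, 3, 5, 2, 3, 5), ncol = 2,
                              dimnames = list(paste0("P", 1:3), c("c1", "t1"))),
                       kind = "iBAQ")
  qt$condition <- c("control", "treated")
  fot <- ibaq_to_fot(qt)
  expect_equal(unname(fot$values[, 1]), c(2e5, 3e5, 5e5))
  expect_identical(fot$kind, "FOT")

  m <- matrix(c(1, NA), ncol = 1, dimnames = list(c("P1", "P2"), "s1"))
  qt2 <- quant_table(m, condition = "control")
  fot2 <- ibaq_to_fot(qt2)
  expect_equal(unname(fot2$values[, 1]), c(1e6, NA))

  set.seed(1)
  m3 <- matrix(rlnorm(30), 10, 3,
               dimnames = list(paste0("P", 1:10), paste0("s", 1:3)))
  m3[c(2, 14)] <- NA
  fot3 <- ibaq_to_fot(quant_table(m3, condition = rep("control", 3)))
  expect_equal(unname(colSums(fot3$values, na.rm = TRUE)), rep(1e6, 3))

  bad <- quant_table(matrix(NA_real_, 2, 1,
                            dimnames = list(c("a", "b"), "s1")),
                     condition = "control")
  expect_error(ibaq_to_fot(bad), "no positive values")
})

test_that("imputation fills each column with its own minimum", {
  m <- matrix(c(4, NA, 2, 10, NA, NA), ncol = 2,
              dimnames = list(paste0("P", 1:3), c("a", "b")))
  qt <- quant_table(m, condition = c("control", "treated"), kind = "FOT")
  imp <- impute_missing(qt)
  expect_equal(unname(imp$values[, 1]), c(4, 2, 2))
  expect_equal(unname(imp$values[, 2]), c(10, 10, 10))

  full <- quant_table(matrix(1:4, 2, 2,
                             dimnames = list(c("x", "y"), c("a", "b"))),
                      condition = c("control", "treated"))
  expect_identical(impute_missing(full)$values, full$values)
})

test_that("quantile normalization matches a rank-mean oracle, ties averaged", {
  qt <- qt_from_matrix(matrix(c(1, 2, 3, 4, 5, 6), ncol = 2), kind = "FOT")
  qt$condition <- c("control", "treated")
  qn <- quantile_normalize(qt)
  expect_equal(unname(qn$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, 2]), c(2.5, 3.5, 4.5))

  one <- quant_table(matrix(c(5, 1, 3), 3, 1,
                            dimnames = list(paste0("P", 1:3), "s")),
                     condition = "control", kind = "FOT")
  expect_equal(quantile_normalize(one)$values, one$values,
               ignore_attr = TRUE)

  # tie case against a brute-force oracle: target = row means of sorted
  # columns; tied entries share the mean of their tied ranks' targets
  m <- matrix(c(1, 1, 2, 3, 4, 5), ncol = 2,
              dimnames = list(paste0("P", 1:3), c("a", "b")))
  target <- rowMeans(cbind(sort(m[, 1]), sort(m[, 2])))
  oracle <- m
  for (j in 1:2) {
    r <- rank(m[, j], ties.method = "average")
    oracle[, j] <- approx(seq_len(3), target, xout = r)$y
  }
  qn2 <- quantile_normalize(quant_table(m, condition = c("control", "treated"),
                                        kind = "FOT"))
  expect_equal(qn2$values, oracle, ignore_attr = TRUE)

  withNA <- quant_table(matrix(c(1, NA, 3, 4), 2, 2,
                               dimnames = list(c("x", "y"), c("a", "b"))),
                        condition = c("control", "treated"), kind = "FOT")
  expect_error(quantile_normalize(withNA), "missing")
})

test_that("after quantile normalization all sorted columns are identical", {
  set.seed(9)
  for (k in 1:5) {
    m <- matrix(rlnorm(60), 15, 4,
                dimnames = list(paste0("P", 1:15), paste0("s", 1:4)))
    qn <- quantile_normalize(quant_table(
      m, condition = rep(c("control", "treated"), 2), kind = "FOT"))
    sorted <- apply(qn$values, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  }
})

test_that("AICAP is the treated/control ratio of mean normalized abundance", {
  m <- matrix(c(100, 100, 50, 50), nrow = 1,
              dimnames = list("P1", c("c1", "c2", "t1", "t2")))
  qt <- quant_table(m, condition = c("control", "control",
                                     "treated", "treated"),
                    kind = "FOT_normalized")
  res <- compute_aicap(qt)
  expect_equal(res$aicap, 0.5)

  m2 <- matrix(c(7, 7, 7, 7), nrow = 1,
               dimnames = list("P1", c("c1", "c2", "t1", "t2")))
  qt2 <- quant_table(m2, condition = c("control", "control",
                                       "treated", "treated"),
                     kind = "FOT_normalized")
  res2 <- compute_aicap(qt2)
  expect_equal(res2$aicap, 1)
  expect_equal(res2$p_value, 1)

  m3 <- matrix(c(0, 0, 5, 6), nrow = 1,
               dimnames = list("P1", c("c1", "c2", "t1", "t2")))
  qt3 <- quant_table(m3, condition = c("control", "control",
                                       "treated", "treated"),
                     kind = "FOT_normalized")
  res3 <- compute_aicap(qt3)
  expect_identical(res3$flag, "undefined")
  expect_true(is.na(res3$aicap))

  qt4 <- quant_table(m2[, 1:2, drop = FALSE],
                     condition = c("control", "treated"),
                     kind = "FOT_normalized")
  expect_error(compute_aicap(qt4), "2 replicates")
})

test_that("the Welch test matches its closed form on random small cases", {
  set.seed(20)
  for (k in 1:20) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- rnorm(nx, sd = runif(1, 0.5, 2))
    y <- rnorm(ny, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    m <- matrix(c(x, y), nrow = 1,
                dimnames = list("P1", paste0("s", seq_len(nx + ny))))
    qt <- quant_table(pmax(m, 0) + 10,  # keep non-negative
                      condition = rep(c("control", "treated"), c(nx, ny)),
                      kind = "FOT_normalized")
    res <- compute_aicap(qt)
    xx <- qt$values[1, 1:nx]; yy <- qt$values[1, nx + 1:ny]
    se2x <- var(xx) / nx; se2y <- var(yy) / ny
    tstat <- (mean(yy) - mean(xx)) / sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
    p_oracle <- 2 * pt(-abs(tstat), df)
    expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  }
})

test_that("the pipeline is invariant to per-sample positive rescaling", {
  sim <- simulate_quant_experiment(n_proteins = 120, seed = 17)
  res1 <- aicap_pipeline(sim$table)
  scaled <- sim$table
  set.seed(18)
  scaled$values <- sweep(scaled$values, 2, runif(6, 0.2, 5), "*")
  res2 <- aicap_pipeline(scaled)
  expect_equal(res1$aicap, res2$aicap, tolerance = 1e-9)
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-9)
})

test_that("AICAP groups use left-closed bins anchored at the printed ones", {
  expect_identical(assign_aicap_group(0.072), "0-0.3")   # MED1
  expect_identical(assign_aicap_group(0.537), "0.5-0.7") # BRD4
  expect_identical(assign_aicap_group(0.401), "0.3-0.5") # RNAPII
  expect_identical(assign_aicap_group(c(0, 0.3, 0.5, 0.7, 0.9, 1.1, 3)),
                   c("0-0.3", "0.3-0.5", "0.5-0.7", "0.7-0.9", "0.9-1.1",
                     "1.1+", "1.1+"))
  expect_error(assign_aicap_group(-0.1), "non-negative")
})

test_that("planted depletion is recovered at low noise without censoring", {
  # draw the planted factors from a stream unrelated to the generator seed:
  # quantile normalization is blind to effects comonotone with abundance
  set.seed(719)
  d <- pmin(pmax(rlnorm(300, 0, 0.8), 0.05), 3)
  sim <- simulate_quant_experiment(n_proteins = 300, depletion = d,
                                   noise_cv = 0.05, missing_rate = 0,
                                   seed = 19)
  res <- aicap_pipeline(sim$table)
  expect_gt(cor(d, res$aicap, method = "spearman"), 0.9)
})
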