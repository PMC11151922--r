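test_that("temporal_sd_mean uses the sample (n-1) standard deviation", {
  r <- temporal_sd_mean(c(2, 4))
  expect_equal(r$sd, sqrt(2))          # |2 - 4| / sqrt(2)
  expect_equal(r$mean, 3)
  expect_equal(temporal_sd_mean(c(5, 5, 5)), list(sd = 0, mean = 5))

  x <- c(1.3, 4.2, 0.7, 2.2)
  r1 <- temporal_sd_mean(x)
  r2 <- temporal_sd_mean(3.7 * x)      # homogeneity of degree 1
  expect_equal(r2$sd, 3.7 * r1$sd)
  expect_equal(r2$mean, 3.7 * r1$mean)

  expect_error(temporal_sd_mean(5), "length >= 2")
  expect_error(temporal_sd_mean(c(1, NA)), "finite")
})

test_that("single-unit single-patch hierarchy collapses to one CV", {
  tn <- make_tensor(array(c(2, 4), c(1, 1, 2)))
  p <- var_partition(tn)
  expect_equal(unname(p$cv), rep(sqrt(2) / 3, 4), tolerance = 1e-12)
  expect_equal(unname(p$cv), rep(0.4714045, 4), tolerance = 1e-6)
  expect_equal(unname(p$phi), rep(1, 4))
  expect_false(any(p$degenerate))
})

test_that("perfectly anticorrelated patches give zero regional CV and zero spatial synchrony", {
  vals <- array(0, c(1, 2, 2)); vals[1, 1, ] <- c(2, 4); vals[1, 2, ] <- c(4, 2)
  p <- var_partition(make_tensor(vals))
  expect_equal(p$cv[["c_r"]], 0)
  expect_equal(p$phi[["c_l2r"]], 0)
  expect_equal(p$inv[["c_r"]], Inf)
})

test_that("the 2x2x3 worked example reproduces the oracle-derived components", {
  p <- var_partition(micro_tensor())
  # frozen from the independent brute-force oracle (all component SDs are 1)
  expect_equal(p$cv[["s_l"]], 0.375)
  expect_equal(p$cv[["c_l"]], 0.25)
  expect_equal(p$cv[["s_r"]], 0.125)
  expect_equal(p$cv[["c_r"]], 0.125)
  expect_equal(p$phi[["s2c_l"]], 2 / 3)
  expect_equal(p$phi[["c_l2r"]], 0.5)
  expect_equal(p$phi[["s_l2r"]], 1 / 3)
  expect_equal(p$phi[["s2c_r"]], 1)
  # and agrees with the oracle run afresh
  o <- oracle_partition(unclass(micro_tensor()))
  expect_equal(p$cv[["s_l"]], o$cv_s_l)
  expect_equal(p$phi[["s2c_l"]], o$phi_s2c_l)
})

test_that("partition matches the brute-force oracle and its identities on random tensors", {
  set.seed(101)
  worst_oracle <- 0; worst_identity <- 0; all_phi_ok <- TRUE
  for (i in 1:200) {
    tn <- random_tensor()
    p <- var_partition(tn)
    o <- oracle_partition(unclass(tn))
    worst_oracle <- max(
      worst_oracle,
      abs(unname(p$cv) - c(o$cv_s_l, o$cv_c_l, o$cv_s_r, o$cv_c_r)),
      abs(unname(p$phi) - c(o$phi_s2c_l, o$phi_c_l2r, o$phi_s_l2r, o$phi_s2c_r)))
    worst_identity <- max(
      worst_identity,
      abs(p$cv[["c_r"]] - p$cv[["c_l"]] * p$phi[["c_l2r"]]),
      abs(p$cv[["c_l"]] - p$cv[["s_l"]] * p$phi[["s2c_l"]]),
      abs(p$cv[["s_r"]] - p$cv[["s_l"]] * p$phi[["s_l2r"]]),
      abs(p$cv[["c_r"]] - p$cv[["s_r"]] * p$phi[["s2c_r"]]),
      # path consistency: both routes give cv_c_r / cv_s_l
      abs(p$phi[["s2c_l"]] * p$phi[["c_l2r"]] -
            p$phi[["s_l2r"]] * p$phi[["s2c_r"]]))
    all_phi_ok <- all_phi_ok && all(p$phi >= 0 & p$phi <= 1 + 1e-12)
  }
  expect_lt(worst_oracle, 1e-10)
  expect_lt(worst_identity, 1e-12)
  expect_true(all_phi_ok)
})

test_that("partition is scale- and permutation-invariant", {
  set.seed(7)
  tn <- random_tensor(3, 3, 5)
  p <- var_partition(tn)

  scaled <- make_tensor(unclass(tn) * 17.3)
  ps <- var_partition(scaled)
  expect_equal(ps$cv, p$cv)
  expect_equal(ps$phi, p$phi)

  perm_u <- sample(3); perm_k <- sample(3)
  permuted <- make_tensor(unclass(tn)[perm_u, perm_k, , drop = FALSE])
  pp <- var_partition(permuted)
  expect_equal(pp$cv, p$cv)
  expect_equal(pp$phi, p$phi)
})

test_that("degenerate inputs are flagged or rejected as specified", {
  expect_error(var_partition(make_tensor(array(0, c(2, 2, 3)))),
               "degenerate metacommunity")
  # all series constant: every CV is 0, all synchronies 0/0 -> 1, flagged
  p <- var_partition(make_tensor(array(5, c(2, 2, 3))))
  expect_equal(unname(p$cv), rep(0, 4))
  expect_equal(unname(p$phi), rep(1, 4))
  expect_true(all(p$degenerate))
  expect_equal(unname(p$inv), rep(Inf, 4))
})

test_that("fruit-set partition runs on the complete-case unit subset", {
  vals <- array(runif(12, 0.2, 0.8), c(2, 2, 3))
  vals[2, 1, 2] <- NA
  dimnames(vals) <- list(unit = c("a", "b"), patch = c("A", "B"), time = 1:3)
  tn <- pollistab:::new_metacommunity_tensor(vals, "fruit_set", allow_na = TRUE)
  expect_warning(p <- var_partition(tn), "complete-case")
  expect_equal(p$n_units_dropped, 1L)
  expect_equal(p$n_units, 1L)
  expect_equal(p$cv, var_partition(make_tensor(vals[1, , , drop = FALSE]))$cv)
})

test_that("invariability is the reciprocal CV and involutive", {
  p <- var_partition(micro_tensor())
  expect_equal(p$inv[["c_r"]], 8)          # cv_c_r = 0.125
  p2 <- invariability(p)
  expect_equal(p2$inv, p$inv)
  expect_equal(1 / (1 / p$cv[["s_l"]]), p$cv[["s_l"]])
})

test_that("variance-scale synchrony is the square of the CV-ratio scale", {
  tn <- micro_tensor()
  p1 <- var_partition(tn)
  p2 <- var_partition(tn, synchrony_scale = "variance")
  expect_equal(p2$phi, p1$phi^2)
  expect_equal(p2$cv, p1$cv)   # CVs are unaffected by the synchrony scale
})

test_that("tidy and glance return well-formed tibbles", {
  p <- var_partition(micro_tensor())
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12)
  expect_setequal(unique(td$statistic), c("cv", "invariability", "synchrony"))
  g <- glance(p)
  expect_equal(nrow(g), 1)
  expect_equal(g$cv_s_l, 0.375)
  expect_equal(g$inv_c_r, 8)
})
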