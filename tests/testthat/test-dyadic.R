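test_that("dyad table has one canonical row per dyad", {
  ds <- sim_datasets(seed = 61, K = 1)
  expect_equal(nrow(ds$dyads), 6)              # 4 persons -> 6 dyads
  expect_true(all(ds$dyads$i < ds$dyads$j))
  ds25 <- sim_datasets(seed = 62)
  expect_equal(nrow(ds25$dyads), 25 * 6)       # 150 dyads
})

test_that("dyad table aligns metaperceptions with the correct direction", {
  sim <- simulate_srm_arrma(sim_config(seed = 63, K = 1))
  ds <- pipeline_datasets(sim)
  tr <- sim$truth[[1]]
  for (r in seq_len(nrow(ds$dyads))) {
    i <- ds$dyads$i[r]; j <- ds$dyads$j[r]
    expect_equal(ds$dyads$gamma_ij[r], tr$gamma[i, j])
    expect_equal(ds$dyads$gamma_ji[r], tr$gamma[j, i])
    expect_equal(ds$dyads$gamma_mp_ij[r], tr$gamma_mp[i, j])
  }
})

test_that("half-block style unidirectional metaperceptions give NA mp_ji", {
  sim <- simulate_srm_arrma(sim_config(seed = 64, K = 1))
  resp_eff <- composite_effects(lapply(sim$response_tables[[1]],
                                       decompose_round_robin))
  mp_eff <- composite_effects(lapply(sim$mp_tables[[1]],
                                     decompose_round_robin))
  # keep only upper-triangle metaperceptions (one direction per dyad)
  mp_eff$relationship[lower.tri(mp_eff$relationship)] <- NA
  dy <- build_dyad_table(resp_eff, mp_eff)
  expect_equal(nrow(dy), 6)
  expect_true(all(is.na(dy$gamma_mp_ji)))
  expect_true(all(!is.na(dy$gamma_mp_ij)))
  expect_error(to_pairwise(dy), "unidirectional")
  # minimal fit still works on the dyad table
  expect_s3_class(fit_minimal_dyadic(dy), "arrma_dyadic_fit")
})

test_that("pairwise restructuring is exchange-symmetric by construction", {
  ds <- sim_datasets(seed = 65)
  pw <- to_pairwise(ds$dyads)
  expect_equal(nrow(pw), 2 * nrow(ds$dyads))
  expect_equal(mean(pw$self_gamma), mean(pw$partner_gamma))
  expect_equal(var(pw$self_gamma), var(pw$partner_gamma))
  expect_equal(mean(pw$self_mp_gamma), mean(pw$partner_mp_gamma))
  # covariance matrix is invariant under the role swap
  X <- as.matrix(pw[, c("self_gamma", "partner_gamma", "self_mp_gamma",
                        "partner_mp_gamma")])
  S <- cov(X)
  swap <- c(2, 1, 4, 3)
  expect_equal(S, S[swap, swap], ignore_attr = TRUE, tolerance = 1e-12)
  # one dyad gives two rows with swapped roles
  one <- to_pairwise(ds$dyads[1, ])
  expect_equal(one$self_gamma[1], one$partner_gamma[2])
  expect_equal(one$self_mp_gamma[1], one$partner_mp_gamma[2])
})

test_that("minimal dyadic fit: deterministic case and closed-form equality", {
  ds <- sim_datasets(seed = 66)
  dy <- ds$dyads
  dy$gamma_mp_ij <- dy$gamma_ij
  fit0 <- fit_minimal_dyadic(dy)
  expect_equal(fit0$b, 1, tolerance = 1e-12)
  expect_equal(fit0$c, 0, tolerance = 1e-12)

  for (data in list(ds$dyads, to_pairwise(ds$dyads))) {
    fit <- fit_minimal_dyadic(data)
    d3 <- arrma:::dyadic_three_cols(data)
    R <- cor(cbind(d3$x, d3$y))
    cf <- arrma_closed_form(R[1, 3], R[1, 2], R[2, 3])
    expect_equal(fit$standardized_b, cf$b_std, tolerance = 1e-9)
    expect_equal(fit$standardized_c, cf$c_std, tolerance = 1e-9)
    o <- lm(d3$y ~ d3$x)
    expect_equal(unname(coef(o)[2:3]), c(fit$b, fit$c), tolerance = 1e-10)
  }
})

test_that("dyad-cluster robust standard errors are available for pairwise input", {
  ds <- sim_datasets(seed = 67)
  pw <- to_pairwise(ds$dyads)
  plain <- fit_minimal_dyadic(pw)
  robust <- fit_minimal_dyadic(pw, robust = "dyad")
  expect_false(isTRUE(all.equal(plain$se[["b"]], robust$se[["b"]])))
  expect_equal(plain$b, robust$b)            # point estimates unchanged
})

test_that("full distinguishable fit reproduces the sample matrix exactly", {
  ds <- sim_datasets(seed = 68)
  fit <- fit_full_dyadic_distinguishable(ds$dyads)
  expect_equal(fit$chi_square, 0)
  expect_equal(fit$df, 0L)
  # rebuild the implied covariance matrix from the estimates
  S <- fit$S
  bv1 <- c(fit$B, fit$C); bv2 <- c(fit$C_prime, fit$B_prime)
  Sxx <- S[c("g1", "g2"), c("g1", "g2")]
  impl <- matrix(NA, 4, 4, dimnames = dimnames(S))
  impl[1:2, 1:2] <- Sxx
  impl[1:2, 3] <- Sxx %*% bv1; impl[3, 1:2] <- impl[1:2, 3]
  impl[1:2, 4] <- Sxx %*% bv2; impl[4, 1:2] <- impl[1:2, 4]
  impl[3, 3] <- drop(t(bv1) %*% Sxx %*% bv1) + fit$disturbance_var[1]
  impl[4, 4] <- drop(t(bv2) %*% Sxx %*% bv2) + fit$disturbance_var[2]
  impl[3, 4] <- impl[4, 3] <- drop(t(bv1) %*% Sxx %*% bv2) + fit$D
  expect_equal(impl, S, tolerance = 1e-10)
  expect_error(fit_full_dyadic_distinguishable(to_pairwise(ds$dyads)),
               "dyad-format")
})

test_that("full distinguishable fit recovers D = 0 truth within sampling error", {
  fits <- lapply(1:12, function(s) {
    ds <- sim_datasets(seed = 900 + s, K = 40, cov_d = 0)
    fit_full_dyadic_distinguishable(ds$dyads)$D
  })
  d <- unlist(fits)
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("I-SAT is exactly zero on pairwise input with 6 df", {
  ds <- sim_datasets(seed = 70)
  pw <- to_pairwise(ds$dyads)
  fit <- fit_isat(pw)
  expect_equal(fit$df, 6L)
  expect_lt(fit$chi_square, 1e-8)
  # dyad-format chi-square is nonnegative and designation-dependent
  fd <- fit_isat(ds$dyads)
  expect_gte(fd$chi_square, 0)
  expect_equal(fd$df, 6L)
})

test_that("I-SAT on pairwise data is invariant to member relabeling", {
  ds <- sim_datasets(seed = 5)
  dy <- ds$dyads
  set.seed(5)
  flip <- sample(c(TRUE, FALSE), nrow(dy), replace = TRUE)
  dy2 <- dy
  dy2[flip, c("i", "j")] <- dy[flip, c("j", "i")]
  dy2[flip, c("gamma_ij", "gamma_ji")] <- dy[flip, c("gamma_ji", "gamma_ij")]
  dy2[flip, c("gamma_mp_ij", "gamma_mp_ji")] <-
    dy[flip, c("gamma_mp_ji", "gamma_mp_ij")]
  f1 <- fit_isat(to_pairwise(dy))
  f2 <- fit_isat(to_pairwise(dy2))
  expect_equal(f1$chi_square, f2$chi_square, tolerance = 1e-8)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
})

test_that("constrained estimates are invariant to member designation", {
  ds <- sim_datasets(seed = 71)
  dy <- ds$dyads
  set.seed(7)
  flip <- sample(c(TRUE, FALSE), nrow(dy), replace = TRUE)
  dy2 <- dy
  dy2[flip, c("gamma_ij", "gamma_ji")] <- dy[flip, c("gamma_ji", "gamma_ij")]
  dy2[flip, c("gamma_mp_ij", "gamma_mp_ji")] <-
    dy[flip, c("gamma_mp_ji", "gamma_mp_ij")]
  f1 <- fit_full_dyadic_indistinguishable(to_pairwise(dy))
  f2 <- fit_full_dyadic_indistinguishable(to_pairwise(dy2))
  for (par in c("B", "C", "A", "D")) {
    expect_equal(f1[[par]], f2[[par]], tolerance = 1e-6)
  }
  expect_equal(f1$B, f1$B_prime)             # equality constraint holds
  expect_equal(f1$C, f1$C_prime)
})

test_that("indistinguishable fit on dyad input reports the I-SAT adjustment", {
  ds <- sim_datasets(seed = 72)
  fit <- fit_full_dyadic_indistinguishable(ds$dyads)
  expect_equal(fit$df, 6L)
  expect_equal(fit$adjusted_df, 0L)
  expect_equal(fit$adjusted_chi_square,
               fit$chi_square - fit$isat$chi_square, tolerance = 1e-9)
  expect_gte(fit$adjusted_chi_square, -1e-6)
})
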