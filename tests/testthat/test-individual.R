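test_that("individual dataset projects the three needed components", {
  ds <- sim_datasets(seed = 31, K = 1)
  expect_s3_class(ds$individual, "individual_records")
  expect_equal(nrow(ds$individual), 4)
  expect_named(ds$individual, c("group_id", "person_id", "alpha_r",
                                "beta_r", "alpha_mp"))
  sim <- simulate_srm_arrma(sim_config(seed = 31, K = 1))
  expect_equal(ds$individual$alpha_r, unname(sim$truth[[1]]$alpha))
  expect_equal(ds$individual$alpha_mp, unname(sim$truth[[1]]$alpha_mp))
})

test_that("mismatched person sets between constructs are an error", {
  re <- decompose_round_robin(random_rr(4, seed = 1))
  rr2 <- random_rr(4, seed = 2)
  rr2$members <- paste0("X", 1:4)
  dimnames(rr2$values) <- list(rr2$members, rr2$members)
  me <- decompose_round_robin(rr2)
  expect_error(suppressMessages(build_individual_dataset(re, me)),
               "person sets differ")
})

test_that("pooled dataset inherits per-group zero sums", {
  ds <- sim_datasets(seed = 8)
  expect_equal(nrow(ds$individual), 100)
  sums <- aggregate(cbind(alpha_r, beta_r, alpha_mp) ~ group_id,
                    ds$individual, sum)
  expect_lt(max(abs(as.matrix(sums[, -1]))), 1e-9)
})

test_that("closed-form standardized paths match hand arithmetic", {
  # zero reciprocity: paths reduce to the raw correlations
  cf <- arrma_closed_form(0.5, 0.0, 0.3)
  expect_equal(cf$b_std, 0.5)
  expect_equal(cf$c_std, 0.3)
  # hand-computed case
  cf2 <- arrma_closed_form(0.6, 0.5, 0.4)
  expect_equal(cf2$b_std, 0.4 / 0.75)
  expect_equal(cf2$c_std, 0.1 / 0.75)
  # numerator annihilation
  cf3 <- arrma_closed_form(0.35 * 0.52, 0.35, 0.52)
  expect_equal(cf3$b_std, 0)
  # perfect reciprocity is singular
  expect_error(arrma_closed_form(0.5, 1, 0.5), "unidentified")
  expect_error(arrma_closed_form(1.2, 0.5, 0.5), "\\[-1, 1\\]")
})

test_that("deterministic projection gives b = 1, c = 0, R^2 = 1", {
  set.seed(2)
  a <- rnorm(40); b <- rnorm(40)
  rec <- data.frame(alpha_r = a, beta_r = b, alpha_mp = a)
  fit <- fit_individual_arrma(rec)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$c, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("full fit equals the OLS oracle and the closed-form standardization", {
  ds <- sim_datasets(seed = 40)
  fit <- fit_individual_arrma(ds$individual)
  # unstandardized coefficients: lm oracle
  o <- lm(alpha_mp ~ alpha_r + beta_r, data = ds$individual)
  expect_equal(fit$b, unname(coef(o)["alpha_r"]), tolerance = 1e-10)
  expect_equal(fit$c, unname(coef(o)["beta_r"]), tolerance = 1e-10)
  # standardized coefficients: closed form at the sample correlations
  R <- cor(ds$individual[, c("alpha_r", "beta_r", "alpha_mp")])
  cf <- arrma_closed_form(R[1, 3], R[1, 2], R[2, 3])
  expect_equal(fit$standardized_b, cf$b_std, tolerance = 1e-9)
  expect_equal(fit$standardized_c, cf$c_std, tolerance = 1e-9)
  # reciprocity is the sample covariance
  expect_equal(fit$a_cov, cov(ds$individual$alpha_r, ds$individual$beta_r))
})

test_that("restricted fit: A invariant, chi-square equals the regression LRT", {
  ds <- sim_datasets(seed = 41)
  full <- fit_individual_arrma(ds$individual)
  restr <- fit_individual_arrma(ds$individual, restrict_accuracy = TRUE)
  expect_equal(restr$a_cov, full$a_cov, tolerance = 1e-7)
  expect_equal(restr$df, 1)
  expect_gte(restr$chi_square, 0)
  # independent oracle: (N-1) log(RSS0/RSS1) from nested OLS fits
  r1 <- resid(lm(alpha_mp ~ alpha_r + beta_r, ds$individual))
  r0 <- resid(lm(alpha_mp ~ alpha_r, ds$individual))
  n <- nrow(ds$individual)
  expect_equal(restr$chi_square, (n - 1) * log(sum(r0^2) / sum(r1^2)),
               tolerance = 1e-7)
  expect_equal(restr$c, 0)
})

test_that("degenerate inputs are rejected", {
  rec <- data.frame(alpha_r = rep(0, 10), beta_r = rnorm(10),
                    alpha_mp = rnorm(10))
  expect_error(fit_individual_arrma(rec), "zero variance")
  expect_error(fit_individual_arrma(data.frame(alpha_r = 1:2, beta_r = 1:2,
                                               alpha_mp = 1:2)),
               "at least 4")
})

test_that("latent model builder lays out markers, loadings, error covariances", {
  ds1 <- sim_datasets(seed = 51, m = 1)
  expect_error(build_individual_latent_model(list(ds1$individual)),
               "composite")
  sim <- simulate_srm_arrma(sim_config(seed = 52, m = 2, var_noise = 0.3))
  recs <- lapply(1:2, function(k) {
    re <- lapply(sim$response_tables, function(g) decompose_round_robin(g[[k]]))
    me <- lapply(sim$mp_tables, function(g) decompose_round_robin(g[[k]]))
    suppressMessages(build_individual_dataset(re, me))
  })
  lm2 <- build_individual_latent_model(recs)
  expect_equal(length(lm2$spec$observed), 6)
  expect_equal(lm2$spec$latent, c("ACTOR", "PARTNER", "ACTOR_MP"))
  p <- lm2$spec$paths
  markers <- p[is.na(p$label) & p$from %in% lm2$spec$latent, ]
  expect_equal(nrow(markers), 3)            # one fixed marker per construct
  expect_true(all(markers$value == 1))
  free_load <- p[!is.na(p$label) & grepl("^l", p$label), ]
  expect_equal(nrow(free_load), 3)          # (m - 1) per construct
  v <- lm2$spec$covariances
  errcov <- v[grepl("^r_", v$label), ]
  expect_equal(nrow(errcov), 2)             # paired a_k with mp_k
  expect_true(all(c("B", "C", "A") %in% v$label | c("B", "C", "A") %in%
                    p$label))
})

test_that("latent fit recovers loadings and structure from generated data", {
  sim <- simulate_srm_arrma(sim_config(seed = 11, m = 3, var_noise = 0.4,
                                       var_shared_noise = 0.1))
  recs <- lapply(1:3, function(k) {
    re <- lapply(sim$response_tables, function(g) decompose_round_robin(g[[k]]))
    me <- lapply(sim$mp_tables, function(g) decompose_round_robin(g[[k]]))
    suppressMessages(build_individual_dataset(re, me))
  })
  model <- build_individual_latent_model(recs)
  fit <- fit_individual_latent(model)
  expect_true(fit$converged)
  # all true loadings are 1; estimates should be near 1 with sane SEs
  loads <- fit$estimates[grepl("^l", names(fit$estimates))]
  expect_true(all(abs(loads - 1) < 0.35))
  # structural paths in the neighborhood of the generating values
  expect_equal(unname(fit$estimates["B"]), 0.8, tolerance = 0.35)
  expect_gt(fit$estimates["A"], 0)
  # shared indicator noise shows up as positive error covariances
  expect_gt(mean(fit$estimates[grepl("^r_", names(fit$estimates))]), 0)
})
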