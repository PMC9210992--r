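make_reg_spec <- function() {
  model_spec(
    observed = c("x1", "x2", "y"),
    paths = data.frame(from = c("x1", "x2"), to = "y",
                       label = c("b1", "b2"), value = NA),
    covariances = data.frame(v1 = c("x1", "x2", "x1", "y"),
                             v2 = c("x1", "x2", "x2", "y"),
                             label = c("v1", "v2", "c12", "ve"),
                             value = NA))
}

test_that("saturated model gives F = 0 and reproduces S", {
  set.seed(10)
  X <- matrix(rnorm(200 * 3), 200, 3,
              dimnames = list(NULL, c("x1", "x2", "y")))
  mom <- sample_moments(X)
  fit <- ml_fit(make_reg_spec(), mom)
  expect_lt(fit$F_ml, 1e-10)
  expect_lt(fit$chi_square, 1e-8)
  expect_equal(fit$df, 0L)
  expect_equal(fit$Sigma_hat, mom$S, tolerance = 1e-6)
  expect_lt(fit$gradient_norm, 1e-5)
})

test_that("regression spec reproduces the normal-equations solution", {
  set.seed(11)
  x1 <- rnorm(150); x2 <- 0.5 * x1 + rnorm(150)
  y <- 0.7 * x1 - 0.3 * x2 + rnorm(150)
  X <- cbind(x1 = x1, x2 = x2, y = y)
  fit <- ml_fit(make_reg_spec(), sample_moments(X))
  o <- lm(y ~ x1 + x2)
  expect_equal(unname(fit$estimates[c("b1", "b2")]),
               unname(coef(o)[2:3]), tolerance = 1e-6)
  expect_equal(unname(fit$estimates["c12"]), cov(x1, x2), tolerance = 1e-5)
})

test_that("equality constraints via shared labels reduce free parameters", {
  spec_eq <- model_spec(
    observed = c("x1", "x2", "y"),
    paths = data.frame(from = c("x1", "x2"), to = "y",
                       label = c("b", "b"), value = NA),
    covariances = data.frame(v1 = c("x1", "x2", "x1", "y"),
                             v2 = c("x1", "x2", "x2", "y"),
                             label = c("v1", "v2", "c12", "ve"),
                             value = NA))
  set.seed(12)
  x1 <- rnorm(200); x2 <- rnorm(200)
  y <- 0.5 * x1 + 0.8 * x2 + rnorm(200)
  fit <- ml_fit(spec_eq, sample_moments(cbind(x1 = x1, x2 = x2, y = y)))
  expect_equal(fit$df, 1L)
  expect_gt(fit$chi_square, 0)
  # profile oracle: constrained b is the OLS of y on (x1 + x2)
  o <- lm(y ~ I(x1 + x2))
  expect_equal(unname(fit$estimates["b"]), unname(coef(o)[2]),
               tolerance = 1e-4)
})

test_that("standardization matches refits and the published correlation case", {
  # unit variances: standardized equals unstandardized
  spec <- make_reg_spec()
  S <- matrix(c(1, 0.3, 0.5, 0.3, 1, 0.4, 0.5, 0.4, 1), 3,
              dimnames = list(c("x1", "x2", "y"), c("x1", "x2", "y")))
  fit <- ml_fit(spec, sample_moments(S = S, n = 100))
  std <- fit$standardized
  expect_equal(std$standardized[std$label == "b1"],
               std$unstandardized[std$label == "b1"], tolerance = 1e-6)
  # a covariance of 0.721 with variances chosen so the correlation is 0.713
  v <- 0.721 / 0.713
  S2 <- matrix(c(v, 0.721, 0.721, v), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  spec2 <- model_spec(observed = c("a", "b"),
                      covariances = data.frame(v1 = c("a", "b", "a"),
                                               v2 = c("a", "b", "b"),
                                               label = c("va", "vb", "cab"),
                                               value = NA))
  fit2 <- ml_fit(spec2, sample_moments(S = S2, n = 100))
  s2 <- fit2$standardized
  expect_equal(s2$standardized[s2$label == "cab"], 0.713, tolerance = 1e-6)
  # random spec: standardized estimates equal a refit on the correlation matrix
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3) %*% matrix(c(2, 0.5, 0, 0, 1.5, 0.3,
                                               0, 0, 0.8), 3)
  colnames(X) <- c("x1", "x2", "y")
  f_cov <- ml_fit(make_reg_spec(), sample_moments(X))
  f_cor <- ml_fit(make_reg_spec(),
                  sample_moments(S = cov2cor(cov(X)), n = 100))
  sc <- f_cov$standardized
  expect_equal(sc$standardized[sc$label == "b1"],
               unname(f_cor$estimates["b1"]), tolerance = 1e-4)
  expect_equal(sc$standardized[sc$label == "b2"],
               unname(f_cor$estimates["b2"]), tolerance = 1e-4)
})

test_that("fit is invariant to observed-variable reordering", {
  set.seed(14)
  X <- cbind(x1 = rnorm(120), x2 = rnorm(120), y = rnorm(120))
  X[, "y"] <- 0.4 * X[, "x1"] + rnorm(120)
  spec1 <- make_reg_spec()
  spec2 <- model_spec(observed = c("y", "x2", "x1"),
                      paths = spec1$paths, covariances = spec1$covariances)
  f1 <- ml_fit(spec1, sample_moments(X))
  f2 <- ml_fit(spec2, sample_moments(X[, c(3, 2, 1)]))
  expect_equal(f1$estimates, f2$estimates[names(f1$estimates)],
               tolerance = 1e-6)
})

test_that("likelihood-ratio comparison validates nesting and degenerate cases", {
  set.seed(15)
  X <- cbind(x1 = rnorm(100), x2 = rnorm(100), y = rnorm(100))
  mom <- sample_moments(X)
  general <- ml_fit(make_reg_spec(), mom)
  spec_r <- make_reg_spec()
  spec_r$paths$label[2] <- NA; spec_r$paths$value[2] <- 0
  restricted <- ml_fit(spec_r, mom)
  lr <- likelihood_ratio(restricted, general)
  expect_equal(lr$delta_df, 1L)
  # general is saturated, so the difference equals the restricted chi-square
  expect_equal(lr$delta_chi, restricted$chi_square, tolerance = 1e-8)
  same <- likelihood_ratio(general, general)
  expect_true(same$identical)
  expect_equal(same$delta_chi, 0)
  expect_error(likelihood_ratio(general, restricted), "fewer df")
})

test_that("restricted-model chi-square is chi-square(1) distributed under the null", {
  # iid trivariate normal data with b2 = 0 truth
  set.seed(16)
  reps <- 300
  stats <- numeric(reps)
  spec_r <- make_reg_spec()
  spec_r$paths$label[2] <- NA; spec_r$paths$value[2] <- 0
  for (r in seq_len(reps)) {
    x1 <- rnorm(80); x2 <- 0.4 * x1 + rnorm(80)
    y <- 0.6 * x1 + rnorm(80)
    stats[r] <- ml_fit(spec_r, sample_moments(cbind(x1 = x1, x2 = x2,
                                                    y = y)),
                       se = FALSE)$chi_square
  }
  # empirical exceedance of the 95th theoretical percentile
  exceed <- mean(stats > qchisq(0.95, 1))
  ci <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(exceed - 0.05), ci + 0.02)
  expect_gt(mean(stats), 0.75)   # mean of chi-square(1) is 1
  expect_lt(mean(stats), 1.35)
})

test_that("mean structures enter the discrepancy and the df count", {
  set.seed(17)
  X <- cbind(a = rnorm(150, mean = 2), b = rnorm(150, mean = -1))
  spec <- model_spec(observed = c("a", "b"),
                     covariances = data.frame(v1 = c("a", "b", "a"),
                                              v2 = c("a", "b", "b"),
                                              label = c("va", "vb", "cab"),
                                              value = NA),
                     means = data.frame(var = c("a", "b"),
                                        label = c("ma", "ma"), value = NA))
  fit <- ml_fit(spec, sample_moments(X))
  expect_equal(fit$df, 1L)          # 5 moments, 4 free labels
  expect_gt(fit$chi_square, 1)      # means truly differ
  spec_free <- spec
  spec_free$means$label <- c("ma", "mb")
  fit2 <- ml_fit(spec_free, sample_moments(X))
  expect_lt(fit2$chi_square, 1e-8)
  expect_equal(unname(fit2$estimates[c("ma", "mb")]),
               unname(colMeans(X)), tolerance = 1e-6)
})

test_that("structural errors are caught: loops, unknown vars, over-parameterization", {
  expect_error(model_spec("x", paths = data.frame(from = "x", to = "z",
                                                  label = "p", value = NA)),
               "unknown variable")
  expect_error(model_spec(c("x", "y"),
                          paths = data.frame(from = c("x", "y"),
                                             to = c("y", "x"),
                                             label = c("a", "b"),
                                             value = NA)),
               "feedback loop")
  over <- model_spec(c("x", "y"),
                     covariances = data.frame(
                       v1 = c("x", "y", "x", "x", "y"),
                       v2 = c("x", "y", "y", "x", "y"),
                       label = c("a", "b", "c", "d", "e"), value = NA))
  set.seed(18)
  expect_error(ml_fit(over, sample_moments(cbind(x = rnorm(50),
                                                 y = rnorm(50)))),
               "more free parameters")
})

test_that("non-identified models are reported via the information matrix", {
  # free loadings together with a free latent variance: only the products
  # loading * sqrt(variance) are determined, so the information matrix is
  # rank deficient
  spec <- model_spec(
    observed = c("x1", "x2", "x3"), latent = "F",
    paths = data.frame(from = "F", to = c("x1", "x2", "x3"),
                       label = c("l1", "l2", "l3"), value = 1),
    covariances = data.frame(v1 = c("F", "x1", "x2", "x3"),
                             v2 = c("F", "x1", "x2", "x3"),
                             label = c("vf", NA, NA, NA),
                             value = c(1, 0.25, 0.25, 0.25)))
  set.seed(19)
  f <- rnorm(300)
  X <- cbind(x1 = f + rnorm(300, sd = 0.5), x2 = f + rnorm(300, sd = 0.5),
             x3 = f + rnorm(300, sd = 0.5))
  expect_error(ml_fit(spec, sample_moments(X)), "not identified")
})

test_that("near-singular sample matrices trigger the ridge warning", {
  set.seed(20)
  x <- rnorm(60)
  X <- cbind(x1 = x, x2 = x + rnorm(60, sd = 1e-9))
  spec <- model_spec(c("x1", "x2"),
                     covariances = data.frame(v1 = c("x1", "x2", "x1"),
                                              v2 = c("x1", "x2", "x2"),
                                              label = c("a", "b", "c"),
                                              value = NA))
  expect_warning(ml_fit(spec, sample_moments(X), se = FALSE), "ridge")
})

test_that("negative variance estimates warn but are reported", {
  # Heywood case: an indicator variance below its communality drives the
  # error variance negative; it is reported, not bounded at zero
  S <- matrix(c(0.75, 0.9, 0.9, 0.9, 1.3, 0.95, 0.9, 0.95, 1.3), 3,
              dimnames = list(c("x1", "x2", "x3"), c("x1", "x2", "x3")))
  spec <- model_spec(
    observed = c("x1", "x2", "x3"), latent = "F",
    paths = data.frame(from = "F", to = c("x1", "x2", "x3"),
                       label = NA, value = 1),
    covariances = data.frame(v1 = c("F", "x1", "x2", "x3"),
                             v2 = c("F", "x1", "x2", "x3"),
                             label = c("vf", "e1", "e2", "e3"),
                             value = NA))
  expect_warning(fit <- ml_fit(spec, sample_moments(S = S, n = 80),
                               se = FALSE),
                 "negative variance")
  expect_lt(fit$estimates[["e1"]], 0)
})

test_that("model specs round-trip through YAML", {
  spec <- make_reg_spec()
  txt <- spec_to_yaml(spec)
  spec2 <- spec_from_yaml(txt)
  expect_equal(spec2$observed, spec$observed)
  expect_equal(spec2$paths$label, spec$paths$label)
  expect_equal(spec2$covariances$v1, spec$covariances$v1)
  f <- tempfile(fileext = ".yaml")
  spec_to_yaml(spec, f)
  spec3 <- spec_from_yaml(f)
  expect_equal(spec3$paths$from, spec$paths$from)
})
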