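#' Simulation configuration for the SRM + ARRMA generative model
#'
#' Defaults describe the reference study conditions used throughout the
#' package's validation: 25 round-robin groups of 4 persons, strong assumed
#' reciprocity, moderate reciprocity at both levels, weak accuracy, and
#' negatively correlated metaperception disturbances.  Effects are generated
#' directly on the estimate scale (see the methods vignette): actor/partner
#' pairs are group-centered and relationship-effect pairs are projected onto
#' the zero row/column-sum space, with their covariances pre-inflated so the
#' realized effects carry exactly the configured moments.
#'
#' @param K number of groups.
#' @param n group size (>= 4).
#' @param mu grand mean of every measurement (rating-scale midpoint).
#' @param var_actor,var_partner variances of the response actor and partner
#'   effects.
#' @param cov_actor_partner generalized reciprocity covariance of actor and
#'   partner effects.
#' @param var_rel relationship-effect variance.
#' @param cov_rel_dyadic dyadic reciprocity covariance of yoked
#'   relationship-effect pairs.
#' @param b_ind,c_ind individual-level assumed-reciprocity and accuracy
#'   paths.
#' @param var_e_ind individual-level disturbance variance.
#' @param b_dyad,c_dyad dyadic-level paths.
#' @param var_e_dyad dyadic disturbance variance.
#' @param cov_d covariance of the two members' metaperception disturbances
#'   (truth for parameter D).
#' @param var_partner_mp variance of metaperception partner effects (not
#'   used by any ARRMA fit; defaults to `var_partner`).
#' @param m indicators per construct.
#' @param var_noise per-indicator, per-cell error variance.
#' @param var_shared_noise variance of a per-indicator noise component shared
#'   between the response and metaperception cells of the same indicator
#'   (induces correlated indicator errors, as observed when one person
#'   produces both measurements); off by default.
#' @param seed integer seed; one seed fully determines the output, and group
#'   k's draws do not change when more groups are added.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(K = 25, n = 4, mu = 4,
                       var_actor = 1, var_partner = 1,
                       cov_actor_partner = 0.4,
                       var_rel = 1, cov_rel_dyadic = 0.4,
                       b_ind = 0.8, c_ind = 0.1, var_e_ind = 0.3,
                       b_dyad = 0.6, c_dyad = 0.15, var_e_dyad = 0.5,
                       cov_d = -0.2, var_partner_mp = var_partner,
                       m = 1, var_noise = 0, var_shared_noise = 0,
                       seed = 1) {
  cfg <- list(K = as.integer(K), n = as.integer(n), mu = mu,
              var_actor = var_actor, var_partner = var_partner,
              cov_actor_partner = cov_actor_partner,
              var_rel = var_rel, cov_rel_dyadic = cov_rel_dyadic,
              b_ind = b_ind, c_ind = c_ind, var_e_ind = var_e_ind,
              b_dyad = b_dyad, c_dyad = c_dyad, var_e_dyad = var_e_dyad,
              cov_d = cov_d, var_partner_mp = var_partner_mp,
              m = as.integer(m), var_noise = var_noise,
              var_shared_noise = var_shared_noise,
              seed = as.integer(seed))
  vars <- cfg[c("var_actor", "var_partner", "var_rel", "var_e_ind",
                "var_e_dyad", "var_noise", "var_partner_mp",
                "var_shared_noise")]
  if (any(unlist(vars) < 0)) stop("variances must be nonnegative")
  if (abs(cfg$cov_actor_partner) >
      sqrt(cfg$var_actor * cfg$var_partner) + 1e-12) {
    stop("infeasible actor/partner covariance block")
  }
  if (abs(cfg$cov_rel_dyadic) > cfg$var_rel + 1e-12) {
    stop("infeasible relationship covariance block")
  }
  if (abs(cfg$cov_d) > cfg$var_e_dyad + 1e-12) {
    stop("infeasible disturbance covariance block")
  }
  if (cfg$K < 1 || cfg$n < 4) stop("need K >= 1 and n >= 4")
  if (cfg$m < 1) stop("need m >= 1 indicators")
  class(cfg) <- "sim_config"
  cfg
}

## Least-squares relationship residual of a square matrix with NA diagonal
## (the projection underlying decompose_round_robin).
rr_residual <- function(v) {
  n <- nrow(v)
  rm <- rowMeans(v, na.rm = TRUE); cm <- colMeans(v, na.rm = TRUE)
  gm <- mean(v, na.rm = TRUE)
  w1 <- (n - 1)^2 / (n^2 - 2 * n); w2 <- (n - 1) / (n^2 - 2 * n)
  w3 <- (n - 1) / (n - 2)
  alpha <- w1 * rm + w2 * cm - w3 * gm
  beta <- w1 * cm + w2 * rm - w3 * gm
  g <- v - outer(alpha, rep(1, n)) - outer(rep(1, n), beta) - gm
  diag(g) <- NA_real_
  g
}

## The projection onto the relationship space maps the raw per-dyad moment
## pair (variance, yoked covariance) linearly to the post-projection pair.
## Returns that 2x2 map for group size n (cached).
proj_env <- new.env(parent = emptyenv())

rr_projection_moment_map <- function(n) {
  key <- as.character(n)
  if (!is.null(proj_env[[key]])) return(proj_env[[key]])
  cells <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)
  ncell <- nrow(cells)
  P <- matrix(0, ncell, ncell)
  for (k in seq_len(ncell)) {
    E <- matrix(0, n, n); diag(E) <- NA_real_
    E[cells[k, 1], cells[k, 2]] <- 1
    gk <- rr_residual(E)
    P[, k] <- gk[cells]
  }
  Tm <- matrix(0, ncell, ncell)   # transpose pairing
  for (k in seq_len(ncell)) {
    kk <- which(cells[, 1] == cells[k, 2] & cells[, 2] == cells[k, 1])
    Tm[kk, k] <- 1
  }
  PTP <- P %*% Tm %*% P
  i12 <- which(cells[, 1] == 1 & cells[, 2] == 2)
  i21 <- which(cells[, 1] == 2 & cells[, 2] == 1)
  M <- rbind(c(P[i12, i12], PTP[i12, i12]),
             c(P[i12, i21], PTP[i12, i21]))
  proj_env[[key]] <- M
  M
}

## Draw yoked pairs on the off-diagonal of an n x n matrix so that after
## projection every cell has variance `v` and yoked covariance `c`.
draw_projected_gammas <- function(n, v, c) {
  if (v == 0) {
    g <- matrix(0, n, n); diag(g) <- NA_real_
    return(g)
  }
  M <- rr_projection_moment_map(n)
  raw <- solve(M, c(v, c))
  if (raw[1] < 0 || abs(raw[2]) > raw[1] + 1e-12) {
    stop("relationship covariance block infeasible after projection ",
         "inflation at n = ", n, " (variance ", signif(raw[1], 4),
         ", covariance ", signif(raw[2], 4), ")")
  }
  ch <- chol(matrix(c(raw[1], raw[2], raw[2], raw[1]), 2))
  g <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pair <- drop(stats::rnorm(2) %*% ch)
    g[i, j] <- pair[1]; g[j, i] <- pair[2]
  }
  rr_residual(g)
}

## centered draws with exact post-centering covariance; eigen square root
## with clipped eigenvalues so zero-variance components are exactly zero
draw_centered_pairs <- function(n, v1, v2, cv) {
  infl <- n / (n - 1)
  Sg <- matrix(c(v1, cv, cv, v2), 2) * infl
  z <- matrix(stats::rnorm(2 * n), n, 2)
  if (all(Sg == 0)) return(z * 0)
  E <- eigen(Sg, symmetric = TRUE)
  rt <- E$vectors %*% diag(sqrt(pmax(E$values, 0)), 2) %*% t(E$vectors)
  scale(z %*% rt, scale = FALSE)
}

#' Simulate round-robin data from the SRM + ARRMA generative model
#'
#' For each group: actor/partner effect pairs are bivariate normal with the
#' configured generalized-reciprocity covariance; yoked relationship-effect
#' pairs are bivariate normal with the dyadic-reciprocity covariance;
#' metaperception actor effects are a linear function of the response actor
#' and partner effects plus disturbance; metaperception relationship effects
#' are a linear function of the yoked response relationship effects plus
#' correlated disturbances.  Each of `m` indicators per construct adds fresh
#' cell-level noise.  Group k's stream is split from the global seed, so
#' enlarging `K` never alters earlier groups.
#'
#' @param config a [sim_config()].
#' @return object of class `arrma_sim`: `response_tables` and `mp_tables`
#'   (lists over groups of lists over indicators of [round_robin_table()]s)
#'   and `truth` (per-group latent effects plus the configured paths).
#' @export
simulate_srm_arrma <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  group_seeds <- sample.int(2147483646L, cf$K, replace = TRUE)
  response_tables <- vector("list", cf$K)
  mp_tables <- vector("list", cf$K)
  truth <- vector("list", cf$K)
  for (k in seq_len(cf$K)) {
    set.seed(group_seeds[k])
    gid <- sprintf("g%03d", k)
    members <- paste0(gid, "p", seq_len(cf$n))
    ab <- draw_centered_pairs(cf$n, cf$var_actor, cf$var_partner,
                              cf$cov_actor_partner)
    alpha <- ab[, 1]; beta <- ab[, 2]
    e_i <- drop(draw_centered_pairs(cf$n, cf$var_e_ind, cf$var_e_ind,
                                    0)[, 1])
    alpha_mp <- cf$b_ind * alpha + cf$c_ind * beta + e_i
    beta_mp <- drop(draw_centered_pairs(cf$n, cf$var_partner_mp,
                                        cf$var_partner_mp, 0)[, 1])
    G <- draw_projected_gammas(cf$n, cf$var_rel, cf$cov_rel_dyadic)
    Dm <- draw_projected_gammas(cf$n, cf$var_e_dyad, cf$cov_d)
    Gmp <- cf$b_dyad * G + cf$c_dyad * t(G) + Dm
    shared <- lapply(seq_len(cf$m), function(ind) {
      if (cf$var_shared_noise > 0) {
        matrix(stats::rnorm(cf$n^2, sd = sqrt(cf$var_shared_noise)), cf$n)
      } else matrix(0, cf$n, cf$n)
    })
    mk_tables <- function(base, kind, prefix) {
      lapply(seq_len(cf$m), function(ind) {
        noise <- if (cf$var_noise > 0) {
          matrix(stats::rnorm(cf$n^2, sd = sqrt(cf$var_noise)), cf$n)
        } else matrix(0, cf$n, cf$n)
        vals <- base + noise + shared[[ind]]
        round_robin_table(vals, members = members, group_id = gid,
                          variable = paste0(prefix, ind), kind = kind)
      })
    }
    base_resp <- cf$mu + outer(alpha, rep(1, cf$n)) +
      outer(rep(1, cf$n), beta) + G
    base_mp <- cf$mu + outer(alpha_mp, rep(1, cf$n)) +
      outer(rep(1, cf$n), beta_mp) + Gmp
    response_tables[[k]] <- mk_tables(base_resp, "response", "resp")
    mp_tables[[k]] <- mk_tables(base_mp, "metaperception", "mp")
    rownames(G) <- colnames(G) <- members
    rownames(Gmp) <- colnames(Gmp) <- members
    truth[[k]] <- list(group_id = gid, members = members,
                       alpha = setNames(alpha, members),
                       beta = setNames(beta, members),
                       alpha_mp = setNames(alpha_mp, members),
                       beta_mp = setNames(beta_mp, members),
                       gamma = G, gamma_mp = Gmp)
  }
  structure(list(config = cf, response_tables = response_tables,
                 mp_tables = mp_tables, truth = truth),
            class = "arrma_sim")
}

#' @export
print.arrma_sim <- function(x, ...) {
  cat("Simulated SRM/ARRMA data:", x$config$K, "groups of",
      x$config$n, "|", x$config$m, "indicator(s) per construct | seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Run the full estimation pipeline on simulated (or real) tables
#'
#' Decomposes every indicator table, averages indicators into composites per
#' group, and assembles the individual and dyadic datasets.
#'
#' @param sim an `arrma_sim` (or a list with `response_tables` and
#'   `mp_tables` in the same layout).
#' @return list with `individual` (an `individual_records` data frame) and
#'   `dyads` (a `dyad_table`).
#' @export
pipeline_datasets <- function(sim) {
  comp <- function(tabs) composite_effects(lapply(tabs, decompose_round_robin))
  resp_eff <- lapply(sim$response_tables, comp)
  mp_eff <- lapply(sim$mp_tables, comp)
  individual <- suppressMessages(build_individual_dataset(resp_eff, mp_eff))
  dyads <- build_dyad_table(resp_eff, mp_eff)
  list(individual = individual, dyads = dyads)
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeatedly simulates data from a known configuration, runs the full
#' pipeline (simulate, decompose, assemble, fit), and summarizes bias, RMSE,
#' and Monte-Carlo standard error for every ARRMA parameter: the
#' individual-level paths and reciprocity covariance, the minimal dyadic
#' paths and dyadic reciprocity, and the full-dyadic distinguishable paths
#' and disturbance covariance.  Fit failures are counted and reported, not
#' fatal.
#'
#' @param config a [sim_config()]; its seed spawns one sub-seed per
#'   replicate.
#' @param replicates number of Monte-Carlo replicates.
#' @param wald_alpha significance level for the per-replicate Wald test of
#'   the individual accuracy path (its rejection rate is reported).
#' @return object of class `recovery_report`: data frame `summary` with one
#'   row per parameter (truth, mean estimate, bias, RMSE, Monte-Carlo SE),
#'   `c_wald_rejection_rate`, `n_failed`, `replicates`.
#' @export
recovery_experiment <- function(config, replicates = 200, wald_alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"), replicates >= 2)
  set.seed(config$seed)
  rep_seeds <- sample.int(2147483646L, replicates, replace = TRUE)
  truth <- c(b_ind = config$b_ind, c_ind = config$c_ind,
             a_ind = config$cov_actor_partner,
             b_min = config$b_dyad, c_min = config$c_dyad,
             a_dyad = config$cov_rel_dyadic,
             B_full = config$b_dyad, B_prime_full = config$b_dyad,
             C_full = config$c_dyad, C_prime_full = config$c_dyad,
             D_full = config$cov_d)
  est <- matrix(NA_real_, replicates, length(truth),
                dimnames = list(NULL, names(truth)))
  c_reject <- rep(NA, replicates)
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    cfg_r <- config; cfg_r$seed <- rep_seeds[r]
    res <- tryCatch({
      sim <- simulate_srm_arrma(cfg_r)
      ds <- pipeline_datasets(sim)
      fi <- fit_individual_arrma(ds$individual)
      fm <- fit_minimal_dyadic(ds$dyads)
      ff <- fit_full_dyadic_distinguishable(ds$dyads)
      list(vals = c(fi$b, fi$c, fi$a_cov, fm$b, fm$c, fm$a_cov,
                    ff$B, ff$B_prime, ff$C, ff$C_prime, ff$D),
           reject = fi$p[["c"]] < wald_alpha)
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    est[r, ] <- res$vals
    c_reject[r] <- res$reject
  }
  ok <- stats::complete.cases(est)
  mean_est <- colMeans(est[ok, , drop = FALSE])
  bias <- mean_est - truth
  rmse <- sqrt(colMeans(sweep(est[ok, , drop = FALSE], 2, truth)^2))
  mc_se <- apply(est[ok, , drop = FALSE], 2, stats::sd) / sqrt(sum(ok))
  structure(list(
    summary = data.frame(parameter = names(truth), truth = unname(truth),
                         mean_estimate = unname(mean_est),
                         bias = unname(bias), rmse = unname(rmse),
                         mc_se = unname(mc_se)),
    c_wald_rejection_rate = mean(c_reject[ok]),
    n_failed = n_failed, replicates = replicates,
    config = config),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", x$replicates, "replicates (",
      x$n_failed, "failed ) | K =", x$config$K, ", n =", x$config$n, "\n")
  s <- x$summary
  s[, -1] <- round(s[, -1], 4)
  print(s, row.names = FALSE)
  cat(sprintf("  Wald rejection rate for accuracy path: %.3f\n",
              x$c_wald_rejection_rate))
  invisible(x)
}
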