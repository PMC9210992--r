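#' Build the dyad-format dataset of relationship effects
#'
#' Merges the yoked relationship effects of the interpersonal response with
#' the relationship effects of the metaperception into one row per dyad (the
#' "dyad structure").  Member designation is canonicalized lexicographically
#' (`i < j`) so results do not depend on input ordering.  Metaperceptions may
#' be unidirectional (half-block designs): then `gamma_mp_ji` is `NA`.
#'
#' @param response_effects `srm_effects` or list of them (per group, and for
#'   block designs per direction).  Both directions of every response dyad
#'   must be present.
#' @param mp_effects metaperception `srm_effects` or list of them.
#' @return data frame of class `dyad_table` with columns `group_id`, `i`,
#'   `j`, `gamma_ij`, `gamma_ji`, `gamma_mp_ij`, `gamma_mp_ji`, where
#'   `gamma_mp_ij` is the relationship effect of i's prediction of j's
#'   response to i.
#' @export
build_dyad_table <- function(response_effects, mp_effects) {
  resp <- effects_pair_lookup(response_effects)
  mp <- effects_pair_lookup(mp_effects)
  groups <- unique(resp$group_id)
  rows <- list()
  for (g in groups) {
    rg <- resp[resp$group_id == g, ]
    mg <- mp[mp$group_id == g, ]
    key <- function(a, b) paste(a, b, sep = "\r")
    rmap <- setNames(rg$relationship_effect, key(rg$actor_id, rg$partner_id))
    mmap <- setNames(mg$relationship_effect, key(mg$actor_id, mg$partner_id))
    pairs <- unique(t(apply(rg[, c("actor_id", "partner_id")], 1, sort)))
    if (any(duplicated(key(rg$actor_id, rg$partner_id)))) {
      stop("group '", g, "': duplicate directed response pairs")
    }
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      gij <- rmap[key(i, j)]; gji <- rmap[key(j, i)]
      if (is.na(gij) || is.na(gji)) {
        stop("group '", g, "': response relationship effect missing for ",
             "direction ", if (is.na(gij)) paste0(i, "->", j)
             else paste0(j, "->", i))
      }
      rows[[length(rows) + 1]] <- data.frame(
        group_id = g, i = i, j = j,
        gamma_ij = unname(gij), gamma_ji = unname(gji),
        gamma_mp_ij = unname(mmap[key(i, j)]),
        gamma_mp_ji = unname(mmap[key(j, i)]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out[, c("group_id", "i", "j")])) {
    stop("duplicate dyads after canonicalization")
  }
  if (any(is.na(out$gamma_mp_ij) & is.na(out$gamma_mp_ji))) {
    stop("some dyads carry no metaperception relationship effect at all")
  }
  # ensure the defined mp direction sits in gamma_mp_ij for half-block data
  flip <- is.na(out$gamma_mp_ij) & !is.na(out$gamma_mp_ji)
  if (any(flip)) {
    out[flip, c("i", "j")] <- out[flip, c("j", "i")]
    out[flip, c("gamma_ij", "gamma_ji")] <- out[flip, c("gamma_ji", "gamma_ij")]
    out[flip, c("gamma_mp_ij", "gamma_mp_ji")] <-
      out[flip, c("gamma_mp_ji", "gamma_mp_ij")]
  }
  class(out) <- c("dyad_table", "data.frame")
  out
}

effects_pair_lookup <- function(effects) {
  effects <- as_effects_list(effects)
  do.call(rbind, lapply(effects, relationship_df))
}

#' Pairwise (double-entry) restructuring of a dyad table
#'
#' Each dyad contributes two rows with the member roles swapped, so the
#' "self" and "partner" columns have identical sample means and variances by
#' construction and all cross-moments are exchange-symmetric.
#'
#' @param records a `dyad_table`; reciprocal metaperceptions are required
#'   (use the incomplete-data minimal model otherwise).
#' @return data frame of class `pairwise_table` with columns `dyad_id`,
#'   `member_role`, `self_gamma`, `partner_gamma`, `self_mp_gamma`,
#'   `partner_mp_gamma`.
#' @export
to_pairwise <- function(records) {
  stopifnot(inherits(records, "dyad_table") || is.data.frame(records))
  if (any(is.na(records$gamma_mp_ij)) || any(is.na(records$gamma_mp_ji))) {
    stop("metaperceptions are unidirectional; pairwise double entry needs ",
         "both directions (use fit_minimal_dyadic on the dyad table instead)")
  }
  dyad_id <- paste(records$group_id, records$i, records$j, sep = ":")
  first <- data.frame(dyad_id = dyad_id, member_role = 1L,
                      self_gamma = records$gamma_ij,
                      partner_gamma = records$gamma_ji,
                      self_mp_gamma = records$gamma_mp_ij,
                      partner_mp_gamma = records$gamma_mp_ji,
                      stringsAsFactors = FALSE)
  second <- data.frame(dyad_id = dyad_id, member_role = 2L,
                       self_gamma = records$gamma_ji,
                       partner_gamma = records$gamma_ij,
                       self_mp_gamma = records$gamma_mp_ji,
                       partner_mp_gamma = records$gamma_mp_ij,
                       stringsAsFactors = FALSE)
  out <- rbind(first, second)
  out <- out[order(out$dyad_id, out$member_role), ]
  rownames(out) <- NULL
  class(out) <- c("pairwise_table", "data.frame")
  out
}

## Extract the (outcome, predictor1, predictor2) columns for minimal fits and
## the four-variable layout for full fits.
dyadic_three_cols <- function(data) {
  if (inherits(data, "pairwise_table") ||
      all(c("self_gamma", "partner_gamma", "self_mp_gamma") %in% names(data))) {
    list(y = data$self_mp_gamma,
         x = cbind(g_self = data$self_gamma, g_partner = data$partner_gamma),
         entry = "pairwise")
  } else {
    if (any(is.na(data$gamma_mp_ij))) {
      stop("gamma_mp_ij missing for some dyads")
    }
    list(y = data$gamma_mp_ij,
         x = cbind(g_self = data$gamma_ij, g_partner = data$gamma_ji),
         entry = "dyad")
  }
}

dyadic_four_matrix <- function(data) {
  if (inherits(data, "pairwise_table") ||
      all(c("self_gamma", "partner_gamma", "self_mp_gamma",
            "partner_mp_gamma") %in% names(data))) {
    list(X = cbind(g1 = data$self_gamma, g2 = data$partner_gamma,
                   mp1 = data$self_mp_gamma, mp2 = data$partner_mp_gamma),
         entry = "pairwise",
         n_dyads = length(unique(data$dyad_id)))
  } else {
    if (any(is.na(data$gamma_mp_ij)) || any(is.na(data$gamma_mp_ji))) {
      stop("full dyadic models need reciprocal metaperceptions")
    }
    list(X = cbind(g1 = data$gamma_ij, g2 = data$gamma_ji,
                   mp1 = data$gamma_mp_ij, mp2 = data$gamma_mp_ji),
         entry = "dyad", n_dyads = nrow(data))
  }
}

#' Minimal dyadic ARRMA fit
#'
#' Regression of the dyadic metaperception relationship effect on the two
#' yoked response relationship effects, with their covariance free (dyadic
#' reciprocity, A).  Accepts dyad-format input (one row per dyad; works with
#' unidirectional metaperceptions) or a pairwise double-entry table (one
#' pooled regression over the doubled rows, matching the usual reporting of a
#' single (B, C) pair).  Standardized coefficients equal the closed-form
#' two-predictor solution at the sample correlations.
#'
#' Standard errors for pairwise input are computed from the doubled table
#' as-is; the two rows of one dyad are not independent, so these match
#' conventional double-entry reports but understate sampling variability.  A
#' dyad-cluster robust option (`robust = "dyad"`) is available.
#'
#' @param data a `dyad_table` or `pairwise_table`.
#' @param robust `"none"` (default) or `"dyad"` for cluster-robust standard
#'   errors on pairwise input.
#' @return object of class `arrma_dyadic_fit` with `b`, `c`, `a_cov`,
#'   `a_corr`, standardized paths, `se`, `z`, `p`, `r_squared`, `e_var`,
#'   `n_obs`, `entry`.
#' @export
fit_minimal_dyadic <- function(data, robust = c("none", "dyad")) {
  robust <- match.arg(robust)
  d3 <- dyadic_three_cols(data)
  X <- cbind(d3$x, y = d3$y)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 rows")
  S <- stats::cov(X)
  if (S[1, 1] <= 0 || S[2, 2] <= 0) stop("zero variance in a predictor")
  fit <- path_fit_two_predictor(S, n, pred = c("g_self", "g_partner"),
                                outcome = "y")
  se <- c(b = fit$se[1], c = fit$se[2],
          a_cov = cov_se(S, n, 1, 2))
  if (robust == "dyad" && d3$entry == "pairwise") {
    se[c("b", "c")] <- cluster_robust_se(d3$x, d3$y, data$dyad_id)
  }
  out <- list(b = fit$b[1], c = fit$b[2],
              a_cov = S[1, 2], a_corr = stats::cov2cor(S)[1, 2],
              standardized_b = fit$b_std[1], standardized_c = fit$b_std[2],
              se = se, e_var = fit$e_var, r_squared = fit$r_squared,
              n_obs = n, entry = d3$entry, robust = robust)
  out$z <- c(b = out$b / se[["b"]], c = out$c / se[["c"]],
             a_cov = out$a_cov / se[["a_cov"]])
  out$p <- 2 * stats::pnorm(-abs(out$z))
  class(out) <- "arrma_dyadic_fit"
  out
}

cluster_robust_se <- function(x, y, cluster) {
  X <- cbind(1, x)
  b <- solve(crossprod(X), crossprod(X, y))
  r <- drop(y - X %*% b)
  bread <- solve(crossprod(X))
  scores <- rowsum(X * r, cluster)
  meat <- crossprod(as.matrix(scores))
  V <- bread %*% meat %*% bread
  sqrt(diag(V))[-1]
}

#' @export
print.arrma_dyadic_fit <- function(x, ...) {
  cat("Minimal dyadic ARRMA (", x$entry, " entry) | N rows = ", x$n_obs,
      "\n", sep = "")
  tab <- data.frame(
    unstandardized = c(B = x$b, A = x$a_cov, C = x$c),
    se = c(x$se[["b"]], x$se[["a_cov"]], x$se[["c"]]),
    standardized = c(x$standardized_b, x$a_corr, x$standardized_c),
    p = c(x$p[["b"]], x$p[["a_cov"]], x$p[["c"]]))
  print(round(tab, 4))
  cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Full dyadic ARRMA for distinguishable dyads
#'
#' Two-equation just-identified system on dyad-format input: each member's
#' metaperception relationship effect is regressed on their own response
#' relationship effect (assumed reciprocity, B and B') and on the partner's
#' (metaperception accuracy, C and C'), with a free covariance between the
#' two response effects (reciprocity, A) and a free covariance between the
#' two disturbances (reciprocity of metaperceptions, D).  The model
#' reproduces the sample covariance matrix exactly: chi-square 0 on 0 df.
#'
#' @param records a `dyad_table` (pairwise input is rejected: member roles
#'   must be fixed for distinguishable dyads).
#' @return object of class `full_dyadic_fit`.
#' @export
fit_full_dyadic_distinguishable <- function(records) {
  if (inherits(records, "pairwise_table")) {
    stop("distinguishable-dyad fit requires dyad-format input, not the ",
         "pairwise double-entry table")
  }
  d4 <- dyadic_four_matrix(records)
  X <- d4$X
  n <- nrow(X)
  if (n < 5) stop("need at least 5 dyads")
  S <- stats::cov(X)
  eq1 <- path_fit_two_predictor(S, n, pred = c("g1", "g2"), outcome = "mp1")
  eq2 <- path_fit_two_predictor(S, n, pred = c("g2", "g1"), outcome = "mp2")
  b1 <- c(eq1$b[1], eq1$b[2])            # B, C   (mp1 on g1, g2)
  b2 <- c(eq2$b[1], eq2$b[2])            # B', C' (mp2 on g2, g1)
  # disturbance covariance: residual cross-covariance on the n-1 divisor
  bv1 <- c(b1[1], b1[2])                 # coefficients on (g1, g2)
  bv2 <- c(b2[2], b2[1])                 # coefficients on (g1, g2)
  Sxx <- S[c("g1", "g2"), c("g1", "g2")]
  D <- S["mp1", "mp2"] -
    drop(crossprod(bv1, S[c("g1", "g2"), "mp2"])) -
    drop(crossprod(bv2, S[c("g1", "g2"), "mp1"])) +
    drop(t(bv1) %*% Sxx %*% bv2)
  d_corr <- D / sqrt(eq1$e_var * eq2$e_var)
  out <- list(
    B = b1[1], B_prime = b2[1], C = b1[2], C_prime = b2[2],
    A = S["g1", "g2"], A_corr = stats::cov2cor(S)["g1", "g2"],
    D = D, D_corr = d_corr,
    std = c(B = eq1$b_std[1], C = eq1$b_std[2],
            B_prime = eq2$b_std[1], C_prime = eq2$b_std[2]),
    disturbance_var = c(eq1$e_var, eq2$e_var),
    r_squared_mp = eq1$r_squared, r_squared_mp_prime = eq2$r_squared,
    se = c(B = eq1$se[1], C = eq1$se[2],
           B_prime = eq2$se[1], C_prime = eq2$se[2],
           A = cov_se(S, n, 1, 2),
           D = sqrt((eq1$e_var * eq2$e_var + D^2) / (n - 1))),
    chi_square = 0, df = 0L, p_value = NA_real_,
    adjusted_chi_square = NULL, adjusted_df = NULL,
    constrained = FALSE, entry = d4$entry, n_obs = n, S = S)
  class(out) <- "full_dyadic_fit"
  out
}

#' Olsen-Kenny indistinguishability constraints
#'
#' The equality constraints that encode arbitrary member designation: equal
#' predictor means, equal predictor variances, equal outcome intercepts,
#' equal disturbance variances (with both disturbance loadings fixed at
#' 1.00), and equal structural paths (B = B', C = C').  All are on by
#' default; individual constraints can be released.
#'
#' @param equal_predictor_means,equal_predictor_variances,equal_outcome_intercepts,equal_disturbance_variances,equal_paths logicals.
#' @return object of class `constraint_set`.
#' @export
olsen_kenny_constraints <- function(equal_predictor_means = TRUE,
                                    equal_predictor_variances = TRUE,
                                    equal_outcome_intercepts = TRUE,
                                    equal_disturbance_variances = TRUE,
                                    equal_paths = TRUE) {
  structure(list(equal_predictor_means = equal_predictor_means,
                 equal_predictor_variances = equal_predictor_variances,
                 equal_outcome_intercepts = equal_outcome_intercepts,
                 equal_disturbance_variances = equal_disturbance_variances,
                 equal_paths = equal_paths),
            class = "constraint_set")
}

full_dyadic_spec <- function(constraints, start = NULL) {
  lab <- function(flag, shared, a, b) if (flag) c(shared, shared) else c(a, b)
  cs <- constraints
  paths <- data.frame(
    from = c("g1", "g2", "g2", "g1"),
    to = c("mp1", "mp1", "mp2", "mp2"),
    label = c(lab(cs$equal_paths, "B", "B", "Bp")[1],
              lab(cs$equal_paths, "C", "C", "Cp")[1],
              lab(cs$equal_paths, "B", "B", "Bp")[2],
              lab(cs$equal_paths, "C", "C", "Cp")[2]),
    value = NA_real_)
  covariances <- data.frame(
    v1 = c("g1", "g2", "g1", "mp1", "mp2", "mp1"),
    v2 = c("g1", "g2", "g2", "mp1", "mp2", "mp2"),
    label = c(lab(cs$equal_predictor_variances, "Vg", "Vg1", "Vg2"),
              "A",
              lab(cs$equal_disturbance_variances, "Vd", "Vd1", "Vd2"),
              "D"),
    value = NA_real_)
  means <- data.frame(
    var = c("g1", "g2", "mp1", "mp2"),
    label = c(lab(cs$equal_predictor_means, "Mg", "Mg1", "Mg2"),
              lab(cs$equal_outcome_intercepts, "Imp", "Imp1", "Imp2")),
    value = NA_real_)
  model_spec(observed = c("g1", "g2", "mp1", "mp2"),
             paths = paths, covariances = covariances, means = means)
}

#' Full dyadic ARRMA for indistinguishable dyads
#'
#' Constrained maximum-likelihood fit of the full dyadic model with the
#' Olsen-Kenny equality constraints and a mean structure, on pairwise
#' double-entry or dyad-format input.  The I-SAT (indistinguishable,
#' saturated) model is fitted alongside: with pairwise input its chi-square
#' is exactly zero (the doubled sample moments satisfy the equalities), and
#' with dyad-format input the I-SAT chi-square and df are subtracted from the
#' model's to give the adjusted fit statistic.
#'
#' @param data a `pairwise_table` or `dyad_table`.
#' @param constraints an [olsen_kenny_constraints()] object.
#' @param chisq_multiplier passed to [ml_fit()].
#' @return object of class `full_dyadic_fit`; the engine fit is in `$covfit`
#'   and the I-SAT fit in `$isat`.
#' @export
fit_full_dyadic_indistinguishable <- function(
    data, constraints = olsen_kenny_constraints(),
    chisq_multiplier = c("n-1", "n")) {
  chisq_multiplier <- match.arg(chisq_multiplier)
  d4 <- dyadic_four_matrix(data)
  X <- d4$X
  n <- nrow(X)
  mom <- sample_moments(X)
  spec <- full_dyadic_spec(constraints)
  # start from the symmetrized closed-form unconstrained solution
  S <- mom$S; mns <- mom$means
  Sxx <- S[c("g1", "g2"), c("g1", "g2")]
  b1 <- solve(Sxx, S[c("g1", "g2"), "mp1"])
  b2 <- solve(Sxx[2:1, 2:1], S[c("g2", "g1"), "mp2"])
  ev1 <- S["mp1", "mp1"] - crossprod(b1, S[c("g1", "g2"), "mp1"])
  ev2 <- S["mp2", "mp2"] - crossprod(b2, S[c("g2", "g1"), "mp2"])
  start <- c(B = mean(c(b1[1], b2[1])), C = mean(c(b1[2], b2[2])),
             Vg = mean(c(S[1, 1], S[2, 2])), A = S[1, 2],
             Vd = mean(c(ev1, ev2)), D = S["mp1", "mp2"] / 2,
             Mg = mean(mns[c("g1", "g2")]),
             Imp = mean(mns[c("mp1", "mp2")]))
  start <- start[names(start) %in% free_labels(spec)]
  eng <- ml_fit(spec, mom, start = start, chisq_multiplier = chisq_multiplier)
  isat <- fit_isat(data, chisq_multiplier = chisq_multiplier)
  est <- eng$estimates
  # when a constraint is released the primed parameter has its own label
  getp <- function(primed, shared) {
    if (primed %in% names(est)) est[[primed]] else est[[shared]]
  }
  Vd_hat <- if ("Vd" %in% names(est)) c(est[["Vd"]], est[["Vd"]])
            else c(est[["Vd1"]], est[["Vd2"]])
  Vg_hat <- if ("Vg" %in% names(est)) c(est[["Vg"]], est[["Vg"]])
            else c(est[["Vg1"]], est[["Vg2"]])
  std <- eng$standardized
  stdv <- function(labi) std$standardized[std$label == labi][1]
  adj_chi <- if (eng$df >= isat$df) eng$chi_square - isat$chi_square
             else NA_real_
  adj_df <- if (eng$df >= isat$df) eng$df - isat$df else NA_integer_
  impvar_mp <- diag(eng$Sigma_hat)[c("mp1", "mp2")]
  out <- list(
    B = est[["B"]], B_prime = getp("Bp", "B"),
    C = est[["C"]], C_prime = getp("Cp", "C"),
    A = est[["A"]], A_corr = est[["A"]] / sqrt(prod(Vg_hat)),
    D = est[["D"]], D_corr = est[["D"]] / sqrt(prod(Vd_hat)),
    std = c(B = stdv("B"), C = stdv("C")),
    disturbance_var = Vd_hat,
    r_squared_mp = unname(1 - Vd_hat[1] / impvar_mp[1]),
    r_squared_mp_prime = unname(1 - Vd_hat[2] / impvar_mp[2]),
    se = c(B = unname(eng$se[if ("B" %in% names(est)) "B" else "Bp"]),
           C = unname(eng$se[if ("C" %in% names(est)) "C" else "Cp"]),
           A = unname(eng$se["A"]), D = unname(eng$se["D"])),
    chi_square = eng$chi_square, df = eng$df, p_value = eng$p_value,
    adjusted_chi_square = adj_chi, adjusted_df = adj_df,
    constrained = TRUE, entry = d4$entry, n_obs = n,
    covfit = eng, isat = isat)
  class(out) <- "full_dyadic_fit"
  out
}

#' Fit the I-SAT model
#'
#' The saturated four-variable model (two yoked response relationship
#' effects, two metaperception relationship effects) subject only to the
#' indistinguishability equalities: equal means and variances within each
#' variable pair and symmetric cross-covariances under the member-designation
#' swap.  Eight free parameters against fourteen sample moments give 6 df.
#' On pairwise double-entered data the doubled sample moments satisfy the
#' equalities exactly and the chi-square is zero; on dyad-format input the
#' chi-square reflects the arbitrariness of member designation and is used to
#' adjust substantive constrained fits.
#'
#' @param data a `pairwise_table` or `dyad_table`.
#' @param chisq_multiplier passed to [ml_fit()].
#' @return a `covfit` object (with attribute `entry`).
#' @export
fit_isat <- function(data, chisq_multiplier = c("n-1", "n")) {
  chisq_multiplier <- match.arg(chisq_multiplier)
  d4 <- dyadic_four_matrix(data)
  mom <- sample_moments(d4$X)
  spec <- isat_spec()
  S <- mom$S; mns <- mom$means
  start <- c(Mg = mean(mns[c("g1", "g2")]),
             Mmp = mean(mns[c("mp1", "mp2")]),
             Vg = mean(c(S["g1", "g1"], S["g2", "g2"])),
             Vmp = mean(c(S["mp1", "mp1"], S["mp2", "mp2"])),
             Cgg = S["g1", "g2"], Cmm = S["mp1", "mp2"],
             Cgm_same = mean(c(S["g1", "mp1"], S["g2", "mp2"])),
             Cgm_cross = mean(c(S["g1", "mp2"], S["g2", "mp1"])))
  fit <- ml_fit(spec, mom, start = start,
                chisq_multiplier = chisq_multiplier)
  attr(fit, "entry") <- d4$entry
  fit
}

isat_spec <- function() {
  model_spec(
    observed = c("g1", "g2", "mp1", "mp2"),
    covariances = data.frame(
      v1 = c("g1", "g2", "mp1", "mp2", "g1", "mp1", "g1", "g2", "g1", "g2"),
      v2 = c("g1", "g2", "mp1", "mp2", "g2", "mp2", "mp1", "mp2", "mp2",
             "mp1"),
      label = c("Vg", "Vg", "Vmp", "Vmp", "Cgg", "Cmm",
                "Cgm_same", "Cgm_same", "Cgm_cross", "Cgm_cross"),
      value = NA_real_),
    means = data.frame(var = c("g1", "g2", "mp1", "mp2"),
                       label = c("Mg", "Mg", "Mmp", "Mmp"),
                       value = NA_real_))
}

#' @export
print.full_dyadic_fit <- function(x, ...) {
  cat("Full dyadic ARRMA |",
      if (x$constrained) "indistinguishable (Olsen-Kenny constraints)"
      else "distinguishable", "|", x$entry, "entry | N =", x$n_obs, "\n")
  tab <- data.frame(
    unstandardized = c(B = x$B, `B'` = x$B_prime, A = x$A,
                       C = x$C, `C'` = x$C_prime, D = x$D),
    standardized = c(if (x$constrained)
      c(x$std["B"], x$std["B"], x$A_corr, x$std["C"], x$std["C"], x$D_corr)
      else c(x$std["B"], x$std["B_prime"], x$A_corr,
             x$std["C"], x$std["C_prime"], x$D_corr)))
  print(round(tab, 4))
  cat(sprintf("  R^2(MP) = %.3f, R^2(MP') = %.3f | chi-square(%d) = %.4f\n",
              x$r_squared_mp, x$r_squared_mp_prime, x$df, x$chi_square))
  if (!is.null(x$adjusted_chi_square) && x$entry == "dyad") {
    cat(sprintf("  I-SAT adjusted: chi-square(%d) = %.4f\n",
                x$adjusted_df, x$adjusted_chi_square))
  }
  invisible(x)
}
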