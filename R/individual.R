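#' Assemble the person-level ARRMA dataset
#'
#' Individual-level ARRMA uses three SRM components per person: the actor and
#' partner effects of the interpersonal response and the actor effect of the
#' metaperception.  Partner effects of metaperceptions are not used and are
#' discarded (with a notice).  Effects from several groups are pooled into one
#' dataset, one row per person.
#'
#' @param response_effects `srm_effects` (typically a composite across
#'   indicators) or a list of them, one per group.
#' @param mp_effects matching metaperception `srm_effects` (or list).
#' @return data frame of class `individual_records` with columns `group_id`,
#'   `person_id`, `alpha_r`, `beta_r`, `alpha_mp`.
#' @export
build_individual_dataset <- function(response_effects, mp_effects) {
  response_effects <- as_effects_list(response_effects)
  mp_effects <- as_effects_list(mp_effects)
  if (length(response_effects) != length(mp_effects)) {
    stop("need one metaperception effects object per response effects object")
  }
  mp_by_group <- setNames(mp_effects,
                          vapply(mp_effects, function(e) e$group_id, ""))
  message("metaperception partner effects are not used at the individual ",
          "level and are discarded")
  rows <- lapply(response_effects, function(re) {
    mp <- mp_by_group[[re$group_id]]
    if (is.null(mp)) stop("no metaperception effects for group '",
                          re$group_id, "'")
    persons <- names(re$actor)
    missing_mp <- setdiff(persons, names(mp$actor))
    extra_mp <- setdiff(names(mp$actor), persons)
    if (length(missing_mp) || length(extra_mp)) {
      stop("group '", re$group_id, "': person sets differ between responses ",
           "and metaperceptions (missing: ",
           paste(missing_mp, collapse = ","), "; extra: ",
           paste(extra_mp, collapse = ","), ")")
    }
    data.frame(group_id = re$group_id, person_id = persons,
               alpha_r = unname(re$actor[persons]),
               beta_r = unname(re$partner[persons]),
               alpha_mp = unname(mp$actor[persons]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!is.finite(as.matrix(out[, c("alpha_r", "beta_r", "alpha_mp")])))) {
    stop("non-finite SRM component in individual dataset")
  }
  class(out) <- c("individual_records", "data.frame")
  out
}

as_effects_list <- function(x) {
  if (inherits(x, "srm_effects")) list(x)
  else {
    stopifnot(all(vapply(x, inherits, TRUE, "srm_effects")))
    x
  }
}

#' Standardized ARRMA paths from three correlations
#'
#' Closed-form standardized assumed reciprocity and metaperception accuracy
#' from the correlations among the response actor effect, the response partner
#' effect, and the metaperception actor effect:
#' \deqn{b^* = \frac{\rho_{\alpha_r\alpha_{mp}} -
#'   \rho_{\alpha_r\beta_r}\,\rho_{\beta_r\alpha_{mp}}}{1 -
#'   \rho_{\alpha_r\beta_r}^2}, \qquad
#'   c^* = \frac{\rho_{\beta_r\alpha_{mp}} -
#'   \rho_{\alpha_r\beta_r}\,\rho_{\alpha_r\alpha_{mp}}}{1 -
#'   \rho_{\alpha_r\beta_r}^2}}
#' The same algebra applies at the dyadic level with the relationship-effect
#' correlations in place of the individual-level ones.
#'
#' @param r_ar_amp correlation of the response actor effect with the
#'   metaperception actor effect (assumed-reciprocity correlation).
#' @param r_ar_br correlation of response actor and partner effects
#'   (reciprocity).
#' @param r_br_amp correlation of the response partner effect with the
#'   metaperception actor effect (accuracy correlation).
#' @return list with `b_std` and `c_std`.
#' @export
arrma_closed_form <- function(r_ar_amp, r_ar_br, r_br_amp) {
  for (r in c(r_ar_amp, r_ar_br, r_br_amp)) {
    if (!is.finite(r) || abs(r) > 1) stop("correlations must lie in [-1, 1]")
  }
  if (abs(r_ar_br) >= 1) {
    stop("reciprocity is perfect (|rho| = 1); the model is unidentified")
  }
  den <- 1 - r_ar_br^2
  list(b_std = (r_ar_amp - r_ar_br * r_br_amp) / den,
       c_std = (r_br_amp - r_ar_br * r_ar_amp) / den)
}

#' Fit the individual-level ARRMA model
#'
#' The full model is the just-identified regression of the metaperception
#' actor effect on the response actor effect (assumed reciprocity, B) and the
#' response partner effect (metaperception accuracy, C), with the covariance
#' of the two predictors free (reciprocity, A).  It reproduces the sample
#' covariance matrix exactly, so no fit statistic exists (df = 0).  With
#' `restrict_accuracy = TRUE` the accuracy path is fixed to zero and the model
#' is refit by maximum likelihood; the likelihood-ratio statistic against the
#' saturated moments is reported on 1 df.  The reciprocity covariance is
#' unaffected by the restriction (the predictor block stays saturated).
#'
#' Because SRM effect estimates sum to zero within every group, a pooled
#' dataset of K groups of size n carries K(n-1) independent rows of
#' information, not Kn.  When `records` carries a `group_id` column the
#' residual degrees of freedom are therefore N - K - 2, the restricted-model
#' p-value uses the exact F reference on those degrees of freedom, and path
#' p-values use the matching t reference.  The chi-square value itself is
#' always reported with the conventional (N-1) multiplier so that it is
#' comparable with standard SEM software output.
#'
#' @param records an `individual_records` data frame
#'   (see [build_individual_dataset()]), or any data frame with columns
#'   `alpha_r`, `beta_r`, `alpha_mp` (and optionally `group_id`).
#' @param restrict_accuracy fix the accuracy path C to zero.
#' @param chisq_multiplier passed to [ml_fit()] for the restricted fit.
#' @return object of class `arrma_individual_fit`: `b`, `c`, `a_cov`,
#'   `a_corr`, `standardized_b`, `standardized_c`, `se`, `z`, `p`,
#'   `r_squared`, `e_var`, `n_obs`; for restricted fits also `chi_square`,
#'   `df`, `p_value` and the underlying engine fit in `$covfit`.
#' @export
fit_individual_arrma <- function(records, restrict_accuracy = FALSE,
                                 chisq_multiplier = c("n-1", "n")) {
  chisq_multiplier <- match.arg(chisq_multiplier)
  need <- c("alpha_r", "beta_r", "alpha_mp")
  stopifnot(all(need %in% names(records)))
  X <- as.matrix(records[, need])
  n <- nrow(X)
  if (n < 4) stop("need at least 4 persons; got ", n)
  K <- if ("group_id" %in% names(records)) {
    length(unique(records$group_id))
  } else 0L
  grouped <- K > 1
  resid_df <- if (grouped) n - K - 2L else n - 3L
  if (resid_df < 1) stop("too few persons for the number of groups")
  S <- stats::cov(X)
  if (S[1, 1] <= 0 || S[2, 2] <= 0) {
    stop("zero variance in a predictor (alpha_r or beta_r)")
  }
  if (!restrict_accuracy) {
    fit <- path_fit_two_predictor(S, n, pred = c("alpha_r", "beta_r"),
                                  outcome = "alpha_mp", resid_df = resid_df)
    out <- list(b = fit$b[1], c = fit$b[2],
                a_cov = S[1, 2], a_corr = stats::cov2cor(S)[1, 2],
                standardized_b = fit$b_std[1], standardized_c = fit$b_std[2],
                se = c(b = fit$se[1], c = fit$se[2],
                       a_cov = cov_se(S, if (grouped) n - K + 1 else n,
                                      1, 2)),
                e_var = fit$e_var, r_squared = fit$r_squared,
                chi_square = NULL, df = 0L, p_value = NULL,
                n_obs = n, restricted = FALSE)
  } else {
    spec <- restricted_individual_spec(S)
    mom <- sample_moments(S = S, n = n)
    eng <- ml_fit(spec, mom, chisq_multiplier = chisq_multiplier)
    est <- eng$estimates
    std <- eng$standardized
    # exact F reference for grouped data: F_ml = log(RSS0/RSS1) of the
    # nested regressions, so (exp(F)-1)*resid_df is the F statistic
    p_val <- if (grouped) {
      stats::pf((exp(eng$F_ml) - 1) * resid_df, 1, resid_df,
                lower.tail = FALSE)
    } else eng$p_value
    out <- list(b = unname(est["B"]), c = 0,
                a_cov = unname(est["A"]),
                a_corr = unname(est["A"] / sqrt(est["Va"] * est["Vb"])),
                standardized_b =
                  std$standardized[std$label == "B"][1],
                standardized_c = NA_real_,
                se = c(b = unname(eng$se["B"]), c = NA_real_,
                       a_cov = unname(eng$se["A"])),
                e_var = unname(est["Ve"]),
                r_squared = unname(1 - est["Ve"] /
                                     (est["B"]^2 * est["Va"] + est["Ve"])),
                chi_square = eng$chi_square, df = eng$df,
                p_value = p_val,
                n_obs = n, restricted = TRUE, covfit = eng)
  }
  out$resid_df <- resid_df
  out$z <- c(b = unname(out$b / out$se["b"]),
             c = if (restrict_accuracy) NA_real_
                 else unname(out$c / out$se["c"]),
             a_cov = unname(out$a_cov / out$se["a_cov"]))
  # t reference on the residual df for the path coefficients, normal for the
  # covariance
  out$p <- c(2 * stats::pt(-abs(out$z[c("b", "c")]), resid_df),
             2 * stats::pnorm(-abs(out$z["a_cov"])))
  class(out) <- "arrma_individual_fit"
  out
}

## closed-form two-predictor path fit from a covariance matrix; resid_df
## defaults to ordinary OLS accounting but callers with group-centered rows
## pass the within-group residual degrees of freedom
path_fit_two_predictor <- function(S, n, pred, outcome, resid_df = NULL) {
  Sxx <- S[pred, pred]
  Sxy <- S[pred, outcome]
  Syy <- S[outcome, outcome]
  R <- stats::cov2cor(S)
  if (abs(R[pred[1], pred[2]]) >= 1 - 1e-12) {
    stop("predictors are perfectly correlated; the model is unidentified")
  }
  b <- solve(Sxx, Sxy)
  e_var <- drop(Syy - crossprod(b, Sxy))          # divisor n-1 scale
  cf <- arrma_closed_form(R[pred[1], outcome], R[pred[1], pred[2]],
                          R[pred[2], outcome])
  if (is.null(resid_df)) resid_df <- n - length(pred) - 1
  sigma2 <- (n - 1) * e_var / resid_df            # OLS residual variance
  Vb <- sigma2 * solve(Sxx) / (n - 1)
  list(b = unname(b), se = unname(sqrt(diag(Vb))),
       b_std = c(cf$b_std, cf$c_std),
       e_var = e_var, r_squared = drop(1 - e_var / Syy),
       resid_df = resid_df)
}

## large-sample (Wishart) standard error of a sample covariance
cov_se <- function(S, n, i, j) {
  sqrt((S[i, i] * S[j, j] + S[i, j]^2) / (n - 1))
}

restricted_individual_spec <- function(S = NULL) {
  b0 <- if (is.null(S)) NA_real_ else S[1, 3] / S[1, 1]
  model_spec(
    observed = c("alpha_r", "beta_r", "alpha_mp"),
    paths = data.frame(from = "alpha_r", to = "alpha_mp",
                       label = "B", value = b0),
    covariances = data.frame(
      v1 = c("alpha_r", "beta_r", "alpha_r", "alpha_mp"),
      v2 = c("alpha_r", "beta_r", "beta_r", "alpha_mp"),
      label = c("Va", "Vb", "A", "Ve"),
      value = if (is.null(S)) NA_real_ else
        c(S[1, 1], S[2, 2], S[1, 2],
          max(S[3, 3] - b0^2 * S[1, 1], S[3, 3] / 10))))
}

#' @export
print.arrma_individual_fit <- function(x, ...) {
  cat("Individual-level ARRMA",
      if (x$restricted) "(restricted: accuracy fixed to 0)" else "(full)",
      "| N =", x$n_obs, "\n")
  tab <- data.frame(
    unstandardized = c(B = x$b, A = x$a_cov, C = x$c),
    se = c(x$se["b"], x$se["a_cov"], x$se["c"]),
    standardized = c(x$standardized_b, x$a_corr, x$standardized_c),
    p = c(x$p["b"], x$p["a_cov"], x$p["c"]))
  print(round(tab, 4))
  cat(sprintf("  R^2 = %.3f", x$r_squared))
  if (!is.null(x$chi_square)) {
    cat(sprintf(" | chi-square(%d) = %.4f, p = %.4f",
                x$df, x$chi_square, x$p_value))
  }
  cat("\n")
  invisible(x)
}

#' Latent-variable individual ARRMA model
#'
#' Builds the structural-equation variant with three latent constructs —
#' response actor effects, response partner effects, and metaperception actor
#' effects — each measured by m indicators (the first indicator is the marker
#' with loading fixed at 1.00).  Error components of corresponding response
#' and metaperception indicators are allowed to covary, since the same person
#' produces both.  Structural parameters are assumed reciprocity (`B`),
#' reciprocity (`A`, an exogenous latent covariance), and metaperception
#' accuracy (`C`).
#'
#' @param indicator_records list of `individual_records` data frames, one per
#'   indicator, all with identical persons in identical order.
#' @return list of class `arrma_latent_model` with `spec` (a [model_spec()]),
#'   `data` (wide person-by-variable matrix with columns `a1..am`, `p1..pm`,
#'   `mp1..mpm`), and `m`.
#' @export
build_individual_latent_model <- function(indicator_records) {
  m <- length(indicator_records)
  if (m < 2) {
    stop("need >= 2 indicators per construct; with a single indicator use ",
         "the composite path model (fit_individual_arrma)")
  }
  ids <- lapply(indicator_records,
                function(d) paste(d$group_id, d$person_id))
  for (k in seq_len(m)) {
    if (!identical(ids[[k]], ids[[1]])) {
      stop("indicator ", k, " has a different person set/order")
    }
  }
  wide <- do.call(cbind, c(
    lapply(seq_len(m), function(k)
      setNames(indicator_records[[k]]["alpha_r"], paste0("a", k))),
    lapply(seq_len(m), function(k)
      setNames(indicator_records[[k]]["beta_r"], paste0("p", k))),
    lapply(seq_len(m), function(k)
      setNames(indicator_records[[k]]["alpha_mp"], paste0("mp", k)))))
  obs <- colnames(wide)
  a_ind <- paste0("a", seq_len(m))
  p_ind <- paste0("p", seq_len(m))
  mp_ind <- paste0("mp", seq_len(m))
  loading_rows <- function(latent, ind, tag) {
    data.frame(from = latent, to = ind,
               label = c(NA, paste0("l", tag, 2:m)),
               value = c(1, rep(1, m - 1)))
  }
  paths <- rbind(
    loading_rows("ACTOR", a_ind, "a"),
    loading_rows("PARTNER", p_ind, "p"),
    loading_rows("ACTOR_MP", mp_ind, "mp"),
    data.frame(from = c("ACTOR", "PARTNER"), to = "ACTOR_MP",
               label = c("B", "C"), value = NA))
  vr <- function(v) stats::var(wide[[v]])
  covariances <- rbind(
    data.frame(v1 = "ACTOR", v2 = "ACTOR", label = "Va",
               value = vr("a1") / 2),
    data.frame(v1 = "PARTNER", v2 = "PARTNER", label = "Vb",
               value = vr("p1") / 2),
    data.frame(v1 = "ACTOR", v2 = "PARTNER", label = "A",
               value = stats::cov(wide$a1, wide$p1) / 2),
    data.frame(v1 = "ACTOR_MP", v2 = "ACTOR_MP", label = "Ve",
               value = vr("mp1") / 4),
    data.frame(v1 = obs, v2 = obs, label = paste0("e_", obs),
               value = vapply(obs, vr, 0) / 2),
    data.frame(v1 = a_ind, v2 = mp_ind,
               label = paste0("r_", seq_len(m)), value = 0))
  spec <- model_spec(observed = obs,
                     latent = c("ACTOR", "PARTNER", "ACTOR_MP"),
                     paths = paths, covariances = covariances)
  structure(list(spec = spec, data = as.matrix(wide), m = m),
            class = "arrma_latent_model")
}

#' Fit the latent individual ARRMA model
#'
#' @param model an [build_individual_latent_model()] result.
#' @param ... passed to [ml_fit()].
#' @return a `covfit` object.
#' @export
fit_individual_latent <- function(model, ...) {
  stopifnot(inherits(model, "arrma_latent_model"))
  mom <- sample_moments(model$data)
  ml_fit(model$spec, mom, ...)
}
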