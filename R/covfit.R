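## Generic ML covariance + mean structure engine (RAM parameterization).
## Equality constraints are encoded by sharing a parameter label across
## several path / covariance / mean entries.

#' Declare a covariance-and-mean structure model
#'
#' A model is a directed path structure over observed and latent variables
#' (recursive only), a set of variances/covariances among exogenous variables
#' and disturbances, and optionally means/intercepts.  Each entry is either
#' fixed to a numeric value or free with a character label; entries sharing a
#' label are constrained to equality.
#'
#' @param observed character vector of observed variable names (order fixes
#'   the moment layout).
#' @param latent character vector of latent variable names (may be empty).
#' @param paths data frame with columns `from`, `to`, `label` (NA for fixed),
#'   `value` (fixed value, or start value for free entries; NA allowed).
#' @param covariances data frame with columns `v1`, `v2`, `label`, `value`.
#'   `v1 == v2` entries are variances (of exogenous variables or of the
#'   disturbance of endogenous ones).
#' @param means optional data frame with columns `var`, `label`, `value`
#'   (means of exogenous variables, intercepts of endogenous ones).  When
#'   present the model carries a mean structure.
#' @return object of class `model_spec`.
#' @seealso [ml_fit()], [spec_to_yaml()]
#' @export
model_spec <- function(observed, latent = character(),
                       paths = NULL, covariances = NULL, means = NULL) {
  observed <- as.character(observed)
  latent <- as.character(latent)
  vars <- c(observed, latent)
  if (anyDuplicated(vars)) stop("variable names must be unique")
  paths <- normalize_entries(paths, c("from", "to"), vars)
  covariances <- normalize_entries(covariances, c("v1", "v2"), vars)
  means <- if (is.null(means)) {
    data.frame(var = character(), label = character(), value = numeric())
  } else normalize_entries(means, "var", vars)
  check_recursive(paths, vars)
  structure(list(observed = observed, latent = latent, paths = paths,
                 covariances = covariances, means = means),
            class = "model_spec")
}

normalize_entries <- function(df, keycols, vars) {
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(character()), length(keycols)),
                                 keycols))
    df$label <- character(); df$value <- numeric()
    return(df)
  }
  df <- as.data.frame(df)
  for (k in keycols) {
    df[[k]] <- as.character(df[[k]])
    bad <- setdiff(df[[k]], vars)
    if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(df$label)) df$label <- NA_character_
  if (is.null(df$value)) df$value <- NA_real_
  df$label <- as.character(df$label)
  df$value <- as.numeric(df$value)
  if (any(is.na(df$label) & is.na(df$value))) {
    stop("each entry needs a label (free) or a value (fixed)")
  }
  df
}

check_recursive <- function(paths, vars) {
  if (!nrow(paths)) return(invisible())
  adj <- paths[, c("from", "to")]
  remaining <- vars
  repeat {
    edges <- adj[adj$from %in% remaining & adj$to %in% remaining, ,
                 drop = FALSE]
    if (!nrow(edges)) break
    # peel variables that are not a source for any remaining edge
    sinks <- setdiff(remaining, unique(edges$from))
    if (!length(sinks)) stop("path structure contains a feedback loop")
    remaining <- setdiff(remaining, sinks)
  }
  invisible()
}

free_labels <- function(spec) {
  labs <- c(spec$paths$label, spec$covariances$label, spec$means$label)
  unique(labs[!is.na(labs)])
}

default_start <- function(spec) {
  labs <- free_labels(spec)
  start <- setNames(rep(0, length(labs)), labs)
  # variances start at 1 unless a start value is supplied
  v <- spec$covariances
  for (i in seq_len(nrow(v))) {
    if (!is.na(v$label[i]) && v$v1[i] == v$v2[i] && start[v$label[i]] == 0) {
      start[v$label[i]] <- 1
    }
  }
  for (tab in list(spec$paths, spec$covariances, spec$means)) {
    for (i in seq_len(nrow(tab))) {
      if (!is.na(tab$label[i]) && !is.na(tab$value[i])) {
        start[tab$label[i]] <- tab$value[i]
      }
    }
  }
  start
}

## Seed free covariance/mean labels between observed variables from the
## sample moments (unless the spec supplies explicit start values), so
## saturated blocks start at their optimum.
moment_start <- function(spec, th0, S, xbar) {
  obs <- spec$observed
  v <- spec$covariances
  seeded <- character(0)
  for (i in seq_len(nrow(v))) {
    lab <- v$label[i]
    if (is.na(lab) || !is.na(v$value[i]) || lab %in% seeded) next
    if (v$v1[i] %in% obs && v$v2[i] %in% obs) {
      th0[lab] <- S[v$v1[i], v$v2[i]]
      seeded <- c(seeded, lab)
    }
  }
  m <- spec$means
  for (i in seq_len(nrow(m))) {
    lab <- m$label[i]
    if (is.na(lab) || !is.na(m$value[i]) || lab %in% seeded) next
    if (m$var[i] %in% obs && !is.null(xbar)) {
      th0[lab] <- xbar[m$var[i]]
      seeded <- c(seeded, lab)
    }
  }
  th0
}

## Build RAM matrices A (paths), S (covariances), M (means) for parameter
## vector theta (named by label).
ram_matrices <- function(spec, theta) {
  vars <- c(spec$observed, spec$latent)
  k <- length(vars)
  A <- matrix(0, k, k, dimnames = list(vars, vars))
  S <- matrix(0, k, k, dimnames = list(vars, vars))
  M <- setNames(rep(0, k), vars)
  p <- spec$paths
  for (i in seq_len(nrow(p))) {
    val <- if (is.na(p$label[i])) p$value[i] else theta[[p$label[i]]]
    A[p$to[i], p$from[i]] <- val
  }
  v <- spec$covariances
  for (i in seq_len(nrow(v))) {
    val <- if (is.na(v$label[i])) v$value[i] else theta[[v$label[i]]]
    S[v$v1[i], v$v2[i]] <- val
    S[v$v2[i], v$v1[i]] <- val
  }
  m <- spec$means
  for (i in seq_len(nrow(m))) {
    val <- if (is.na(m$label[i])) m$value[i] else theta[[m$label[i]]]
    M[m$var[i]] <- val
  }
  list(A = A, S = S, M = M)
}

#' Model-implied moments
#'
#' @param spec a [model_spec()].
#' @param theta named parameter vector (one element per free label).
#' @return list with `Sigma` (implied covariance of the observed variables),
#'   `mu` (implied observed means, NULL without a mean structure), and the
#'   full-variable covariance matrix `Sigma_all`.
#' @export
implied_moments <- function(spec, theta) {
  ram <- ram_matrices(spec, theta)
  k <- nrow(ram$A)
  B <- solve(diag(k) - ram$A)
  Sigma_all <- B %*% ram$S %*% t(B)
  obs <- spec$observed
  mu <- if (nrow(spec$means)) drop(B %*% ram$M)[obs] else NULL
  list(Sigma = Sigma_all[obs, obs, drop = FALSE], mu = mu,
       Sigma_all = Sigma_all)
}

#' Sample moments for covariance-structure fitting
#'
#' @param data matrix or data frame of observations (columns = variables), or
#'   NULL when `S` is given directly.
#' @param S covariance matrix (used when `data` is NULL).
#' @param means mean vector (optional when `S` given).
#' @param n number of observations.
#' @param divisor `"n-1"` (default) or `"n"` for the covariance denominator.
#' @return object of class `sample_moments` with elements `S`, `means`, `n`,
#'   `divisor`.
#' @export
sample_moments <- function(data = NULL, S = NULL, means = NULL, n = NULL,
                           divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  if (!is.null(data)) {
    data <- as.matrix(data)
    n <- nrow(data)
    S <- stats::cov(data)
    if (divisor == "n") S <- S * (n - 1) / n
    means <- colMeans(data)
  } else {
    if (is.null(S) || is.null(n)) stop("need either data, or S plus n")
    S <- as.matrix(S)
  }
  if (max(abs(S - t(S))) > 1e-12 * max(1, max(abs(S)))) {
    stop("covariance matrix is not symmetric")
  }
  S <- (S + t(S)) / 2
  structure(list(S = S, means = means, n = n, divisor = divisor),
            class = "sample_moments")
}

#' Fit a covariance(+mean) structure model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' \deqn{F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1})
#'       - \log|S| - p + (\bar x - \mu(\theta))'\Sigma(\theta)^{-1}
#'       (\bar x - \mu(\theta))}
#' (the mean term only when the model carries a mean structure) with a
#' quasi-Newton optimizer; equality constraints are absorbed by shared
#' parameter labels.  The chi-square statistic is `multiplier * F_min` with
#' multiplier N-1 (default) or N, degrees of freedom p(p+1)/2 (+p with means)
#' minus the number of free labels.  Standard errors come from the observed
#' information (numerical Hessian of F).
#'
#' @param spec a [model_spec()].
#' @param moments a [sample_moments()]; variable names of `moments$S` must
#'   cover `spec$observed`.
#' @param start optional named start vector (defaults: supplied start values,
#'   else 0 for paths/covariances/means and 1 for variances).
#' @param se compute standard errors (set FALSE to skip the Hessian).
#' @param chisq_multiplier `"n-1"` (conventional SEM software) or `"n"`.
#' @param control list: `rel.tol` (default 1e-10), `iter.max` (1000),
#'   `eval.max` (4000).
#' @return object of class `covfit`: estimates, se, z, p per label; implied
#'   moments; `F_ml`, `chi_square`, `df`, `p_value`, `nfi`; `standardized`
#'   data frame; convergence diagnostics.
#' @export
ml_fit <- function(spec, moments, start = NULL, se = TRUE,
                   chisq_multiplier = c("n-1", "n"), control = list()) {
  stopifnot(inherits(spec, "model_spec"), inherits(moments, "sample_moments"))
  chisq_multiplier <- match.arg(chisq_multiplier)
  obs <- spec$observed
  if (!all(obs %in% colnames(moments$S))) {
    stop("sample moments lack variables: ",
         paste(setdiff(obs, colnames(moments$S)), collapse = ", "))
  }
  S <- moments$S[obs, obs, drop = FALSE]
  p <- length(obs)
  meanstructure <- nrow(spec$means) > 0
  if (meanstructure && is.null(moments$means)) {
    stop("model has a mean structure but sample moments carry no means")
  }
  xbar <- if (meanstructure) moments$means[obs] else NULL

  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    ridge <- 1e-8 * sum(diag(S)) / p
    warning("sample covariance matrix is near-singular; adding ridge ",
            signif(ridge, 3), " to its diagonal")
    S <- S + diag(ridge, p)
  }
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]

  labs <- free_labels(spec)
  th0 <- default_start(spec)
  th0 <- moment_start(spec, th0, S, xbar)
  if (!is.null(start)) th0[names(start)] <- start
  npar <- length(labs)

  objective <- function(theta) {
    names(theta) <- labs
    im <- tryCatch(implied_moments(spec, theta), error = function(e) NULL)
    if (is.null(im)) return(1e10)
    Sg <- im$Sigma
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv_S <- chol2inv(ch) %*% S
    f <- logdet + sum(diag(Sinv_S)) - logdetS - p
    if (meanstructure) {
      d <- xbar - im$mu
      f <- f + drop(crossprod(backsolve(ch, d, transpose = TRUE)))
    }
    if (!is.finite(f)) return(1e10)
    f
  }

  ctl <- utils::modifyList(
    list(rel.tol = 1e-10, iter.max = 1000, eval.max = 4000), control)
  if (npar > 0) {
    opt <- stats::nlminb(th0, objective,
                         control = list(rel.tol = ctl$rel.tol,
                                        iter.max = ctl$iter.max,
                                        eval.max = ctl$eval.max))
    theta <- setNames(opt$par, labs)
    F_ml <- max(opt$objective, 0)
    iterations <- opt$iterations
    gnorm <- function(th) tryCatch(max(abs(pracma::grad(objective, th))),
                                   error = function(e) Inf)
    grad_norm <- gnorm(theta)
    # first-order condition is the convergence criterion; nlminb's own codes
    # flag "false convergence" even at clean optima
    if (grad_norm > 1e-6 * max(1, abs(F_ml)) && F_ml > 1e-12) {
      opt2 <- stats::optim(theta, objective, method = "BFGS",
                           control = list(maxit = ctl$iter.max,
                                          reltol = 1e-14))
      if (opt2$value <= F_ml) {
        theta <- setNames(opt2$par, labs)
        F_ml <- max(opt2$value, 0)
        iterations <- iterations + opt2$counts[1]
        grad_norm <- gnorm(theta)
      }
    }
    converged <- opt$convergence == 0 || F_ml < 1e-10 || grad_norm < 1e-4
    if (!converged) {
      stop("ml_fit did not converge (F = ", signif(F_ml, 6),
           ", max |gradient| = ", signif(grad_norm, 3), " after ",
           iterations, " iterations); try different start values")
    }
  } else {
    theta <- setNames(numeric(0), character(0))
    F_ml <- objective(theta)
    converged <- TRUE; iterations <- 0L; grad_norm <- 0
  }

  mult <- if (chisq_multiplier == "n-1") moments$n - 1 else moments$n
  nmom <- p * (p + 1) / 2 + if (meanstructure) p else 0
  df <- as.integer(nmom - npar)
  if (df < 0) stop("model has more free parameters (", npar,
                   ") than sample moments (", nmom, ")")
  chi_square <- mult * F_ml
  p_value <- if (df > 0) stats::pchisq(chi_square, df, lower.tail = FALSE)
             else NA_real_

  ses <- zs <- ps <- setNames(rep(NA_real_, npar), labs)
  if (se && npar > 0) {
    H <- tryCatch(pracma::hessian(objective, theta), error = function(e) NULL)
    Vc <- if (!is.null(H)) tryCatch(2 / mult * solve(H),
                                    error = function(e) NULL) else NULL
    if (!is.null(Vc)) {
      dg <- diag(Vc)
      ses <- setNames(ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_), labs)
      zs <- theta / ses
      ps <- 2 * stats::pnorm(-abs(zs))
      if (any(dg <= 0)) {
        warning("observed information not positive definite; ",
                "some standard errors unavailable")
      }
    } else {
      warning("Hessian could not be inverted; standard errors unavailable")
    }
    # identification check via information-matrix rank (relative eigenvalue
    # threshold: a flat direction signals an unidentified combination)
    if (!is.null(H)) {
      ev_h <- eigen((H + t(H)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values
      r <- sum(abs(ev_h) > 1e-6 * max(abs(ev_h)))
      if (r < npar) {
        stop("model not identified: information matrix has rank ", r,
             " for ", npar, " free parameters")
      }
    }
  }

  im <- implied_moments(spec, theta)
  neg_var <- negative_variances(spec, theta)
  if (length(neg_var)) {
    warning("negative variance estimate(s): ",
            paste(sprintf("%s=%.4g", names(neg_var), neg_var),
                  collapse = ", "),
            " (reported as estimated, not bounded at zero)")
  }

  # Bentler-Bonett NFI against the independence baseline (free variances and
  # means, zero covariances): F_baseline = -log det of the correlation matrix
  chi_base <- mult * (-determinant(stats::cov2cor(S),
                                   logarithm = TRUE)$modulus[1])
  nfi <- if (chi_base > 0) 1 - chi_square / chi_base else NA_real_

  fit <- structure(
    list(spec = spec, estimates = theta, se = ses, z = zs, p = ps,
         Sigma_hat = im$Sigma, mu_hat = im$mu,
         F_ml = F_ml, chi_square = chi_square, df = df, p_value = p_value,
         nfi = nfi, n = moments$n, chisq_multiplier = chisq_multiplier,
         divisor = moments$divisor, converged = converged,
         iterations = iterations, gradient_norm = grad_norm,
         negative_variances = neg_var),
    class = "covfit")
  fit$standardized <- standardize_estimates(fit)
  fit
}

negative_variances <- function(spec, theta) {
  v <- spec$covariances
  out <- numeric(0)
  for (i in seq_len(nrow(v))) {
    if (v$v1[i] == v$v2[i] && !is.na(v$label[i])) {
      val <- theta[[v$label[i]]]
      if (is.finite(val) && val < 0) out[v$label[i]] <- val
    }
  }
  out
}

#' Standardized estimates of a fitted model
#'
#' Paths are rescaled by sd(source)/sd(target) computed from the model-implied
#' covariance matrix (observed and latent variables alike); covariances are
#' converted to correlations.  Means/intercepts are left unstandardized.
#'
#' @param fit a [ml_fit()] result.
#' @return data frame with columns `label`, `type`, `from`, `to`,
#'   `unstandardized`, `standardized` (one row per model entry that carries a
#'   free label; shared labels appear once per location).
#' @export
standardize_estimates <- function(fit) {
  stopifnot(inherits(fit, "covfit"))
  spec <- fit$spec
  Sall <- implied_moments(spec, fit$estimates)$Sigma_all
  sds <- sqrt(pmax(diag(Sall), 0))
  if (any(sds == 0)) {
    zv <- colnames(Sall)[sds == 0]
    stop("zero implied variance for: ", paste(zv, collapse = ", "))
  }
  rows <- list()
  p <- spec$paths
  for (i in seq_len(nrow(p))) {
    if (is.na(p$label[i])) next
    est <- fit$estimates[[p$label[i]]]
    rows[[length(rows) + 1]] <- data.frame(
      label = p$label[i], type = "path", from = p$from[i], to = p$to[i],
      unstandardized = est,
      standardized = est * sds[p$from[i]] / sds[p$to[i]])
  }
  v <- spec$covariances
  for (i in seq_len(nrow(v))) {
    if (is.na(v$label[i])) next
    est <- fit$estimates[[v$label[i]]]
    std <- if (v$v1[i] == v$v2[i]) est / (sds[v$v1[i]]^2)
           else est / (sds[v$v1[i]] * sds[v$v2[i]])
    rows[[length(rows) + 1]] <- data.frame(
      label = v$label[i],
      type = if (v$v1[i] == v$v2[i]) "variance" else "covariance",
      from = v$v1[i], to = v$v2[i],
      unstandardized = est, standardized = std)
  }
  m <- spec$means
  for (i in seq_len(nrow(m))) {
    if (is.na(m$label[i])) next
    est <- fit$estimates[[m$label[i]]]
    rows[[length(rows) + 1]] <- data.frame(
      label = m$label[i], type = "mean", from = m$var[i], to = m$var[i],
      unstandardized = est, standardized = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio comparison of nested fits
#'
#' @param restricted,general [ml_fit()] results on the same observed
#'   variables; the restricted model must be nested in the general one (its
#'   constraints are a superset).
#' @return list with `delta_chi`, `delta_df`, `p_value`, and `identical`
#'   (TRUE when the two fits have the same df, in which case the p-value is
#'   undefined).
#' @export
likelihood_ratio <- function(restricted, general) {
  stopifnot(inherits(restricted, "covfit"), inherits(general, "covfit"))
  if (!setequal(restricted$spec$observed, general$spec$observed)) {
    stop("fits are not nested: different observed variables")
  }
  delta_df <- restricted$df - general$df
  if (delta_df < 0) {
    stop("fits are not nested: the restricted model has fewer df")
  }
  delta_chi <- restricted$chi_square - general$chi_square
  if (delta_chi < -1e-6) {
    stop("restricted chi-square is smaller than the general one; ",
         "the models are not nested (or a fit failed to converge)")
  }
  delta_chi <- max(delta_chi, 0)
  list(delta_chi = delta_chi, delta_df = delta_df,
       p_value = if (delta_df > 0)
         stats::pchisq(delta_chi, delta_df, lower.tail = FALSE)
       else NA_real_,
       identical = delta_df == 0)
}

#' @export
print.covfit <- function(x, ...) {
  cat("ML covariance-structure fit:", length(x$estimates),
      "free parameter(s)\n")
  cat(sprintf("  chi-square = %.4f on %d df%s | N = %d (multiplier %s, cov divisor %s)\n",
              x$chi_square, x$df,
              if (x$df > 0) sprintf(" (p = %.4f)", x$p_value) else "",
              x$n, x$chisq_multiplier, x$divisor))
  if (length(x$estimates)) {
    tab <- data.frame(estimate = x$estimates, se = x$se, z = x$z, p = x$p)
    print(round(tab, 4))
  }
  invisible(x)
}

#' Serialize a model spec to YAML
#'
#' @param spec a [model_spec()].
#' @param path file path; when NULL the YAML string is returned.
#' @return `path` invisibly, or the YAML string.
#' @export
spec_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  obj <- list(observed = spec$observed, latent = spec$latent,
              paths = df_to_list(spec$paths),
              covariances = df_to_list(spec$covariances),
              means = df_to_list(spec$means))
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a model spec from YAML
#'
#' @param path file path (or a YAML string produced by [spec_to_yaml()]).
#' @return a [model_spec()].
#' @export
spec_from_yaml <- function(path) {
  obj <- if (file.exists(path)) yaml::read_yaml(path)
         else yaml::yaml.load(path)
  mkdf <- function(lst) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lapply(lst, function(e) {
      as.data.frame(lapply(e, function(x) if (is.null(x)) NA else x))
    }))
  }
  model_spec(observed = unlist(obj$observed),
             latent = unlist(obj$latent) %||% character(),
             paths = mkdf(obj$paths),
             covariances = mkdf(obj$covariances),
             means = mkdf(obj$means))
}

df_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    row[!vapply(row, function(x) is.na(x) || is.null(x), TRUE)]
  })
}
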