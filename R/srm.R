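#' Marginal means of a dyadic table
#'
#' Row (actor) means, column (partner) means, and the grand mean, computed
#' over the defined cells only: for a round robin the n^2 - n off-diagonal
#' cells, for a block all r x c cells.
#'
#' @param table an [round_robin_table()] or [block_table()].
#' @return list with `n` (or `r`, `c`), `row_means`, `col_means`, `grand_mean`.
#' @export
compute_marginals <- function(table) {
  UseMethod("compute_marginals")
}

#' @export
compute_marginals.rr_table <- function(table) {
  v <- table$values
  list(n = nrow(v),
       row_means = rowMeans(v, na.rm = TRUE),
       col_means = colMeans(v, na.rm = TRUE),
       grand_mean = mean(v, na.rm = TRUE))
}

#' @export
compute_marginals.block_table <- function(table) {
  v <- table$values
  list(r = nrow(v), c = ncol(v),
       row_means = rowMeans(v),
       col_means = colMeans(v),
       grand_mean = mean(v))
}

new_srm_effects <- function(group_id, variable, kind, design, mu,
                            actor, partner, relationship) {
  structure(
    list(group_id = group_id, variable = variable, kind = kind,
         design = design, mu = mu, actor = actor, partner = partner,
         relationship = relationship),
    class = "srm_effects")
}

#' Round-robin SRM decomposition
#'
#' Decomposes an n x n round robin with missing diagonal into the group mean,
#' actor effects, partner effects, and relationship effects by the
#' least-squares closed forms.  With row marginal means `M_i.`, column
#' marginal means `M_.j`, and grand mean `M..` over the n^2 - n defined cells,
#'
#' \deqn{\alpha_i = \frac{(n-1)^2}{n(n-2)} M_{i.} + \frac{n-1}{n(n-2)} M_{.i}
#'       - \frac{n-1}{n-2} M_{..}}
#' \deqn{\beta_j  = \frac{(n-1)^2}{n(n-2)} M_{.j} + \frac{n-1}{n(n-2)} M_{j.}
#'       - \frac{n-1}{n-2} M_{..}}
#' \deqn{\gamma_{ij} = X_{ij} - \alpha_i - \beta_j - M_{..}}
#'
#' Actor and partner effects each sum to zero, the relationship residuals have
#' zero row and column sums over defined cells, and
#' \eqn{\mu + \alpha_i + \beta_j + \gamma_{ij}} reproduces every defined cell
#' exactly.  With a single indicator the relationship effect absorbs the
#' measurement error (they are confounded without multiple indicators).
#'
#' @param table an [round_robin_table()].
#' @param tol absolute tolerance used by the internal zero-sum sanity checks.
#' @return an object of class `srm_effects` with elements `mu`, `actor`,
#'   `partner` (named numeric vectors) and `relationship` (matrix, NA
#'   diagonal).
#' @export
decompose_round_robin <- function(table, tol = 1e-9) {
  stopifnot(inherits(table, "rr_table"))
  v <- table$values
  n <- nrow(v)
  m <- compute_marginals(table)
  w1 <- (n - 1)^2 / (n^2 - 2 * n)
  w2 <- (n - 1)   / (n^2 - 2 * n)
  w3 <- (n - 1)   / (n - 2)
  alpha <- w1 * m$row_means + w2 * m$col_means - w3 * m$grand_mean
  beta  <- w1 * m$col_means + w2 * m$row_means - w3 * m$grand_mean
  gamma <- v - outer(alpha, rep(1, n)) - outer(rep(1, n), beta) - m$grand_mean
  diag(gamma) <- NA_real_
  if (abs(sum(alpha)) > tol * n || abs(sum(beta)) > tol * n) {
    stop("internal error: actor/partner effects do not sum to zero")
  }
  new_srm_effects(table$group_id, table$variable, table$kind, "round_robin",
                  m$grand_mean, alpha, beta, gamma)
}

#' Block SRM decomposition
#'
#' Within one block the grand mean is the average of all r x c cells, the
#' actor effect is the row mean minus the grand mean, the partner effect is
#' the column mean minus the grand mean, and the relationship effect is the
#' residual \eqn{\gamma_{ij} = Y_{ij} - \alpha_i - \beta_j - M_{..}}.  The
#' same arithmetic applies to responses and to (half-block) metaperceptions.
#'
#' @param table a [block_table()].
#' @return an `srm_effects` object; `actor` is named by the row members and
#'   `partner` by the column members.
#' @export
decompose_block <- function(table) {
  stopifnot(inherits(table, "block_table"))
  m <- compute_marginals(table)
  alpha <- m$row_means - m$grand_mean
  beta  <- m$col_means - m$grand_mean
  gamma <- sweep(sweep(table$values, 1, alpha), 2, beta) - m$grand_mean
  new_srm_effects(table$group_id, table$variable, table$kind, table$design,
                  m$grand_mean, alpha, beta, gamma)
}

#' Average SRM effects across indicators of one construct
#'
#' Indicators of a latent construct are averaged cell-wise: the composite
#' group mean, actor, partner, and relationship effects are the arithmetic
#' means of the per-indicator effects.  All inputs must come from the same
#' group and design and share the same person sets.
#'
#' @param effects list of `srm_effects` (one per indicator).
#' @param variable label for the composite (default concatenates the inputs).
#' @return a single `srm_effects` object flagged as a composite.
#' @export
composite_effects <- function(effects, variable = NULL) {
  if (inherits(effects, "srm_effects")) effects <- list(effects)
  stopifnot(length(effects) >= 1,
            all(vapply(effects, inherits, TRUE, "srm_effects")))
  ref <- effects[[1]]
  for (e in effects[-1]) {
    if (!identical(names(e$actor), names(ref$actor)) ||
        !identical(names(e$partner), names(ref$partner))) {
      stop("indicator member sets differ: [",
           paste(names(e$actor), collapse = ","), "] vs [",
           paste(names(ref$actor), collapse = ","), "]")
    }
    if (!identical(e$design, ref$design) ||
        !identical(e$group_id, ref$group_id)) {
      stop("indicators must share group and design")
    }
  }
  avg <- function(get) Reduce(`+`, lapply(effects, get)) / length(effects)
  out <- new_srm_effects(
    ref$group_id,
    variable %||% paste(vapply(effects, function(e) e$variable, ""),
                        collapse = "+"),
    ref$kind, ref$design,
    mu = avg(function(e) e$mu),
    actor = avg(function(e) e$actor),
    partner = avg(function(e) e$partner),
    relationship = avg(function(e) e$relationship))
  out$composite <- length(effects) > 1
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.srm_effects <- function(x, ...) {
  cat("SRM effects: group", x$group_id, "| variable", x$variable, "|",
      x$design, "\n  mu =", signif(x$mu, 4), "\n")
  cat("  actor:  ", paste(sprintf("%s=%.3f", names(x$actor), x$actor),
                          collapse = " "), "\n")
  cat("  partner:", paste(sprintf("%s=%.3f", names(x$partner), x$partner),
                          collapse = " "), "\n")
  invisible(x)
}

#' Person-level effects as a data frame
#'
#' @param x an `srm_effects` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with group_id, person_id, variable, actor_effect,
#'   partner_effect (persons missing a role in block designs get NA).
#' @export
as.data.frame.srm_effects <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  persons <- union(names(x$actor), names(x$partner))
  data.frame(group_id = x$group_id, person_id = persons,
             variable = x$variable,
             actor_effect = unname(x$actor[persons]),
             partner_effect = unname(x$partner[persons]),
             stringsAsFactors = FALSE)
}

#' Directed-pair relationship effects as a data frame
#'
#' @param x an `srm_effects` object.
#' @return data frame with group_id, actor_id, partner_id, variable,
#'   relationship_effect; one row per defined cell.
#' @export
relationship_df <- function(x) {
  stopifnot(inherits(x, "srm_effects"))
  g <- x$relationship
  idx <- which(!is.na(g), arr.ind = TRUE)
  data.frame(group_id = x$group_id,
             actor_id = rownames(g)[idx[, 1]],
             partner_id = colnames(g)[idx[, 2]],
             variable = x$variable,
             relationship_effect = g[idx],
             stringsAsFactors = FALSE)
}
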