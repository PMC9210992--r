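## CSV dialect: UTF-8, comma-separated, "." decimal, empty string for
## undefined cells.  Identifiers are opaque strings (never coerced to
## numbers).

#' Read dyadic data from CSV
#'
#' Wide format: one matrix per file, first column the actor id, header the
#' partner ids, empty string on the (round-robin) diagonal; the file naming
#' convention is `{group}_{variable}.csv`.  Long format: one file with
#' columns `group_id, actor_id, partner_id, variable, kind, value`, split
#' into one table per (group, variable, kind).
#'
#' A numeric round-robin diagonal cell is rejected (self-ratings are not
#' collected); a long-format row with `actor_id == partner_id` is a
#' self-rating and is dropped with a notice.
#'
#' @param path one or more file paths (wide: one table per file).
#' @param format `"wide"` or `"long"`.
#' @param design `"round_robin"`, `"asymmetric_block"`, or `"half_block"`.
#' @param kind `"response"` or `"metaperception"` (wide format only; long
#'   files carry a kind column).
#' @param group_id,variable overrides for wide files (default: parsed from
#'   the file name as `{group}_{variable}.csv`).
#' @param ... passed to [round_robin_table()] (e.g. `min_group_size`).
#' @return list of [round_robin_table()] / [block_table()] objects.
#' @export
read_dyadic_data <- function(path,
                             format = c("wide", "long"),
                             design = c("round_robin", "asymmetric_block",
                                        "half_block"),
                             kind = c("response", "metaperception"),
                             group_id = NULL, variable = NULL, ...) {
  format <- match.arg(format)
  design <- match.arg(design)
  kind <- match.arg(kind)
  if (format == "wide") {
    out <- lapply(path, read_wide_file, design = design, kind = kind,
                  group_id = group_id, variable = variable, ...)
    return(out)
  }
  read_long_file(path, design = design, ...)
}

read_wide_file <- function(file, design, kind, group_id = NULL,
                           variable = NULL, ...) {
  if (!file.exists(file)) stop("file not found: ", file)
  raw <- utils::read.csv(file, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  actors <- raw[[1]]
  partners <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals),
                                 dimnames = list(actors, partners)))
  bad <- vals != "" & !is.na(vals) & is.na(num)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("file ", file, ": non-numeric value at actor=", actors[w[1]],
         " partner=", partners[w[2]])
  }
  stem <- sub("\\.csv$", "", basename(file))
  if (is.null(group_id)) group_id <- sub("_.*$", "", stem)
  if (is.null(variable)) variable <- sub("^[^_]*_", "", stem)
  if (design == "round_robin") {
    if (!identical(sort(actors), sort(partners))) {
      stop("file ", file, ": round-robin actor and partner ids differ")
    }
    num <- num[, actors, drop = FALSE]   # align column order to rows
    dg <- vals[cbind(seq_along(actors), match(actors, partners))]
    if (any(dg != "" & !is.na(dg))) {
      i <- which(dg != "")[1]
      stop("file ", file, ": diagonal cell (", actors[i], ",", actors[i],
           ") must be empty; self-ratings are not collected")
    }
    round_robin_table(num, members = actors, group_id = group_id,
                      variable = variable, kind = kind, ...)
  } else {
    block_table(num, row_members = actors, col_members = partners,
                group_id = group_id, variable = variable, kind = kind,
                design = design)
  }
}

read_long_file <- function(file, design, ...) {
  if (!file.exists(file)) stop("file not found: ", file)
  d <- utils::read.csv(file, colClasses = "character",
                       fileEncoding = "UTF-8")
  need <- c("group_id", "actor_id", "partner_id", "variable", "kind",
            "value")
  if (!all(need %in% names(d))) {
    stop("long file ", file, " must have columns: ",
         paste(need, collapse = ", "))
  }
  selfr <- d$actor_id == d$partner_id
  if (any(selfr)) {
    message(sum(selfr), " self-rating row(s) ignored in ", file)
    d <- d[!selfr, ]
  }
  keys <- d[, c("group_id", "actor_id", "partner_id", "variable", "kind")]
  if (anyDuplicated(keys)) {
    i <- which(duplicated(keys))[1]
    stop("long file ", file, ": duplicate row for group=", d$group_id[i],
         " actor=", d$actor_id[i], " partner=", d$partner_id[i],
         " variable=", d$variable[i])
  }
  d$value <- as.numeric(d$value)
  split_keys <- interaction(d$group_id, d$variable, d$kind, drop = TRUE)
  lapply(split(d, split_keys), function(s) {
    if (design == "round_robin") {
      members <- sort(unique(c(s$actor_id, s$partner_id)))
      v <- matrix(NA_real_, length(members), length(members),
                  dimnames = list(members, members))
      v[cbind(match(s$actor_id, members), match(s$partner_id, members))] <-
        s$value
      round_robin_table(v, members = members, group_id = s$group_id[1],
                        variable = s$variable[1], kind = s$kind[1], ...)
    } else {
      rows <- sort(unique(s$actor_id)); cols <- sort(unique(s$partner_id))
      v <- matrix(NA_real_, length(rows), length(cols),
                  dimnames = list(rows, cols))
      v[cbind(match(s$actor_id, rows), match(s$partner_id, cols))] <- s$value
      block_table(v, row_members = rows, col_members = cols,
                  group_id = s$group_id[1], variable = s$variable[1],
                  kind = s$kind[1], design = design)
    }
  })
}

#' Write tables to wide CSV files
#'
#' @param tables list of `rr_table`/`block_table` objects (or a single one).
#' @param dir output directory (created if needed); one file per table named
#'   `{group}_{variable}.csv`, empty diagonal for round robins.
#' @return the file paths, invisibly.
#' @export
write_wide_csv <- function(tables, dir) {
  if (inherits(tables, c("rr_table", "block_table"))) tables <- list(tables)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(tables, function(tb) {
    f <- file.path(dir, paste0(tb$group_id, "_", tb$variable, ".csv"))
    v <- tb$values
    ch <- matrix(formatC(v, format = "g", digits = 15), nrow(v))
    ch[is.na(v)] <- ""
    df <- data.frame(actor = rownames(v), ch, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("actor", colnames(v))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    f
  }, "")
  invisible(paths)
}

#' Write tables to one long CSV file
#'
#' @param tables list of table objects (round robin or block).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(tables, path) {
  if (inherits(tables, c("rr_table", "block_table"))) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    v <- tb$values
    idx <- which(!is.na(v), arr.ind = TRUE)
    data.frame(group_id = tb$group_id,
               actor_id = rownames(v)[idx[, 1]],
               partner_id = colnames(v)[idx[, 2]],
               variable = tb$variable, kind = tb$kind,
               value = v[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write SRM effects to CSV
#'
#' @param effects list of `srm_effects` (or one).
#' @param person_path CSV for person-level effects (group_id, person_id,
#'   variable, actor_effect, partner_effect).
#' @param pair_path CSV for directed-pair relationship effects (group_id,
#'   actor_id, partner_id, variable, relationship_effect).
#' @return invisibly, a list with the two paths.
#' @export
write_effects_csv <- function(effects, person_path, pair_path) {
  effects <- as_effects_list(effects)
  person <- do.call(rbind, lapply(effects, as.data.frame))
  pair <- do.call(rbind, lapply(effects, relationship_df))
  utils::write.csv(person, person_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(pair, pair_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(list(person = person_path, pair = pair_path))
}

#' Read/write dyad-format CSV
#'
#' Columns: `group_id, i, j, gamma_ij, gamma_ji, gamma_mp_ij, gamma_mp_ji`
#' (the last may be empty for unidirectional metaperceptions).  Member
#' designation is canonicalized to `i < j` on read.
#'
#' @param path file path.
#' @return a `dyad_table`.
#' @export
read_dyad_csv <- function(path) {
  need <- c("group_id", "i", "j", "gamma_ij", "gamma_ji", "gamma_mp_ij")
  hdr <- names(utils::read.csv(path, nrows = 0, fileEncoding = "UTF-8"))
  if (!all(need %in% hdr)) {
    stop("dyad CSV must have columns ", paste(need, collapse = ", "))
  }
  d <- utils::read.csv(path, colClasses = c(group_id = "character",
                                            i = "character",
                                            j = "character"),
                       fileEncoding = "UTF-8")
  if (is.null(d$gamma_mp_ji)) d$gamma_mp_ji <- NA_real_
  swap <- d$i > d$j
  if (any(swap)) {
    d[swap, c("i", "j")] <- d[swap, c("j", "i")]
    d[swap, c("gamma_ij", "gamma_ji")] <- d[swap, c("gamma_ji", "gamma_ij")]
    d[swap, c("gamma_mp_ij", "gamma_mp_ji")] <-
      d[swap, c("gamma_mp_ji", "gamma_mp_ij")]
  }
  if (anyDuplicated(d[, c("group_id", "i", "j")])) {
    k <- which(duplicated(d[, c("group_id", "i", "j")]))[1]
    stop("duplicate dyad in ", path, ": group=", d$group_id[k], " (",
         d$i[k], ",", d$j[k], ")")
  }
  class(d) <- c("dyad_table", "data.frame")
  d
}

#' @rdname read_dyad_csv
#' @param records a `dyad_table`.
#' @export
write_dyad_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read/write pairwise double-entry CSV
#'
#' Columns: `dyad_id, member_role, self_gamma, partner_gamma,
#' self_mp_gamma, partner_mp_gamma`.
#'
#' @param path file path.
#' @return a `pairwise_table`.
#' @export
read_pairwise_csv <- function(path) {
  need <- c("dyad_id", "member_role", "self_gamma", "partner_gamma",
            "self_mp_gamma", "partner_mp_gamma")
  hdr <- names(utils::read.csv(path, nrows = 0, fileEncoding = "UTF-8"))
  if (!all(need %in% hdr)) {
    stop("pairwise CSV must have columns ", paste(need, collapse = ", "))
  }
  d <- utils::read.csv(path, colClasses = c(dyad_id = "character"),
                       fileEncoding = "UTF-8")
  tab <- table(d$dyad_id)
  if (any(tab != 2)) {
    stop("pairwise CSV: each dyad needs exactly 2 rows; offending dyad(s): ",
         paste(names(tab)[tab != 2], collapse = ", "))
  }
  class(d) <- c("pairwise_table", "data.frame")
  d
}

#' @rdname read_pairwise_csv
#' @param table a `pairwise_table`.
#' @export
write_pairwise_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Reports mirror the conventional Unstandardized / SE / Standardized /
#' Probability layout plus model-level quantities (R-squared, chi-square,
#' df, sample size, divisor and multiplier conventions).
#'
#' @param fit an `arrma_individual_fit`, `arrma_dyadic_fit`,
#'   `full_dyadic_fit`, or `covfit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_report(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

fit_report <- function(fit) {
  if (inherits(fit, "arrma_individual_fit") ||
      inherits(fit, "arrma_dyadic_fit")) {
    level <- if (inherits(fit, "arrma_individual_fit")) "individual"
             else "dyadic_minimal"
    list(
      model = level,
      parameters = list(
        assumed_reciprocity_B = par_entry(fit$b, fit$se[["b"]],
                                          fit$standardized_b, fit$p[["b"]]),
        reciprocity_A = par_entry(fit$a_cov, fit$se[["a_cov"]], fit$a_corr,
                                  fit$p[["a_cov"]]),
        metaperception_accuracy_C = par_entry(fit$c, fit$se[["c"]],
                                              fit$standardized_c,
                                              fit$p[["c"]])),
      r_squared = fit$r_squared, n_obs = fit$n_obs,
      restricted = isTRUE(fit$restricted),
      chi_square = fit$chi_square %||% NA, df = fit$df,
      p_value = fit$p_value %||% NA)
  } else if (inherits(fit, "full_dyadic_fit")) {
    list(
      model = "dyadic_full",
      constrained = fit$constrained, entry = fit$entry,
      parameters = list(
        B = par_entry(fit$B, fit$se[["B"]], NA, NA),
        B_prime = par_entry(fit$B_prime,
                            fit$se[[if ("B_prime" %in% names(fit$se))
                              "B_prime" else "B"]], NA, NA),
        A = par_entry(fit$A, fit$se[["A"]], fit$A_corr, NA),
        C = par_entry(fit$C, fit$se[["C"]], NA, NA),
        C_prime = par_entry(fit$C_prime,
                            fit$se[[if ("C_prime" %in% names(fit$se))
                              "C_prime" else "C"]], NA, NA),
        D = par_entry(fit$D, fit$se[["D"]], fit$D_corr, NA)),
      r_squared_mp = fit$r_squared_mp,
      r_squared_mp_prime = fit$r_squared_mp_prime,
      chi_square = fit$chi_square, df = fit$df,
      adjusted_chi_square = fit$adjusted_chi_square %||% NA,
      adjusted_df = fit$adjusted_df %||% NA,
      n_obs = fit$n_obs)
  } else if (inherits(fit, "covfit")) {
    list(model = "covariance_structure",
         estimates = as.list(fit$estimates),
         se = as.list(fit$se), p = as.list(fit$p),
         standardized = fit$standardized,
         chi_square = fit$chi_square, df = fit$df, p_value = fit$p_value,
         nfi = fit$nfi, n_obs = fit$n,
         chisq_multiplier = fit$chisq_multiplier, divisor = fit$divisor)
  } else stop("unsupported fit object of class ", class(fit)[1])
}

par_entry <- function(u, se, std, p) {
  list(unstandardized = u, se = se, standardized = std, probability = p)
}

#' Read/write a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `path` invisibly / a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
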