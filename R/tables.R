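#' Round-robin table
#'
#' One group's directed measurements: every member rates every other member,
#' the diagonal (self-ratings) is undefined.  The matrix rows are actors, the
#' columns are partners.
#'
#' @param values numeric n x n matrix; off-diagonal cells must be finite, the
#'   diagonal is ignored (it is set to `NA`).  Dimnames, when present, must
#'   agree with `members`.
#' @param members character vector of unique person identifiers (length n).
#'   Defaults to the rownames of `values`, or `"P1"..."Pn"`.
#' @param group_id group identifier (scalar, coerced to character).
#' @param variable measurement label.
#' @param kind `"response"` or `"metaperception"`.
#' @param min_group_size smallest admissible n.  Round-robin estimation needs
#'   at least 4 members; 3 is allowed only with `allow_triads = TRUE`.
#' @param allow_triads allow n = 3 (with a warning); the closed-form weights
#'   remain defined but estimates are very noisy.
#' @return an object of class `rr_table`.
#' @examples
#' x <- matrix(rnorm(16), 4, 4)
#' rr <- round_robin_table(x, group_id = "g1", variable = "liking")
#' @export
round_robin_table <- function(values, members = NULL, group_id = "g1",
                              variable = "y",
                              kind = c("response", "metaperception"),
                              min_group_size = 4, allow_triads = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) {
    stop("round-robin matrix must be square; got ", n, " x ", ncol(values))
  }
  if (is.null(members)) {
    members <- rownames(values)
    if (is.null(members)) members <- paste0("P", seq_len(n))
  }
  members <- as.character(members)
  if (length(members) != n) stop("length(members) must equal nrow(values)")
  if (anyDuplicated(members)) {
    stop("members must be unique within a group: duplicated ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  min_n <- if (allow_triads) 3L else as.integer(min_group_size)
  if (n < min_n) {
    stop("group '", group_id, "' has n = ", n,
         " members; round-robin decomposition requires n >= ", min_n)
  }
  if (allow_triads && n == 3L) {
    warning("n = 3 round robin: effect estimates are admissible but unstable")
  }
  if (any(!is.na(diag(values)))) {
    message("group '", group_id, "': diagonal (self) entries present ",
            "in the input are ignored")
  }
  diag(values) <- NA_real_
  off <- values[row(values) != col(values)]
  if (any(!is.finite(off))) {
    bad <- which(!is.finite(values) & row(values) != col(values),
                 arr.ind = TRUE)[1, ]
    stop("group '", group_id, "', variable '", variable,
         "': missing/non-finite cell actor=", members[bad[1]],
         " partner=", members[bad[2]])
  }
  dimnames(values) <- list(members, members)
  structure(
    list(group_id = as.character(group_id), members = members,
         values = values, variable = variable, kind = kind),
    class = "rr_table")
}

#' Block table (asymmetric block or half block)
#'
#' Measurements between two disjoint categories of persons: rows are actors
#' from category 1, columns are partners from category 2.  An asymmetric block
#' design carries both directions (a second `block_table` with roles swapped);
#' a half block carries one direction only, e.g. in-group metaperceptions of
#' out-group responses.
#'
#' @param values numeric r x c matrix, all cells finite.
#' @param row_members,col_members identifiers for the two categories; no
#'   overlap is allowed.
#' @param group_id group identifier.
#' @param variable measurement label.
#' @param kind `"response"` or `"metaperception"`.
#' @param design `"asymmetric_block"` or `"half_block"`.
#' @return an object of class `block_table`.
#' @export
block_table <- function(values, row_members = NULL, col_members = NULL,
                        group_id = "g1", variable = "y",
                        kind = c("response", "metaperception"),
                        design = c("asymmetric_block", "half_block")) {
  kind <- match.arg(kind)
  design <- match.arg(design)
  values <- as.matrix(values)
  r <- nrow(values); cc <- ncol(values)
  if (r < 2 || cc < 2) stop("block requires at least 2 rows and 2 columns")
  if (is.null(row_members)) {
    row_members <- rownames(values)
    if (is.null(row_members)) row_members <- paste0("R", seq_len(r))
  }
  if (is.null(col_members)) {
    col_members <- colnames(values)
    if (is.null(col_members)) col_members <- paste0("C", seq_len(cc))
  }
  row_members <- as.character(row_members)
  col_members <- as.character(col_members)
  if (length(row_members) != r || length(col_members) != cc) {
    stop("member lists must match matrix dimensions")
  }
  if (anyDuplicated(c(row_members, col_members))) {
    stop("row and column members must be disjoint and unique")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("group '", group_id, "', variable '", variable,
         "': missing/non-finite cell actor=", row_members[bad[1]],
         " partner=", col_members[bad[2]])
  }
  dimnames(values) <- list(row_members, col_members)
  structure(
    list(group_id = as.character(group_id), row_members = row_members,
         col_members = col_members, values = values, variable = variable,
         kind = kind, design = design),
    class = "block_table")
}

#' @export
print.rr_table <- function(x, ...) {
  cat("Round-robin table: group", x$group_id, "| variable", x$variable,
      "|", x$kind, "| n =", length(x$members), "\n")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
print.block_table <- function(x, ...) {
  cat(sub("_", " ", x$design), "table: group", x$group_id, "| variable",
      x$variable, "|", x$kind, "|", nrow(x$values), "x", ncol(x$values), "\n")
  print(round(x$values, 3))
  invisible(x)
}
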