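#' Reproduce the published family-similarity benchmark
#'
#' Runs the full individual and dyadic ARRMA analyses on a local copy of the
#' archived family interpersonal-similarity dataset (25 four-person family
#' round robins; five similarity indicators and five metaperception
#' indicators).  The archive is not bundled with the package; export it to
#' the package's CSV dialects and point `dir` at the directory containing
#' either
#' * `individual_records.csv` (group_id, person_id, alpha_r, beta_r,
#'   alpha_mp: composite SRM components per person) and `dyads.csv`
#'   (dyad-format relationship effects, see [read_dyad_csv()]), or
#' * long-format raw data `responses_long.csv` / `metaperceptions_long.csv`
#'   (see [read_dyadic_data()]), from which the components are computed here.
#'
#' @param dir directory with the exported archive files.
#' @return list with fits: `individual_full`, `individual_restricted`,
#'   `minimal_pairwise`, `full_distinguishable`, `full_indistinguishable`,
#'   `isat`.
#' @export
family_benchmark <- function(dir) {
  ind_file <- file.path(dir, "individual_records.csv")
  dyad_file <- file.path(dir, "dyads.csv")
  if (file.exists(ind_file) && file.exists(dyad_file)) {
    records <- utils::read.csv(ind_file,
                               colClasses = c(group_id = "character",
                                              person_id = "character"))
    dyads <- read_dyad_csv(dyad_file)
  } else {
    resp_file <- file.path(dir, "responses_long.csv")
    mp_file <- file.path(dir, "metaperceptions_long.csv")
    if (!file.exists(resp_file) || !file.exists(mp_file)) {
      stop("no archive export found in ", dir,
           " (need individual_records.csv + dyads.csv, or ",
           "responses_long.csv + metaperceptions_long.csv)")
    }
    resp <- read_dyadic_data(resp_file, format = "long",
                             design = "round_robin")
    mp <- read_dyadic_data(mp_file, format = "long",
                           design = "round_robin")
    by_group <- function(tabs) split(tabs, vapply(tabs,
                                                  function(tb) tb$group_id,
                                                  ""))
    comp <- function(tabs) composite_effects(
      lapply(tabs, decompose_round_robin))
    resp_eff <- lapply(by_group(resp), comp)
    mp_eff <- lapply(by_group(mp), comp)
    records <- build_individual_dataset(resp_eff, mp_eff)
    dyads <- build_dyad_table(resp_eff, mp_eff)
  }
  pw <- to_pairwise(dyads)
  list(individual_full = fit_individual_arrma(records),
       individual_restricted = fit_individual_arrma(records,
                                                    restrict_accuracy = TRUE),
       minimal_pairwise = fit_minimal_dyadic(pw),
       full_distinguishable = fit_full_dyadic_distinguishable(dyads),
       full_indistinguishable = fit_full_dyadic_indistinguishable(pw),
       isat = fit_isat(pw))
}
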