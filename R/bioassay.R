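#' Read a bioassay table from CSV
#'
#' Reads replicated dose-mortality records. The expected header is
#' \code{strain,compound,concentration_ug_cm2,n_treated,n_dead,replicate}
#' (the \code{replicate} column is optional). Concentration 0 encodes the
#' untreated (0.1\% Triton) control.
#'
#' @param path Path to a UTF-8 CSV file with "." as decimal separator.
#' @return A validated \code{data.frame} of bioassay records.
#' @seealso [validate_bioassay()], [fit_probit()]
#' @export
read_bioassay <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_bioassay(df)
}

#' Validate a bioassay record table
#'
#' Checks column presence, types and the record invariants:
#' \code{0 <= n_dead <= n_treated}, \code{n_treated >= 1} and finite
#' non-negative concentrations. Violations raise an error naming the
#' offending rows.
#'
#' @param df A data.frame of bioassay records.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_bioassay <- function(df) {
  required <- c("strain", "compound", "concentration_ug_cm2",
                "n_treated", "n_dead")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("bioassay table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  conc <- df$concentration_ug_cm2
  bad <- which(!is.finite(conc) | conc < 0)
  if (length(bad) > 0L) {
    stop("non-finite or negative concentration in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$n_treated < 1 | df$n_dead < 0 | df$n_dead > df$n_treated)
  if (length(bad) > 0L) {
    stop("invalid counts (need 0 <= n_dead <= n_treated, n_treated >= 1) ",
         "in row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Abbott's correction for control mortality
#'
#' Adjusts an observed mortality proportion for natural (control) mortality:
#' \eqn{(p_{obs} - p_c) / (1 - p_c)}, clipped below at 0. Off by default
#' throughout the package because reference bioassays conventionally report
#' uncorrected control mortality.
#'
#' @param observed_mortality Observed mortality proportion(s) in \[0, 1\].
#' @param control_mortality Control mortality proportion in \[0, 1).
#' @return Corrected mortality proportion(s).
#' @examples
#' abbott_correct(0.5, 0)      # identity at zero control mortality
#' abbott_correct(0.3, 0.1)    # 0.2222
#' @export
abbott_correct <- function(observed_mortality, control_mortality) {
  stopifnot(all(observed_mortality >= 0 & observed_mortality <= 1),
            all(control_mortality >= 0 & control_mortality <= 1))
  if (any(control_mortality >= 1)) {
    stop("control mortality of 1 leaves the correction undefined",
         call. = FALSE)
  }
  pmax((observed_mortality - control_mortality) / (1 - control_mortality), 0)
}

#' Summarise discriminating-dose mortality per population
#'
#' Pools dead/treated counts at a single diagnostic concentration (the
#' susceptible LC99 in routine monitoring) within each population and
#' reports percent mortality, optionally Abbott-corrected by each
#' population's own control rows (concentration 0).
#'
#' @param records A bioassay-style data.frame with a \code{population}
#'   column plus \code{concentration_ug_cm2}, \code{n_treated},
#'   \code{n_dead}, and optionally \code{season}.
#' @param diagnostic_concentration The discriminating concentration in
#'   micrograms a.i. per square centimetre.
#' @param abbott Apply Abbott's correction using each population's control
#'   rows? Default \code{FALSE}.
#' @return A data.frame with one row per population: \code{population},
#'   \code{season} (if present), \code{n_treated}, \code{n_dead},
#'   \code{mortality_pct}.
#' @examples
#' rec <- data.frame(population = "P1", concentration_ug_cm2 = 0.41,
#'                   n_treated = 512, n_dead = 240)
#' summarize_discriminating_dose(rec, 0.41)$mortality_pct  # 46.875
#' @export
summarize_discriminating_dose <- function(records, diagnostic_concentration,
                                          abbott = FALSE) {
  if (!"population" %in% names(records)) {
    stop("records need a 'population' column", call. = FALSE)
  }
  pops <- unique(records$population)
  at_dose <- records$concentration_ug_cm2 == diagnostic_concentration
  missing_pops <- setdiff(pops, unique(records$population[at_dose]))
  if (length(missing_pops) > 0L) {
    stop("no records at the diagnostic concentration for population(s): ",
         paste(missing_pops, collapse = ", "), call. = FALSE)
  }
  has_season <- "season" %in% names(records)
  rows <- lapply(pops, function(p) {
    sub <- records[records$population == p & at_dose, , drop = FALSE]
    n <- sum(sub$n_treated)
    d <- sum(sub$n_dead)
    mort <- d / n
    if (abbott) {
      ctrl <- records[records$population == p &
                        records$concentration_ug_cm2 == 0, , drop = FALSE]
      if (nrow(ctrl) > 0L) {
        mort <- abbott_correct(mort, sum(ctrl$n_dead) / sum(ctrl$n_treated))
      }
    }
    data.frame(population = p,
               season = if (has_season) sub$season[1L] else NA_character_,
               n_treated = n, n_dead = d,
               mortality_pct = 100 * mort,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!has_season) out$season <- NULL
  out
}

#' Season-level summary of discriminating-dose mortality
#'
#' @param summary_df Output of [summarize_discriminating_dose()] with a
#'   \code{season} column.
#' @return A data.frame with one row per season: minimum, maximum and mean
#'   population mortality percentages and the number of populations.
#' @export
season_mortality_summary <- function(summary_df) {
  if (!"season" %in% names(summary_df)) {
    stop("summary has no 'season' column", call. = FALSE)
  }
  seasons <- unique(summary_df$season)
  do.call(rbind, lapply(seasons, function(s) {
    m <- summary_df$mortality_pct[summary_df$season == s]
    data.frame(season = s, n_populations = length(m),
               min_mortality_pct = min(m), max_mortality_pct = max(m),
               mean_mortality_pct = mean(m), stringsAsFactors = FALSE)
  }))
}
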