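# Demographic / clinical descriptive summary of the target cohort, in the
# layout conventional for spontaneous-report studies: counts with
# percentages of the total report number.

#' Round half-up
#'
#' Base `round()` rounds half to even; descriptive percentages here follow
#' the half-up convention, which is what published count/percent pairs use.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  # epsilon absorbs binary representation error in decimals like 2.675
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

.occupation_labels <- c(MD = "Physician", PH = "Pharmacist", CN = "Consumer",
                        HP = "Other health-professional", LW = "Lawyer",
                        RN = "Nurse", OT = "Other")

.outcome_labels <- c(
  DE = "Death", LT = "Life-Threatening",
  HO = "Hospitalization - Initial or Prolonged", DS = "Disability",
  CA = "Congenital Anomaly",
  RI = "Required Intervention to Prevent Permanent Impairment",
  OT = "Other serious medical events", unknown = "Unknown code"
)

#' Age bands used in the demographic summary
#' @param age_years Numeric vector of ages in years (NA allowed).
#' @return Factor with levels `<18`, `18-<45`, `45-<65`, `>=65`, `Unknown`.
#' @export
age_band <- function(age_years) {
  lv <- c("<18", "18-<45", "45-<65", ">=65", "Unknown")
  out <- rep("Unknown", length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 18] <- "<18"
  out[ok & age_years >= 18 & age_years < 45] <- "18-<45"
  out[ok & age_years >= 45 & age_years < 65] <- "45-<65"
  out[ok & age_years >= 65] <- ">=65"
  factor(out, levels = lv)
}

.count_section <- function(section, values, total, levels = NULL,
                           top_k = NULL) {
  if (is.null(levels)) {
    tab <- sort(table(values), decreasing = TRUE)
    if (!is.null(top_k)) {
      # top-k by count, ties broken alphabetically
      ord <- order(-as.integer(tab), names(tab))
      tab <- tab[ord][seq_len(min(top_k, length(tab)))]
    }
  } else {
    tab <- table(factor(values, levels = levels))
  }
  data.table::data.table(
    section = section,
    category = names(tab),
    n = as.integer(tab),
    pct = round_half_up(100 * as.integer(tab) / total, 2)
  )
}

#' Demographic and clinical summary of the target cohort
#'
#' One row per category with count and percentage of the *total* number of
#' reports (not the non-missing subtotal — the convention that makes the
#' single-assignment sections sum to 100%). Sections: sex, age band, top-k
#' indications, seriousness, serious outcome codes (reports may carry
#' several, so this section can exceed 100%), reporting year, top-k reporter
#' countries, reporter occupation, and time-to-onset day bins.
#'
#' @param cohort A `faers_cohort`; only target-exposed rows are summarized.
#' @param top_k How many indications/countries to list (ties alphabetical).
#' @return data.table with `section`, `category`, `n`, `pct`; the total
#'   report count is in `attr(, "total_reports")`.
#' @export
summarize_cohort <- function(cohort, top_k = 5) {
  tg <- cohort[is_target_ps == TRUE]
  total <- nrow(tg)
  if (total == 0L) stop("cohort has no target-exposed reports")

  sex <- ifelse(toupper(tg$sex) == "F", "Female",
                ifelse(toupper(tg$sex) == "M", "Male", "Unknown"))
  sex[is.na(sex)] <- "Unknown"

  occ <- toupper(trimws(tg$occp_cod))
  occ_lab <- unname(.occupation_labels[occ])
  occ_lab[is.na(occ_lab) & nzchar(occ) & !is.na(occ)] <- occ[is.na(occ_lab) &
                                                               nzchar(occ) & !is.na(occ)]
  occ_lab[is.na(occ_lab) | !nzchar(occ_lab)] <- "Unknown"

  country <- toupper(trimws(tg$reporter_country))
  country[is.na(country) | !nzchar(country)] <- "Unknown"

  ind_long <- data.table::data.table(
    primaryid = rep(tg$primaryid, lengths(tg$indications)),
    ind = unlist(tg$indications, use.names = FALSE)
  )
  ind_long <- unique(ind_long)

  tally <- outcome_tally(tg)
  outc <- data.table::data.table(
    section = "serious_outcome",
    category = unname(.outcome_labels[names(tally)]),
    n = as.integer(tally),
    pct = round_half_up(100 * as.integer(tally) / total, 2)
  )

  onset <- summarize_tto(compute_onset(tg))
  tto_rows <- data.table::data.table(
    section = "time_to_onset",
    category = onset$bins$label,
    n = onset$bins$n,
    pct = round_half_up(100 * onset$bins$n / total, 2)
  )

  out <- data.table::rbindlist(list(
    .count_section("sex", sex, total,
                   levels = c("Female", "Male", "Unknown")),
    .count_section("age_band", age_band(tg$age_years), total,
                   levels = levels(age_band(numeric(0)))),
    .count_section("indication", ind_long$ind, total, top_k = top_k),
    .count_section("seriousness",
                   ifelse(tg$serious, "Serious", "Non-serious"), total,
                   levels = c("Serious", "Non-serious")),
    outc,
    .count_section("reporting_year", tg$year, total,
                   levels = sort(unique(tg$year))),
    .count_section("reporter_country", country, total, top_k = top_k),
    .count_section("reporter_occupation", occ_lab, total),
    tto_rows
  ))
  attr(out, "total_reports") <- total
  out[]
}
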