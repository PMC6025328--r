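#' Exposure scenarios for soil screening levels
#'
#' Default parameter sets for a resident-farmer screening scenario: a
#' 15 kg child exposed 250 days per year over 25 years through incidental
#' soil ingestion, dermal contact and particulate inhalation.  The
#' noncarcinogenic averaging time is `ed_c * 365` days; the carcinogenic
#' calculation averages over a 70-year lifetime (25,550 days) with
#' age-adjusted intake factors and a target excess lifetime cancer risk of
#' one in a million.
#'
#' @param thq target hazard quotient (unitless).
#' @param bw_c child body weight (kg).
#' @param ed_c exposure duration (years).
#' @param at_n averaging time for noncarcinogens (days).
#' @param ef_r exposure frequency (days/year).
#' @param irs_c soil ingestion rate (mg/day).
#' @param sa dermal surface area (cm2/day).
#' @param af soil adherence factor (mg/cm2).
#' @param ira_c inhalation rate (m3/day).
#' @return named list of scenario parameters.
#' @export
noncarc_scenario <- function(thq = 1, bw_c = 15, ed_c = 25, at_n = ed_c * 365,
                             ef_r = 250, irs_c = 100, sa = 3470, af = 0.12,
                             ira_c = 20) {
  scen <- list(thq = thq, bw_c = bw_c, ed_c = ed_c, at_n = at_n, ef_r = ef_r,
               irs_c = irs_c, sa = sa, af = af, ira_c = ira_c)
  check_scenario(scen, "noncarcinogenic")
  scen
}

#' @rdname noncarc_scenario
#' @param tr target excess lifetime cancer risk (unitless).
#' @param at_c averaging time for carcinogens (days).
#' @param ifs_adj age-adjusted soil ingestion factor.
#' @param sfs_adj age-adjusted dermal factor.
#' @param inhf_adj age-adjusted inhalation factor.
#' @export
carc_scenario <- function(tr = 1e-6, at_c = 25550, ef_r = 250, ifs_adj = 100,
                          sfs_adj = 361, inhf_adj = 11) {
  scen <- list(tr = tr, at_c = at_c, ef_r = ef_r, ifs_adj = ifs_adj,
               sfs_adj = sfs_adj, inhf_adj = inhf_adj)
  check_scenario(scen, "carcinogenic")
  scen
}

check_scenario <- function(scen, label) {
  bad <- names(scen)[!vapply(scen, function(v) is.numeric(v) && length(v) == 1 &&
                               is.finite(v) && v > 0, logical(1))]
  if (length(bad)) {
    stop(sprintf("%s scenario parameters must be single positive numbers: %s",
                 label, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(scen)
}

# per-compound dust/vapour dilution factor (m3/kg)
vf_or_pef <- function(tox) {
  out <- ifelse(isTRUE_vec(tox$volatile), tox$vf_s, tox$pef)
  if (any(!is.finite(out) | out <= 0)) {
    stop("each compound needs a positive volatilization factor or particulate emission factor",
         call. = FALSE)
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Noncarcinogenic soil screening level
#'
#' Risk-based soil concentration at which the target hazard quotient is
#' reached for the combined ingestion + dermal + inhalation pathways:
#'
#' ```
#' SSL = (THQ * BW_c * AT_n) / ( EF_r * ED_c *
#'         [ (1/RfD_o)(IRS_c/1e6) + (1/RfD_o)(SA * AF * ABS / 1e6) +
#'           (1/RfD_i)(IRA_c / VF_or_PEF) ] )
#' ```
#'
#' The dermal route divides by the oral reference dose with no
#' gastrointestinal absorption adjustment.
#'
#' @param tox toxicity tibble with columns `id`, `rfd_o`, `rfd_i`,
#'   `abs_skin`, `vf_s`, `pef`, `volatile` (see [pop_toxicity()]).
#' @param scenario list from [noncarc_scenario()].
#' @return tibble with columns `id`, `ssl_mg_kg`.
#' @examples
#' tox <- tibble::tibble(id = "X", rfd_o = 1e-3, rfd_i = 1e-3,
#'                       abs_skin = 0.1, vf_s = NA, pef = 1.316e9,
#'                       volatile = FALSE)
#' ssl_noncarcinogenic(tox)  # ~154.6 mg/kg
#' @export
ssl_noncarcinogenic <- function(tox, scenario = noncarc_scenario()) {
  check_tox(tox, c("rfd_o", "rfd_i"))
  s <- scenario
  denom <- (1 / tox$rfd_o) * (s$irs_c / 1e6) +
    (1 / tox$rfd_o) * (s$sa * s$af * tox$abs_skin / 1e6) +
    (1 / tox$rfd_i) * (s$ira_c / vf_or_pef(tox))
  tibble::tibble(id = tox$id,
                 ssl_mg_kg = unname((s$thq * s$bw_c * s$at_n) /
                                      (s$ef_r * s$ed_c * denom)))
}

#' Carcinogenic soil screening level
#'
#' Risk-based soil concentration at which the target lifetime excess
#' cancer risk is reached:
#'
#' ```
#' SSL = (TR * AT_c) / ( EF_r *
#'         [ IFS_adj * CSF_o / 1e6 + SFS_adj * ABS * CSF_o / 1e6 +
#'           InhF_adj * CSF_i / VF_or_PEF ] )
#' ```
#'
#' Compounds without cancer slope factors get `NA` (they do not enter a
#' carcinogenic screen).
#'
#' @inheritParams ssl_noncarcinogenic
#' @param scenario list from [carc_scenario()].
#' @return tibble with columns `id`, `ssl_mg_kg` (`NA` where no slope
#'   factor is available).
#' @export
ssl_carcinogenic <- function(tox, scenario = carc_scenario()) {
  check_tox(tox, character())
  s <- scenario
  denom <- s$ifs_adj * tox$csf_o / 1e6 +
    s$sfs_adj * tox$abs_skin * tox$csf_o / 1e6 +
    s$inhf_adj * tox$csf_i / vf_or_pef(tox)
  tibble::tibble(id = tox$id,
                 ssl_mg_kg = unname((s$tr * s$at_c) / (s$ef_r * denom)))
}

check_tox <- function(tox, required_pos) {
  need <- c("id", "abs_skin", "pef", "volatile", "rfd_o", "rfd_i", "csf_o", "csf_i")
  missing <- setdiff(need, names(tox))
  if (length(missing)) {
    stop("toxicity table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in required_pos) {
    v <- tox[[col]]
    if (any(!is.finite(v) | v <= 0)) {
      stop(sprintf("toxicity column `%s` must be positive for every compound (missing reference dose?)",
                   col), call. = FALSE)
    }
  }
  if (any(!is.na(tox$abs_skin) & (tox$abs_skin <= 0 | tox$abs_skin > 1))) {
    stop("`abs_skin` must lie in (0, 1]", call. = FALSE)
  }
  invisible(tox)
}

#' Soil screening levels under a chosen effect basis
#'
#' Computes noncarcinogenic and carcinogenic screening levels for every
#' compound and selects the working SSL: the noncarcinogenic one, the
#' carcinogenic one, or (`"combined"`, the conservative default) the
#' per-compound minimum of the two, falling back to whichever is
#' available.
#'
#' @inheritParams ssl_noncarcinogenic
#' @param basis `"noncarcinogenic"`, `"carcinogenic"` or `"combined"`.
#' @param noncarc,carc the two exposure scenarios.
#' @return tibble `id`, `ssl_noncarc`, `ssl_carc`, `ssl_mg_kg`.
#' @export
soil_screening_levels <- function(tox, basis = c("combined", "noncarcinogenic",
                                                 "carcinogenic"),
                                  noncarc = noncarc_scenario(),
                                  carc = carc_scenario()) {
  basis <- match.arg(basis)
  out <- tibble::tibble(
    id = tox$id,
    ssl_noncarc = ssl_noncarcinogenic(tox, noncarc)$ssl_mg_kg,
    ssl_carc = ssl_carcinogenic(tox, carc)$ssl_mg_kg
  )
  out$ssl_mg_kg <- switch(basis,
    noncarcinogenic = out$ssl_noncarc,
    carcinogenic = out$ssl_carc,
    combined = pmin(out$ssl_noncarc, out$ssl_carc, na.rm = TRUE)
  )
  if (any(!is.finite(out$ssl_mg_kg) | out$ssl_mg_kg <= 0)) {
    bad <- out$id[!is.finite(out$ssl_mg_kg) | out$ssl_mg_kg <= 0]
    stop("no positive screening level under basis `", basis, "` for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Hazard quotient
#'
#' Ratio of the present environmental concentration to the screening
#' level, after converting the concentration from ug/kg to mg/kg; a
#' concentration numerically equal to its SSL (in mg/kg) gives HQ = 1.
#'
#' @param pec_ug_kg concentration(s), ug/kg dry soil.
#' @param ssl_mg_kg screening level(s), mg/kg.
#' @return unitless hazard quotient(s).
#' @export
hazard_quotient <- function(pec_ug_kg, ssl_mg_kg) {
  if (any(!is.finite(ssl_mg_kg) | ssl_mg_kg <= 0)) {
    stop("screening levels must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(pec_ug_kg) | pec_ug_kg < 0)) {
    stop("concentrations must be nonnegative and finite", call. = FALSE)
  }
  (pec_ug_kg / 1000) / ssl_mg_kg
}

#' Hazard index
#'
#' Sum of hazard quotients over compounds (simple additive model, no
#' interaction terms).  An index below 1 means no adverse noncancer
#' effects are expected for the scenario; the returned value carries an
#' `exceeds_benchmark` attribute flagging HI > 1.
#'
#' @param hq nonnegative hazard quotients.
#' @param benchmark acceptability threshold (default 1).
#' @return scalar hazard index with attribute `exceeds_benchmark`.
#' @export
hazard_index <- function(hq, benchmark = 1) {
  if (any(!is.finite(hq) | hq < 0)) {
    stop("hazard quotients must be nonnegative and finite", call. = FALSE)
  }
  hi <- sum(hq)
  attr(hi, "exceeds_benchmark") <- hi > benchmark
  hi
}

#' Relative risk contributions
#'
#' Each compound's share of the hazard index, p_i = HQ_i / HI.  The result
#' is a closed composition (sums to 1), the object all downstream
#' log-ratio analysis works on.  Invariant under rescaling of the hazard
#' quotients.
#'
#' @param hq nonnegative hazard quotients with at least one positive entry.
#' @return numeric vector of shares summing to 1.
#' @export
risk_contributions <- function(hq) {
  if (any(!is.finite(hq) | hq < 0)) {
    stop("hazard quotients must be nonnegative and finite", call. = FALSE)
  }
  hi <- sum(hq)
  if (hi <= 0) {
    stop("hazard index is zero; relative contributions are undefined", call. = FALSE)
  }
  hq / hi
}

#' Site-wise hazard screening
#'
#' Runs the full screen for every site of a survey: per-compound screening
#' levels under the chosen effect basis, hazard quotients, the site hazard
#' index with its benchmark flag, and each compound's relative
#' contribution to the site's index.
#'
#' @param samples long tibble with columns `site_id`, `compound`,
#'   `conc_ug_kg` (and optionally `below_dl`), e.g. from [read_samples()]
#'   after [substitute_half_dl()].
#' @inheritParams soil_screening_levels
#' @return long tibble: `site_id`, `compound`, `conc_ug_kg`, `ssl_mg_kg`,
#'   `hq`, `hi`, `exceeds_benchmark`, `contribution`.
#' @examples
#' svy <- generate_survey(n_sites = 5, seed = 1)
#' evaluate_sites(substitute_half_dl(svy$samples))
#' @export
evaluate_sites <- function(samples, tox = pop_toxicity(),
                           basis = c("combined", "noncarcinogenic", "carcinogenic"),
                           noncarc = noncarc_scenario(), carc = carc_scenario()) {
  basis <- match.arg(basis)
  check_samples(samples)
  missing_tox <- setdiff(unique(samples$compound), tox$id)
  if (length(missing_tox)) {
    stop("no toxicity data for: ", paste(missing_tox, collapse = ", "),
         call. = FALSE)
  }
  ssl <- soil_screening_levels(tox, basis, noncarc, carc)
  samples |>
    dplyr::inner_join(dplyr::select(ssl, "id", "ssl_mg_kg"),
                      by = c(compound = "id")) |>
    dplyr::mutate(hq = hazard_quotient(.data$conc_ug_kg, .data$ssl_mg_kg)) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(
      hi = sum(.data$hq),
      exceeds_benchmark = .data$hi > 1,
      contribution = if (sum(.data$hq) > 0) .data$hq / sum(.data$hq) else NA_real_
    ) |>
    dplyr::ungroup()
}

#' Site-by-compound contribution matrix
#'
#' Pivots the output of [evaluate_sites()] to the wide matrix of relative
#' contributions (rows sum to 1) consumed by the compositional analyses.
#'
#' @param hazard tibble from [evaluate_sites()].
#' @return tibble with `site_id` and one column per compound.
#' @export
contribution_matrix <- function(hazard) {
  if (any(is.na(hazard$contribution))) {
    stop("some sites have zero hazard index; contributions are undefined",
         call. = FALSE)
  }
  tidyr::pivot_wider(
    dplyr::select(hazard, "site_id", "compound", "contribution"),
    names_from = "compound", values_from = "contribution"
  )
}
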