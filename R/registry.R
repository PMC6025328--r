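#' Built-in compound registry and reference survey summary
#'
#' The package ships a registry of 31 persistent organic pollutants
#' routinely screened in floodplain soils — 7 PCB congeners,
#' pentachlorobenzene, hexachlorobenzene, 3 HCH isomers, the 6 DDT-family
#' compounds and 13 PAHs — together with the published per-compound summary
#' statistics of a 100-site survey (concentration minimum / median /
#' maximum / MAD, censoring percentage, median hazard quotient and percent
#' contribution to the median hazard index).  Detection limits are not
#' published for that survey; the registry uses each compound's observed
#' minimum as a detection-limit surrogate, which is an assumption and is
#' marked as such here.
#'
#' @name registry
NULL

# id, name, group, risk_group, carcinogen,
# min, med, max, mad (ug/kg), pct_below_dl, med_hq, pct_hi
reference_rows <- function() {
  tibble::tribble(
    ~id,       ~name,                            ~group, ~risk_group, ~carcinogen, ~min,  ~med,   ~max,    ~mad,   ~pct_below_dl, ~med_hq,   ~pct_hi,
    "PCB28",   "PCB 28",                         "PCB",  "OC",        TRUE,        0.06,  0.10,   1.37,    0.02,   38,            0.0001,    0.05,
    "PCB52",   "PCB 52",                         "PCB",  "OC",        TRUE,        0.05,  0.10,   0.56,    0.00,   58,            0.0001,    0.05,
    "PCB101",  "PCB 101",                        "PCB",  "OC",        TRUE,        0.03,  0.13,   1.18,    0.05,   37,            0.00014,   0.07,
    "PCB118",  "PCB 118",                        "PCB",  "OC",        TRUE,        0.02,  0.10,   0.34,    0.07,   57,            0.0001,    0.05,
    "PCB153",  "PCB 153",                        "PCB",  "OC",        TRUE,        0.08,  0.32,   4.66,    0.25,   6,             0.000318,  0.15,
    "PCB138",  "PCB 138",                        "PCB",  "OC",        TRUE,        0.06,  0.32,   3.36,    0.25,   15,            0.00032,   0.15,
    "PCB180",  "PCB 180",                        "PCB",  "OC",        TRUE,        0.05,  0.28,   4.68,    0.24,   9,             0.00028,   0.13,
    "PeCB",    "Pentachlorobenzene",             "OCP",  "OC",        FALSE,       0.01,  0.12,   1.82,    0.09,   16,            1.79e-7,   0.00,
    "HCB",     "Hexachlorobenzene",              "OCP",  "OC",        TRUE,        0.13,  1.21,   8.66,    0.95,   0,             0.000843,  0.39,
    "aHCH",    "alpha-Hexachlorocyclohexane",    "OCP",  "OC",        TRUE,        0.12,  0.44,   9.52,    0.41,   16,            0.001189,  0.56,
    "bHCH",    "beta-Hexachlorocyclohexane",     "OCP",  "OC",        TRUE,        0.03,  0.10,   11.0,    0.00,   74,            7.69e-5,   0.04,
    "gHCH",    "gamma-Hexachlorocyclohexane",    "OCP",  "OC",        TRUE,        0.10,  0.41,   3.88,    0.19,   15,            0.000164,  0.08,
    "opDDE",   "o,p'-DDE",                       "OCP",  "DDX",       TRUE,        0.01,  0.10,   35.4,    0.02,   41,            1.47e-5,   0.01,
    "ppDDE",   "p,p'-DDE",                       "OCP",  "DDX",       TRUE,        0.34,  3.85,   1923,    4.05,   0,             0.000551,  0.26,
    "opDDD",   "o,p'-DDD",                       "OCP",  "DDX",       TRUE,        0.01,  0.13,   12.3,    0.07,   29,            1.35e-5,   0.01,
    "ppDDD",   "p,p'-DDD",                       "OCP",  "DDX",       TRUE,        0.04,  0.52,   38,      0.52,   8,             5.42e-5,   0.03,
    "opDDT",   "o,p'-DDT",                       "OCP",  "DDX",       TRUE,        0.05,  0.49,   329,     0.55,   9,             5.58e-5,   0.03,
    "ppDDT",   "p,p'-DDT",                       "OCP",  "DDX",       TRUE,        0.12,  4.28,   1082,    4.77,   0,             0.000493,  0.23,
    "N",       "Naphthalene",                    "PAH",  "PAH",       FALSE,       4.38,  10.4,   648,     5.09,   0,             0.000614,  0.29,
    "Ace",     "Acenaphthene",                   "PAH",  "PAH",       FALSE,       0.06,  1.67,   589,     1.39,   1,             3.73e-8,   0.00,
    "Fluor",   "Fluorene",                       "PAH",  "PAH",       FALSE,       0.92,  2.86,   477,     1.74,   0,             9.58e-8,   0.00,
    "Ant",     "Anthracene",                     "PAH",  "PAH",       FALSE,       0.67,  5.27,   791,     5.58,   0,             2.2e-8,    0.00,
    "Fl",      "Fluoranthene",                   "PAH",  "PAH",       FALSE,       10.58, 89.31,  4268,    95.2,   0,             2.95e-6,   0.00,
    "Pyr",     "Pyrene",                         "PAH",  "PAH",       FALSE,       8.31,  71.93,  2966,    75.5,   0,             3.11e-6,   0.00,
    "BaA",     "Benz(a)anthracene",              "PAH",  "PAH",       TRUE,        3.00,  35.84,  16705,   36.4,   0,             0.012255,  5.73,
    "Chr",     "Chrysene",                       "PAH",  "PAH",       TRUE,        4.58,  45.81,  1368,    45.5,   0,             0.000158,  0.07,
    "BbF",     "Benzo(b)fluoranthene",           "PAH",  "PAH",       TRUE,        5.58,  53.30,  1818,    53.7,   0,             0.018431,  8.62,
    "BkF",     "Benzo(k)fluoranthene",           "PAH",  "PAH",       TRUE,        2.08,  23.05,  624,     22.3,   0,             0.000792,  0.37,
    "BaP",     "Benzo(a)pyrene",                 "PAH",  "PAH",       TRUE,        3.62,  44.50,  1475,    43.7,   1,             0.152897,  71.53,
    "Ipyr",    "Indeno(1,2,3-cd)pyrene",         "PAH",  "PAH",       TRUE,        2.77,  33.05,  966,     31.3,   0,             0.011278,  5.28,
    "DBahAnt", "Dibenz(ah)anthracene",           "PAH",  "PAH",       TRUE,        0.10,  3.29,   58.43,   3.37,   1,             0.011179,  5.23
  )
}

#' Compound registry for the 31 built-in analytes
#'
#' @return tibble with one row per compound: `id`, `name`, `group`
#'   (PAH / PCB / OCP), `risk_group` (the three profile families seen in
#'   compositional biplots of these surveys: PAH, DDX = DDT and
#'   metabolites, OC = PCBs, HCHs, PeCB and HCB), `detection_limit`
#'   (ug/kg; the reference survey minimum as a surrogate) and
#'   `carcinogen` flag.
#' @examples
#' pop_compounds()
#' @export
pop_compounds <- function() {
  dplyr::transmute(reference_rows(),
    id = .data$id, name = .data$name, group = .data$group,
    risk_group = .data$risk_group,
    detection_limit = .data$min, carcinogen = .data$carcinogen
  )
}

#' Reference survey summary statistics
#'
#' Per-compound concentration summary (minimum, median, maximum, unscaled
#' median absolute deviation, all ug/kg dry soil), percentage of
#' observations below the detection limit, the median hazard quotient and
#' the percent contribution to the median hazard index, for the 100-site
#' reference floodplain survey.
#'
#' @return tibble with 31 rows and columns `id`, `group`, `risk_group`,
#'   `min`, `med`, `max`, `mad`, `pct_below_dl`, `med_hq`, `pct_hi`.
#' @examples
#' sum(pop_reference_summary()$med_hq)  # hazard index of the median profile
#' @export
pop_reference_summary <- function() {
  dplyr::select(reference_rows(), -"name", -"carcinogen")
}

#' Synthetic toxicity registry calibrated to the reference survey
#'
#' Toxicity parameters (oral/inhalation reference doses, cancer slope
#' factors, skin absorption fraction, particulate emission factor) are not
#' published for the reference survey, so this registry is *synthetic*:
#' reference doses are back-calculated so that each compound's
#' noncarcinogenic soil screening level under the default exposure
#' scenario equals its reference-survey median concentration divided by
#' its reference median hazard quotient.  Feeding the reference median
#' concentrations through [evaluate_sites()] with this registry therefore
#' reproduces the reference median hazard quotients, preserving the
#' compound risk ranking (BaP >> BbF > BaA > ...).  Cancer slope factors of
#' flagged carcinogens are calibrated to the same screening level, so all
#' effect bases agree for this registry.  Skin absorption fractions use
#' standard defaults (0.13 PAH, 0.14 PCB, 0.10 OCP) and the particulate
#' emission factor is the usual 1.316e9 m3/kg.
#'
#' @param noncarc,carc exposure scenarios used for the calibration; see
#'   [noncarc_scenario()] and [carc_scenario()].
#' @return tibble with columns `id`, `rfd_o`, `rfd_i`, `csf_o`, `csf_i`,
#'   `abs_skin`, `vf_s`, `pef`, `volatile`.
#' @export
pop_toxicity <- function(noncarc = noncarc_scenario(), carc = carc_scenario()) {
  ref <- reference_rows()
  abs_skin <- c(PAH = 0.13, PCB = 0.14, OCP = 0.10)[ref$group]
  pef <- 1.316e9
  target_ssl <- (ref$med / 1000) / ref$med_hq   # mg/kg
  k_n <- noncarc$irs_c / 1e6 + noncarc$sa * noncarc$af * abs_skin / 1e6 +
    noncarc$ira_c / pef
  rfd <- target_ssl * noncarc$ef_r * noncarc$ed_c * k_n /
    (noncarc$thq * noncarc$bw_c * noncarc$at_n)
  k_c <- carc$ifs_adj / 1e6 + carc$sfs_adj * abs_skin / 1e6 + carc$inhf_adj / pef
  csf <- ifelse(ref$carcinogen,
                carc$tr * carc$at_c / (carc$ef_r * k_c * target_ssl),
                NA_real_)
  tibble::tibble(
    id = ref$id,
    rfd_o = rfd, rfd_i = rfd,
    csf_o = csf, csf_i = csf,
    abs_skin = unname(abs_skin),
    vf_s = NA_real_, pef = pef,
    volatile = FALSE
  )
}
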