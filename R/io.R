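#' Read a site-by-compound concentration survey
#'
#' The expected layout is one row per site with a `site_id` column and one
#' numeric column per registered compound (ug/kg dry soil).  Two censoring
#' dialects are accepted: cells holding the literal token `"<DL"` mark a
#' value below the detection limit, or a companion logical column
#' `<id>_bdl` per compound can carry the flags.  Censored cells are
#' returned with `below_dl = TRUE` and `conc_ug_kg = NA` until
#' [substitute_half_dl()] imputes them.
#'
#' @param path CSV file.
#' @param registry compound registry tibble (see [pop_compounds()]); every
#'   registered compound must have a column.
#' @return long tibble: `site_id`, `compound`, `conc_ug_kg`, `below_dl`.
#' @export
read_samples <- function(path, registry = pop_compounds()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0 || !"site_id" %in% names(raw)) {
    stop("sample file must have a `site_id` column and at least one row",
         call. = FALSE)
  }
  missing <- setdiff(registry$id, names(raw))
  if (length(missing)) {
    stop("sample file lacks columns for registered compounds: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  flag_cols <- paste0(registry$id, "_bdl")
  has_flags <- all(flag_cols %in% names(raw))

  long <- raw |>
    dplyr::select("site_id", dplyr::all_of(registry$id)) |>
    tidyr::pivot_longer(-"site_id", names_to = "compound", values_to = "raw") |>
    dplyr::mutate(
      below_dl = trimws(.data$raw) == "<DL",
      conc_ug_kg = suppressWarnings(as.numeric(.data$raw))
    )
  if (has_flags) {
    flags <- raw |>
      dplyr::select("site_id", dplyr::all_of(flag_cols)) |>
      tidyr::pivot_longer(-"site_id", names_to = "compound", values_to = "flag") |>
      dplyr::mutate(compound = sub("_bdl$", "", .data$compound),
                    flag = toupper(trimws(.data$flag)) %in% c("TRUE", "T", "1"))
    long <- long |>
      dplyr::left_join(flags, by = c("site_id", "compound")) |>
      dplyr::mutate(below_dl = .data$below_dl | .data$flag) |>
      dplyr::select(-"flag")
  }
  bad <- !long$below_dl & (is.na(long$conc_ug_kg) | long$conc_ug_kg < 0)
  if (any(bad)) {
    stop("non-numeric or negative concentrations at ",
         paste(utils::head(paste(long$site_id[bad], long$compound[bad], sep = "/"), 5),
               collapse = ", "), call. = FALSE)
  }
  long$conc_ug_kg[long$below_dl] <- NA_real_
  dplyr::select(long, "site_id", "compound", "conc_ug_kg", "below_dl")
}

#' Read a compound registry CSV
#'
#' Columns: `id,name,group,detection_limit,carcinogen_flag` (a
#' `risk_group` column is carried through when present).
#'
#' @param path CSV file.
#' @return registry tibble as in [pop_compounds()].
#' @export
read_compound_registry <- function(path) {
  reg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "name", "group", "detection_limit")
  missing <- setdiff(need, names(reg))
  if (length(missing)) {
    stop("registry lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reg$id)) stop("registry ids must be unique", call. = FALSE)
  if (any(!is.na(reg$detection_limit) & reg$detection_limit <= 0)) {
    stop("detection limits must be positive", call. = FALSE)
  }
  if ("carcinogen_flag" %in% names(reg)) {
    reg <- dplyr::rename(reg, carcinogen = "carcinogen_flag")
  }
  tibble::as_tibble(reg)
}

#' Read a toxicity parameter CSV
#'
#' Columns: `id,rfd_o,rfd_i,csf_o,csf_i,abs_skin,vf_s,pef,volatile`
#' (blank cells mean the parameter is absent).
#'
#' @param path CSV file.
#' @return toxicity tibble as in [pop_toxicity()].
#' @export
read_toxicity <- function(path) {
  tox <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"volatile" %in% names(tox)) tox$volatile <- FALSE
  tox$volatile <- isTRUE_vec(tox$volatile)
  check_tox(tox, character())
  tibble::as_tibble(tox)
}

check_samples <- function(samples) {
  need <- c("site_id", "compound", "conc_ug_kg")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    stop("sample table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(samples$conc_ug_kg) & samples$conc_ug_kg < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  invisible(samples)
}

#' Substitute half the detection limit for censored values
#'
#' Every measurement flagged `below_dl` is replaced by half the
#' compound's registered detection limit — the conventional simple
#' substitution for left-censored environmental concentrations before
#' summation and log-ratio analysis.  Unflagged values are untouched, so
#' the operation is idempotent.
#'
#' @param samples long tibble from [read_samples()] or
#'   [generate_survey()].
#' @param registry registry tibble supplying `detection_limit` per
#'   compound id.
#' @return the sample tibble with all concentrations positive.
#' @export
substitute_half_dl <- function(samples, registry = pop_compounds()) {
  check_samples(samples)
  if (!"below_dl" %in% names(samples)) samples$below_dl <- FALSE
  out <- dplyr::left_join(samples,
                          dplyr::select(registry, "id", "detection_limit"),
                          by = c(compound = "id"))
  need_dl <- out$below_dl & (is.na(out$detection_limit) | out$detection_limit <= 0)
  if (any(need_dl)) {
    stop("censored values without a registered detection limit: ",
         paste(unique(out$compound[need_dl]), collapse = ", "), call. = FALSE)
  }
  out$conc_ug_kg[out$below_dl] <- out$detection_limit[out$below_dl] / 2
  if (any(!is.finite(out$conc_ug_kg) | out$conc_ug_kg <= 0)) {
    stop("concentrations must be strictly positive after substitution",
         call. = FALSE)
  }
  dplyr::select(out, -"detection_limit")
}

#' Unscaled median absolute deviation
#'
#' `median(|x - median(x)|)` with no consistency factor; robust spread on
#' the same scale as the data.  Set `scaled = TRUE` for the 1.4826-scaled
#' estimator consistent with a normal standard deviation.
#'
#' @param x numeric vector.
#' @param scaled apply the 1.4826 normal-consistency factor?
#' @return nonnegative scalar.
#' @export
mad_unscaled <- function(x, scaled = FALSE) {
  if (length(x) == 0) stop("empty vector", call. = FALSE)
  stats::mad(x, constant = if (scaled) 1.4826 else 1)
}

#' Per-compound survey summary
#'
#' Minimum, median, maximum and (unscaled) median absolute deviation of
#' the concentrations, plus the percentage of observations below the
#' detection limit — the standard per-analyte summary block of a
#' screening survey report.  Expects positive concentrations, i.e. run
#' [substitute_half_dl()] first when the survey is censored.
#'
#' @param samples long tibble with `compound`, `conc_ug_kg` and
#'   optionally `below_dl`.
#' @param scaled_mad passed to [mad_unscaled()].
#' @return tibble: `compound`, `n`, `min`, `med`, `max`, `mad`,
#'   `pct_below_dl`.
#' @export
summarize_compounds <- function(samples, scaled_mad = FALSE) {
  check_samples(samples)
  if (nrow(samples) == 0) stop("no observations to summarize", call. = FALSE)
  if (!"below_dl" %in% names(samples)) samples$below_dl <- FALSE
  if (any(is.na(samples$conc_ug_kg))) {
    stop("concentrations contain NA; substitute censored values first",
         call. = FALSE)
  }
  samples |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$conc_ug_kg),
      med = stats::median(.data$conc_ug_kg),
      max = max(.data$conc_ug_kg),
      mad = mad_unscaled(.data$conc_ug_kg, scaled_mad),
      pct_below_dl = 100 * mean(.data$below_dl),
      .groups = "drop"
    )
}

#' Write a survey summary CSV
#'
#' Column order mirrors the standard report block: MIN, MED, MAX, MAD,
#' percent below detection limit.
#'
#' @param summary tibble from [summarize_compounds()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  readr::write_csv(summary[, c("compound", "min", "med", "max", "mad", "pct_below_dl")],
                   path, progress = FALSE)
  invisible(path)
}
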