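#' Default pollution archetypes for synthetic surveys
#'
#' Three latent profile families echo what compositional biplots of
#' floodplain risk surveys show: a PAH-dominated profile (benzo(a)pyrene
#' carrying most of the hazard), a DDT-dominated profile (p,p'-DDE /
#' p,p'-DDT led), and a mixed organochlorine profile (PCBs, HCHs, PeCB,
#' HCB).  The PAH archetype mean is the closed reference median-hazard
#' composition; the other two are that composition perturbed by boosting
#' their family's parts and re-closing.  Within-archetype variation is
#' Gaussian in ilr coordinates (logistic-normal on the simplex) with a
#' common per-coordinate standard deviation.  The boosts and spread are
#' fixed design constants chosen so that the archetype means are separated
#' by at least four within-archetype spreads in Aitchison distance; this
#' separation invariant is asserted at construction.
#'
#' @param reference reference summary tibble ([pop_reference_summary()]).
#' @param boost_ddx,boost_oc multiplicative boosts applied to the DDX and
#'   OC family parts.
#' @param sigma per-coordinate ilr standard deviation of within-archetype
#'   variation.
#' @param weights named mixing weights (must sum to 1).
#' @return tibble: `archetype`, `weight`, `sigma`, `mean` (list column of
#'   named mean-contribution vectors).
#' @export
default_archetypes <- function(reference = pop_reference_summary(),
                               boost_ddx = 250, boost_oc = 100, sigma = 0.35,
                               weights = c(PAH = 0.4, DDT = 0.3, OC = 0.3)) {
  if (abs(sum(weights) - 1) > 1e-8) stop("mixing weights must sum to 1", call. = FALSE)
  base <- closure(stats::setNames(reference$med_hq, reference$id))
  boost <- function(fam, f) {
    w <- ifelse(reference$risk_group == fam, f, 1)
    closure(base * w)
  }
  out <- tibble::tibble(
    archetype = c("PAH", "DDT", "OC"),
    weight = unname(weights[c("PAH", "DDT", "OC")]),
    sigma = sigma,
    mean = list(base, boost("DDX", boost_ddx), boost("OC", boost_oc))
  )
  spread <- sigma * sqrt(length(base) - 1)
  dists <- utils::combn(3, 2, function(ij) {
    aitchison_dist(out$mean[[ij[1]]], out$mean[[ij[2]]])
  })
  if (any(dists < 4 * spread)) {
    stop(sprintf("archetype separation %.2f below 4 x within-spread %.2f",
                 min(dists), spread), call. = FALSE)
  }
  out
}

#' Generate a synthetic pollution survey
#'
#' Emulates the statistical structure of a ~100-site floodplain screening
#' survey: each site draws an archetype, a contribution composition by
#' logistic-normal sampling around the archetype mean in ilr coordinates,
#' and a site hazard index from a log-normal whose defaults put the median
#' at 0.214 with about 5% of sites above the HI = 1 benchmark.  Hazard
#' quotients `HQ_i = p_i * HI` are then inverted through the risk model
#' (`PEC_i = HQ_i * SSL_i * 1000` ug/kg) to concentrations, so running
#' [evaluate_sites()] on the uncensored output recovers the generating
#' contributions exactly.  Finally, concentrations below their detection
#' limit are censored: flagged `below_dl` and stored at DL/2.
#'
#' @param n_sites number of sites.
#' @param archetypes tibble from [default_archetypes()].
#' @param tox toxicity registry used for the inversion.
#' @param registry compound registry supplying detection limits.
#' @param hi_meanlog,hi_sdlog log-normal parameters of the site hazard
#'   index.
#' @param basis effect basis for the screening levels used in the
#'   inversion.
#' @param censor apply detection-limit censoring?
#' @param seed integer; identical seeds give identical surveys.
#' @return list with `samples` (long tibble: `site_id`, `compound`,
#'   `conc_ug_kg`, `below_dl`) and `truth` (long tibble: `site_id`,
#'   `archetype`, `hi`, `compound`, `contribution`).
#' @examples
#' svy <- generate_survey(n_sites = 10, seed = 7)
#' dplyr::count(dplyr::distinct(svy$truth, site_id, archetype), archetype)
#' @export
generate_survey <- function(n_sites = 100, archetypes = default_archetypes(),
                            tox = pop_toxicity(), registry = pop_compounds(),
                            hi_meanlog = log(0.214),
                            hi_sdlog = -log(0.214) / stats::qnorm(0.95),
                            basis = "noncarcinogenic",
                            censor = TRUE, seed = 1) {
  if (n_sites < 1) stop("need at least one site", call. = FALSE)
  parts <- names(archetypes$mean[[1]])
  if (!setequal(parts, registry$id) || !setequal(parts, tox$id)) {
    stop("archetype parts, registry and toxicity table must cover the same compounds",
         call. = FALSE)
  }
  ssl <- soil_screening_levels(tox, basis)
  ssl_vec <- stats::setNames(ssl$ssl_mg_kg, ssl$id)[parts]
  dl <- stats::setNames(registry$detection_limit, registry$id)[parts]
  d <- length(parts)
  psi <- ilr_basis(d, parts)

  sim <- with_local_seed(seed, {
    arch_idx <- sample.int(nrow(archetypes), n_sites, replace = TRUE,
                           prob = archetypes$weight)
    mu <- do.call(rbind, lapply(archetypes$mean[arch_idx], ilr, basis = psi))
    z <- mu + matrix(stats::rnorm(n_sites * (d - 1), 0,
                                  archetypes$sigma[arch_idx]),
                     n_sites, d - 1)
    list(arch_idx = arch_idx, p = ilr_inv(z, psi),
         hi = stats::rlnorm(n_sites, hi_meanlog, hi_sdlog))
  })
  site_ids <- sprintf("site_%03d", seq_len(n_sites))
  pec <- sweep(sim$p * sim$hi, 2, ssl_vec * 1000, `*`)
  dimnames(pec) <- list(site_ids, parts)

  samples <- tibble::as_tibble(pec, rownames = "site_id") |>
    tidyr::pivot_longer(-"site_id", names_to = "compound",
                        values_to = "conc_ug_kg") |>
    dplyr::mutate(below_dl = FALSE)
  if (censor) {
    dl_long <- dl[samples$compound]
    hit <- samples$conc_ug_kg < dl_long
    samples$below_dl <- hit
    samples$conc_ug_kg[hit] <- dl_long[hit] / 2
  }
  truth <- tibble::as_tibble(sim$p, .name_repair = ~parts) |>
    dplyr::mutate(site_id = site_ids,
                  archetype = archetypes$archetype[sim$arch_idx],
                  hi = sim$hi, .before = 1) |>
    tidyr::pivot_longer(dplyr::all_of(parts), names_to = "compound",
                        values_to = "contribution")
  list(samples = samples, truth = truth)
}
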