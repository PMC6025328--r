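#' Run the full screening-and-composition pipeline
#'
#' Orchestrates every stage on a survey table: half-DL substitution,
#' per-compound summary, site-wise hazard screening, the closed
#' contribution matrix (row sums asserted at the stage boundary), robust
#' compositional PCA, representative-part selection and ternary
#' coordinates of the centered subcomposition, PCoA on Aitchison
#' distances, fuzzy c-means on ilr coordinates (with a cluster-count scan
#' when `clusters` is a range), and per-cluster compositional profiles on
#' centered data.  All tabular artifacts are written as CSV under
#' `outdir`, plus a machine-readable JSON run report (seed, configuration
#' echo, versions, warnings, per-stage timing).  Sites with hazard index
#' above 1 carry an `exceeds_benchmark` flag in every per-site output.
#' A failure in any stage aborts with a stage-labelled error and removes
#' the partially written outputs.  Runs are deterministic given `seed`.
#'
#' @param samples long sample tibble ([read_samples()] /
#'   [generate_survey()]`$samples`).
#' @param outdir output directory (created if needed).
#' @param registry,tox compound and toxicity registries.
#' @param basis effect basis passed to [evaluate_sites()].
#' @param robust robust (MCD) or classical PCA.
#' @param clusters single cluster count, or an integer range to scan with
#'   [choose_cluster_count()] (the best silhouette then decides).
#' @param fuzzifier fuzzy c-means fuzzifier m.
#' @param noncarc,carc exposure scenarios.
#' @param seed integer seed controlling every stochastic stage.
#' @return invisibly, the run report list (also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(samples, outdir, registry = pop_compounds(),
                         tox = pop_toxicity(),
                         basis = c("combined", "noncarcinogenic", "carcinogenic"),
                         robust = TRUE, clusters = 3, fuzzifier = 2,
                         noncarc = noncarc_scenario(), carc = carc_scenario(),
                         seed = 1) {
  basis <- match.arg(basis)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  warnings_log <- character(0)
  timings <- list()
  emit <- function(tbl, file) {
    path <- file.path(outdir, file)
    readr::write_csv(tbl, path, progress = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        unlink(written)
        stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  samp <- stage("half_dl", substitute_half_dl(samples, registry))
  stage("summary", emit(summarize_compounds(samp), "summary.csv"))
  haz <- stage("risk", evaluate_sites(samp, tox, basis, noncarc, carc))
  stage("risk", emit(haz, "hazard.csv"))
  pmat <- stage("contributions", {
    pm <- contribution_matrix(haz)
    rs <- rowSums(pm[, -1])
    stopifnot(all(abs(rs - 1) < 1e-8))
    emit(pm, "contributions.csv")
    pm
  })
  comp <- as_comp_matrix(pmat)

  site_flags <- dplyr::distinct(haz, .data$site_id, .data$hi, .data$exceeds_benchmark)

  pca <- stage("pca", coda_pca(pmat, robust = robust, seed = seed))
  stage("pca", {
    emit(tibble::as_tibble(pca$loadings_clr, rownames = "part"), "pca_loadings_clr.csv")
    emit(dplyr::left_join(tibble::as_tibble(pca$scores, rownames = "site_id"),
                          site_flags, by = "site_id"), "pca_scores.csv")
    emit(tibble::tibble(component = names(pca$eig), eigenvalue = unname(pca$eig),
                        explained_variance = unname(pca$explained_variance)),
         "pca_explained.csv")
  })

  rep_parts <- stage("subcomposition", {
    sel <- select_representative(pca, dplyr::select(registry, part = "id",
                                                    group = "risk_group"))
    emit(sel, "representative_parts.csv")
    sel$part
  })
  stage("ternary", {
    sub <- subcomposition(comp, rep_parts)
    cen <- center_composition(sub)
    tern <- ternary_coords(cen$centered)
    emit(dplyr::left_join(tern, site_flags, by = "site_id"), "ternary.csv")
  })

  pcoa <- stage("pcoa", coda_pcoa(aitchison_dist(comp)))
  stage("pcoa", {
    emit(dplyr::left_join(
      tibble::as_tibble(pcoa$coordinates[, 1:min(4, ncol(pcoa$coordinates)),
                                         drop = FALSE], rownames = "site_id"),
      site_flags, by = "site_id"), "pcoa_coordinates.csv")
  })

  z <- ilr(comp)
  rownames(z) <- rownames(comp)
  selection <- NULL
  n_clusters <- clusters
  if (length(clusters) > 1) {
    selection <- stage("cluster_scan",
                       choose_cluster_count(z, clusters, m = fuzzifier, seed = seed))
    stage("cluster_scan", emit(selection, "cluster_selection.csv"))
    n_clusters <- selection$c[which.max(selection$avg_silhouette)]
  }
  fcm <- stage("fcm", coda_fcm(z, n_clusters, m = fuzzifier, seed = seed))
  stage("fcm", {
    memb <- tibble::as_tibble(fcm$membership, rownames = "site_id")
    memb$hard_label <- unname(fcm$hard_labels)
    emit(dplyr::left_join(memb, site_flags, by = "site_id"), "fcm_membership.csv")
  })
  stage("profiles", {
    cen_all <- center_composition(comp)
    emit(cluster_profiles(cen_all$centered, fcm), "cluster_profiles.csv")
  })

  report <- list(
    n_sites = dplyr::n_distinct(samples$site_id),
    n_compounds = dplyr::n_distinct(samples$compound),
    seed = seed,
    config = list(basis = basis, robust = robust,
                  clusters = clusters, fuzzifier = fuzzifier),
    n_clusters_used = n_clusters,
    sites_above_benchmark = site_flags$site_id[site_flags$exceeds_benchmark],
    explained_variance_pc12 = unname(sum(pca$explained_variance[1:2])),
    warnings = warnings_log,
    timings_s = timings,
    versions = list(package = as.character(utils::packageVersion("soilcoda")),
                    r = R.version.string),
    outputs = basename(written)
  )
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
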