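# shared fixtures: tiny toxicity tables, random compositions, label matching

# toxicity table whose noncarcinogenic SSLs equal `ssl_targets` (mg/kg)
# under the default scenario; closed-form inversion of the SSL equation
make_tox <- function(ssl_targets, abs_skin = 0.1, pef = 1.316e9,
                     scen = noncarc_scenario()) {
  k <- scen$irs_c / 1e6 + scen$sa * scen$af * abs_skin / 1e6 + scen$ira_c / pef
  rfd <- ssl_targets * scen$ef_r * scen$ed_c * k / (scen$thq * scen$bw_c * scen$at_n)
  tibble::tibble(
    id = names(ssl_targets) %||% paste0("C", seq_along(ssl_targets)),
    rfd_o = rfd, rfd_i = rfd,
    csf_o = NA_real_, csf_i = NA_real_,
    abs_skin = abs_skin, vf_s = NA_real_, pef = pef, volatile = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n random compositions with d parts (log-normal parts, then closed)
random_compositions <- function(n, d, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(exp(stats::rnorm(n * d, sd = sd)), n, d,
                dimnames = list(NULL, paste0("p", seq_len(d))))
  })
  closure(m)
}

# best hard-label accuracy over all permutations of cluster labels
label_accuracy <- function(labels, truth) {
  labels <- as.integer(factor(labels))
  truth <- as.integer(factor(truth))
  k <- max(labels, truth)
  perms <- gtools_permutations(k)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    best <- max(best, mean(perms[i, labels] == truth))
  }
  best
}

# all permutations of 1..k (k small)
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  do.call(rbind, lapply(seq_len(k), function(i) {
    sub <- gtools_permutations(k - 1)
    cbind(i, matrix((seq_len(k))[-i][sub], nrow(sub)))
  }))
}

# wide sample CSV text for read_samples tests
write_wide_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  path
}
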