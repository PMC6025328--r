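# run code with a locally fixed RNG state, restoring the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# wide tibble (site_id + parts) or matrix -> composition matrix with rownames
comp_input <- function(x) {
  m <- as_comp_matrix(x)
  check_positive(m)
  closure(m)
}
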