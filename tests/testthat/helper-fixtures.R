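# Small-scale generator settings shared across tests: fast to simulate but
# large enough that the set-algebra and recovery properties are non-trivial.
small_params <- function(seed = 1, ...) {
  defaults <- list(genome_length = 5e4, n_contigs = 8, n_chromosomes = 4,
                   somatic_rate_per_branch = 150, somatic_rate_trunk = 150,
                   n_tumors = 70, n_hosts = 48, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_params, args)
}

# genotype matrix from explicit genotype vectors (markers m1..mk)
gm_from_rows <- function(rows, devil = NULL, location = NULL, year = NULL) {
  k <- length(rows[[1]])
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("m", seq_len(k))
  out <- tibble::as_tibble(m)
  out$tumor_id <- sprintf("T%02d", seq_along(rows))
  if (!is.null(devil)) out$devil_id <- devil
  if (!is.null(location)) out$location <- location
  if (!is.null(year)) out$year <- year
  out
}
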