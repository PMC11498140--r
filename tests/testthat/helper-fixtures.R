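# Shared fixture builders. Everything is generated in code; no binary data.

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_table <- function(m, samples = NULL, asvs = NULL) {
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(asvs)) asvs <- sprintf("ASV%03d", seq_len(ncol(m)))
  asv_table(matrix(as.integer(m), nrow(m), ncol(m),
                   dimnames = list(samples, asvs)))
}

rand_table <- function(n_samples, n_asvs, seed, max_count = 10) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_asvs, 2), n_samples, n_asvs)
  m[sample(length(m), length(m) %/% 3)] <- 0
  # guarantee no all-zero rows
  for (i in which(rowSums(m) == 0)) m[i, sample(n_asvs, 1)] <- max_count
  mk_table(m)
}

# minimal metadata records for hand-built tables
mk_records <- function(sample_id, subject_id, sample_type, timepoint,
                       replicate = 1L) {
  data.frame(sample_id = sample_id, subject_id = subject_id,
             sample_type = sample_type, timepoint = timepoint,
             replicate = as.integer(replicate), stringsAsFactors = FALSE)
}

# small but complete simulated study for integration-style tests
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_subjects = 10, proportion_urban = 0.5, timepoints = c("S", "A", "W"),
    n_env_taxa = 120, n_core_taxa = c(saliva = 40, skin = 60, feces = 40),
    n_contaminant_taxa = 8, n_offtarget_taxa = 5,
    library_size_human = c(500, 900), library_size_mat = c(1200, 2000),
    n_mat_replicates = 2, n_negative_controls = 4, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}
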