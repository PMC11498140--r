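#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Inputs are either file
#' paths (`counts`, `taxonomy`, `metadata`) or a [simulation_config()] via
#' `simulate`; exactly one of the two must be given.
#'
#' @param counts,taxonomy,metadata input file paths (all three, or none)
#' @param simulate optional [simulation_config()] used instead of files
#' @param out_dir output directory
#' @param depth rarefaction depth or `"auto_per_type"`
#' @param rarefaction_seed,permutation_seed,diagnostics_seed integer seeds
#' @param distances distance measures to run (subset of bray, sorensen,
#'   hellinger)
#' @param n_perm permutations for PERMANOVA/PERMDISP
#' @param candidates GLMM candidate covariates
#' @param n_sim residual-diagnostic simulations
#' @param exclude_antibiotics drop antibiotic observations before modeling
#' @param venn_complete_cases complete-case restriction for the Venn counts
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(counts = NULL, taxonomy = NULL, metadata = NULL,
                            simulate = NULL, out_dir,
                            depth = "auto_per_type",
                            rarefaction_seed = 1L, permutation_seed = 1L,
                            diagnostics_seed = 1L,
                            distances = c("sorensen", "bray", "hellinger"),
                            n_perm = 999,
                            candidates = c("built", "outdoor", "gardening",
                                           "pets", "handwashing",
                                           "number_of_persons",
                                           "real_mat_days"),
                            n_sim = 250,
                            exclude_antibiotics = TRUE,
                            venn_complete_cases = TRUE) {
  from_files <- !is.null(counts)
  if (from_files) {
    for (p in c(counts, taxonomy, metadata))
      if (!file.exists(p)) stop("input file not found: ", p)
  } else if (is.null(simulate)) {
    stop("either input file paths or a simulation config must be provided")
  } else {
    stopifnot(inherits(simulate, "simulation_config"))
  }
  distances <- match.arg(distances, c("bray", "sorensen", "hellinger"),
                         several.ok = TRUE)
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                 simulate = simulate, from_files = from_files,
                 out_dir = out_dir, depth = depth,
                 rarefaction_seed = as.integer(rarefaction_seed),
                 permutation_seed = as.integer(permutation_seed),
                 diagnostics_seed = as.integer(diagnostics_seed),
                 distances = distances, n_perm = n_perm,
                 candidates = candidates, n_sim = n_sim,
                 exclude_antibiotics = exclude_antibiotics,
                 venn_complete_cases = venn_complete_cases),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Filter, rarefy, shared-taxa table, ordination plus PERMANOVA/PERMDISP
#' per human type and timepoint, forward-selected GLMMs per human type
#' (plus per-timepoint reruns), Venn partition, and a JSON run manifest
#' recording seeds and row/ASV counts. All tabular outputs are TSV.
#'
#' @param config a [pipeline_config()]
#' @param quiet suppress progress messages
#' @return invisibly, a list with the main in-memory results (`shared`,
#'   `tests`, `models`, `venn`, `manifest`)
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)

  # --- stage: inputs ---
  if (config$from_files) {
    say("reading inputs")
    table <- read_count_table(config$counts)
    taxonomy <- read_taxonomy(config$taxonomy)
    meta <- read_metadata(config$metadata)
  } else {
    say("simulating study")
    study <- generate_study(config$simulate)
    table <- study$table
    taxonomy <- study$taxonomy
    meta <- study$metadata
  }

  # --- stage: filter + rarefy ---
  say("filtering and rarefying")
  filt <- filter_pipeline(table, taxonomy, meta$samples,
                          depth = config$depth,
                          seed = config$rarefaction_seed)
  write_tsv(filt$report, file.path(config$out_dir, "filter_report.tsv"))
  write_count_table(filt$table, file.path(config$out_dir, "rarefied_counts.tsv"))

  # --- stage: shared taxa ---
  say("shared-taxa statistics")
  shared <- shared_table(filt$table, filt$records)
  write_tsv(as.data.frame(shared), file.path(config$out_dir, "shared.tsv"))
  write_tsv(shared_summaries(shared),
            file.path(config$out_dir, "data_characteristics.tsv"))

  venn <- NULL
  first_tp <- intersect(timepoint_levels, unique(filt$records$timepoint))[1]
  venn_types <- intersect(c("mat", "saliva", "skin", "feces"),
                          unique(filt$records$sample_type))
  venn <- try(venn_by_type(filt$table, filt$records, timepoint = first_tp,
                           types = venn_types,
                           complete_cases = config$venn_complete_cases),
              silent = TRUE)
  if (inherits(venn, "try-error")) {
    warnings_log <- c(warnings_log, "venn partition skipped: no complete cases")
    venn <- NULL
  } else {
    write_tsv(venn$partition, file.path(config$out_dir, "venn_partition.tsv"))
  }

  # --- stage: ordination + PERMANOVA/PERMDISP per human type/timepoint ---
  say("community structure tests")
  tests <- list(); disp_rows <- list()
  for (ht in intersect(c("saliva", "skin", "feces"),
                       unique(filt$records$sample_type))) {
    for (tp in intersect(timepoint_levels, unique(filt$records$timepoint))) {
      rec <- filt$records[filt$records$timepoint == tp &
                            filt$records$sample_type %in% c("mat", ht), ,
                          drop = FALSE]
      tab <- table(rec$sample_type)
      if (length(tab) < 2 || any(tab < 3)) next
      sub <- filt$table[match(rec$sample_id, sample_ids(filt$table)), ,
                        drop = FALSE]
      sub <- sub[, colSums(unclass(sub)) > 0, drop = FALSE]
      for (dm in config$distances) {
        d <- distance_matrix(sub, method = dm)
        pa <- permanova(d, rec$sample_type, n_perm = config$n_perm,
                        seed = config$permutation_seed)
        pd <- permdisp(d, rec$sample_type, n_perm = config$n_perm,
                       seed = config$permutation_seed)
        key <- paste(ht, tp, dm, sep = "_")
        tests[[key]] <- list(permanova = pa, permdisp = pd)
        disp_rows[[key]] <- data.frame(
          human_type = ht, timepoint = tp, distance = dm,
          avg_dist_mat = unname(pd$group_means["mat"]),
          avg_dist_human = unname(pd$group_means[ht]),
          permdisp_F = pd$anova_f, permdisp_p = pd$anova_p,
          permanova_F = pa$statistic, permanova_p = pa$permutation_p,
          stringsAsFactors = FALSE)
        if (dm == config$distances[1]) {
          ord <- pcoa(d)
          utils::write.table(
            data.frame(sample_id = ord$ids, ord$coordinates[, seq_len(
              min(3, ncol(ord$coordinates))), drop = FALSE]),
            file.path(config$out_dir, sprintf("pcoa_%s_%s.tsv", ht, tp)),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }
  if (length(disp_rows))
    write_tsv(do.call(rbind, disp_rows),
              file.path(config$out_dir, "dispersion_tests.tsv"))

  # --- stage: GLMMs ---
  say("dispersal models")
  models <- list()
  for (ht in intersect(c("saliva", "skin", "feces"), unique(shared$human_type))) {
    data <- prepare_model_data(shared, meta$subjects, ht,
                               exclude_antibiotics = config$exclude_antibiotics)
    cand <- intersect(config$candidates, names(data))
    res <- try(forward_select(data, cand), silent = TRUE)
    if (inherits(res, "try-error")) {
      warnings_log <- c(warnings_log,
                        sprintf("model for %s failed: %s", ht,
                                conditionMessage(attr(res, "condition"))))
      next
    }
    per_tp <- per_timepoint_models(data, cand)
    for (tp in names(per_tp))
      if (isTRUE(per_tp[[tp]]$skipped))
        warnings_log <- c(warnings_log,
                          sprintf("%s timepoint %s skipped: %s", ht, tp,
                                  per_tp[[tp]]$reason))
    diag <- if (res$model$converged)
      simulate_residuals(res$model,
                         data[stats::complete.cases(
                           data[, res$selected, drop = FALSE]), , drop = FALSE],
                         n_sim = config$n_sim,
                         seed = config$diagnostics_seed)
    else NULL
    models[[ht]] <- list(selection = res, per_timepoint = per_tp,
                         diagnostics = diag)
    co <- res$model$coefficients
    co <- cbind(human_type = ht, co)
    write_tsv(co, file.path(config$out_dir, sprintf("glmm_%s.tsv", ht)))
  }

  # --- manifest ---
  manifest <- list(
    package = "dispersalshare",
    version = as.character(utils::packageVersion("dispersalshare")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seeds = list(rarefaction = config$rarefaction_seed,
                 permutation = config$permutation_seed,
                 diagnostics = config$diagnostics_seed,
                 simulation = if (!config$from_files) config$simulate$seed),
    n_perm = config$n_perm,
    depths = as.list(filt$depths),
    n_samples = nrow(filt$table),
    n_asvs = ncol(filt$table),
    n_shared_records = nrow(shared),
    selected = lapply(models, function(m) m$selection$selected),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: outputs in ", config$out_dir)
  invisible(list(shared = shared, tests = tests, models = models,
                 venn = venn, manifest = manifest))
}
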