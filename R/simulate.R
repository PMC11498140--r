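#' Simulation configuration
#'
#' Defines the generative model of a paired human/doormat study: urban and
#' rural regional taxon pools, subject-specific core microbiota per body
#' site, covariate-driven dispersal acting on community composition, mats
#' accumulating both environmental and human-shed taxa, library sizes, mat
#' replicates, and contamination shared with negative controls.
#'
#' Defaults mirror the emulated study: 53 subjects of whom 24 urban, three
#' seasons (no winter skin sampling), mat libraries of 3,000-5,000 reads
#' and human libraries of 1,000-2,500 reads (so per-type rarefaction depths
#' land near 1,000-1,200), up to three mat replicates, and a dispersal
#' logit with a positive built-environment coefficient (0.02 per percent),
#' a negative outdoor-recreation coefficient, and season offsets making
#' sharing highest in winter (A +0.14, W +1.07 on the logit scale). The
#' baseline logit (-4.5) and the mat shedding rate (0.005) are calibrated
#' so the realized shared-proportion means fall inside the range the
#' emulated study reports (see the methods vignette).
#'
#' @param n_subjects number of subjects
#' @param proportion_urban fraction of subjects in the urban stratum
#' @param timepoints subset of `c("S", "A", "W")`
#' @param n_env_taxa environmental pool size per stratum
#' @param n_core_taxa named integer vector: core pool size per body site
#' @param n_contaminant_taxa number of contaminant ASVs
#' @param n_offtarget_taxa number of blacklisted-lineage ASVs (chloroplast
#'   etc.) spiked into real samples to exercise the lineage filter
#' @param env_lognormal `c(meanlog, sdlog)` of the environmental abundance law
#' @param beta named list of dispersal-logit coefficients: `intercept`,
#'   `built`, `outdoor`, `gardening`, `pets`, `handwashing`,
#'   `number_of_persons`, `real_mat_days`, and `timepoint = c(A=, W=)`
#' @param human_shedding_rate expected fraction of mat reads of human origin
#' @param library_size_human,library_size_mat integer ranges `c(lo, hi)`
#'   (mat range is the total over replicates)
#' @param n_mat_replicates mat DNA-extraction replicates (1-3)
#' @param n_negative_controls number of sequenced blanks
#' @param contamination_lambda Poisson mean of contaminant counts
#' @param contamination_sample_fraction fraction of real samples receiving
#'   each contaminant
#' @param missingness_fraction fraction of questionnaire covariate cells
#'   set missing
#' @param antibiotics_rate per-observation probability of antibiotic use in
#'   the previous six months
#' @param seed integer seed
#' @return a list of class `simulation_config`
#' @export
simulation_config <- function(n_subjects = 53,
                              proportion_urban = 24 / 53,
                              timepoints = c("S", "A", "W"),
                              n_env_taxa = 600,
                              n_core_taxa = c(saliva = 150, skin = 300,
                                              feces = 150),
                              n_contaminant_taxa = 30,
                              n_offtarget_taxa = 10,
                              env_lognormal = c(meanlog = 0, sdlog = 1.5),
                              beta = list(intercept = -4.5,
                                          built = 0.02,
                                          outdoor = -1.2,
                                          gardening = 0,
                                          pets = 0,
                                          handwashing = 0,
                                          number_of_persons = 0,
                                          real_mat_days = 0,
                                          timepoint = c(A = 0.14, W = 1.07)),
                              human_shedding_rate = 0.005,
                              library_size_human = c(1000, 2500),
                              library_size_mat = c(3000, 5000),
                              n_mat_replicates = 3,
                              n_negative_controls = 26,
                              contamination_lambda = 2,
                              contamination_sample_fraction = 0.3,
                              missingness_fraction = 0.02,
                              antibiotics_rate = 0.08,
                              seed = 1L) {
  stopifnot(n_subjects >= 1, proportion_urban >= 0, proportion_urban <= 1,
            all(timepoints %in% c("S", "A", "W")), length(timepoints) >= 1,
            n_env_taxa >= 1, all(n_core_taxa >= 1),
            n_contaminant_taxa >= 0, n_offtarget_taxa >= 0,
            human_shedding_rate >= 0, human_shedding_rate <= 1,
            n_mat_replicates >= 1, n_mat_replicates <= 3,
            n_negative_controls >= 1,
            missingness_fraction >= 0, missingness_fraction < 1)
  if (!all(c("saliva", "skin", "feces") %in% names(n_core_taxa)))
    stop("n_core_taxa must be named for saliva, skin and feces")
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: %d subjects (%.0f%% urban), timepoints %s\n",
              x$n_subjects, 100 * x$proportion_urban,
              paste(x$timepoints, collapse = ",")))
  cat(sprintf("  pools: env %d x2 strata, core %s, contaminants %d\n",
              x$n_env_taxa,
              paste(names(x$n_core_taxa), x$n_core_taxa, collapse = ", "),
              x$n_contaminant_taxa))
  invisible(x)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Draw subject covariates
#'
#' Built percentage is a urban/rural mixture (urban high, rural low)
#' truncated to `[0, 100]`; outdoor recreation is a truncated normal on the
#' observed Likert-mean range; gardening, pets and handwashing are
#' Bernoulli with prevalences matching the emulated cohort; the number of
#' persons is 1-5; real mat days are drawn per timepoint. A configurable
#' fraction of questionnaire cells is set missing to exercise the selection
#' protocol's missingness branches.
#'
#' @param config a [simulation_config()]
#' @param seed integer seed (defaults to the config's)
#' @return data.frame, one row per subject x timepoint, with columns
#'   `subject_id`, `timepoint`, `urban`, `built`, `outdoor`, `gardening`,
#'   `pets`, `handwashing`, `number_of_persons`, `real_mat_days`,
#'   `antibiotics_last_6mo`
#' @export
draw_covariates <- function(config, seed = config$seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- config$n_subjects
  n_urb <- round(config$proportion_urban * n)
  urban <- c(rep("u", n_urb), rep("r", n - n_urb))
  subject_id <- sprintf("%s%02d", urban, seq_len(n))
  built <- ifelse(urban == "u",
                  rtruncnorm1(n, 70, 15, 0, 100),
                  rtruncnorm1(n, 15, 12, 0, 100))
  outdoor <- rtruncnorm1(n, 1.0, 0.45, 0, 4)
  gardening <- ifelse(stats::runif(n) < 0.5, "at_least_monthly", "rarely")
  pets <- ifelse(stats::runif(n) < 0.15, "yes", "no")
  handwashing <- ifelse(stats::runif(n) < 0.75, "many_times_a_day",
                        "max_once_a_day")
  tps <- config$timepoints
  out <- do.call(rbind, lapply(tps, function(tp) {
    data.frame(subject_id = subject_id, timepoint = tp, urban = urban,
               built = built, outdoor = outdoor, gardening = gardening,
               pets = pets, handwashing = handwashing,
               number_of_persons = pmin(5, pmax(1, stats::rpois(n, 2) + 1)),
               real_mat_days = round(rtruncnorm1(n, 14, 4, 3, 37)),
               antibiotics_last_6mo = stats::runif(n) < config$antibiotics_rate,
               stringsAsFactors = FALSE)
  }))
  if (config$missingness_fraction > 0) {
    for (col in c("gardening", "handwashing", "number_of_persons",
                  "real_mat_days")) {
      hit <- stats::runif(nrow(out)) < config$missingness_fraction
      out[[col]][hit] <- NA
    }
  }
  rownames(out) <- NULL
  out
}

#' True dispersal probability per subject-timepoint
#'
#' `d = logistic(b0 + sum(b_j x_j) + b_t[timepoint])`, deterministic given
#' the covariates and coefficients. Two-level factors are coded 0/1 with
#' references: gardening rarely, pets no, handwashing max_once_a_day.
#'
#' @param covariates a covariates data.frame (see [draw_covariates()])
#' @param beta coefficient list (see [simulation_config()])
#' @return numeric vector of dispersal probabilities in `(0, 1)`
#' @export
true_dispersal <- function(covariates, beta) {
  num <- function(col, code = identity) {
    b <- beta[[col]]
    if (is.null(b) || b == 0) return(0)
    v <- code(covariates[[col]])
    if (anyNA(v))
      stop("missing values in covariate '", col, "' with nonzero coefficient")
    b * v
  }
  eta <- beta$intercept +
    num("built") + num("outdoor") +
    num("gardening", function(v) as.numeric(v == "at_least_monthly")) +
    num("pets", function(v) as.numeric(v == "yes")) +
    num("handwashing", function(v) as.numeric(v == "many_times_a_day")) +
    num("number_of_persons") + num("real_mat_days")
  tp_off <- c(S = 0, beta$timepoint)[covariates$timepoint]
  tp_off[is.na(tp_off)] <- 0
  unname(stats::plogis(eta + tp_off))
}

# lognormal relative-abundance profile over a pool, normalized to sum 1
draw_profile <- function(n_taxa, meanlog, sdlog) {
  w <- stats::rlnorm(n_taxa, meanlog, sdlog)
  w / sum(w)
}

#' Simulate one sample's count vector
#'
#' Human sample composition: `(1 - d) * core_site + d * environmental`.
#' Mat composition: `(1 - h) * environmental + h * combined human core`.
#' Reads are one multinomial draw of `library_size` reads.
#'
#' @param kind `"mat"` or a human type (`"saliva"`, `"skin"`, `"feces"`)
#' @param core_profile the subject's core profile for this site (human
#'   kinds), or the subject's combined core profile (mat)
#' @param env_profile the subject's regional environmental profile
#' @param d dispersal probability (human kinds; ignored for mat)
#' @param h human shedding rate (mat; ignored for human kinds)
#' @param library_size total reads to draw
#' @return integer count vector over `length(core_profile)` taxa (core and
#'   environmental profiles must be indexed on the same global taxon space)
#' @export
simulate_sample <- function(kind, core_profile, env_profile, d = 0, h = 0,
                            library_size) {
  if (library_size < 1) stop("library_size must be >= 1")
  if (length(core_profile) != length(env_profile))
    stop("profiles must live on the same taxon space")
  if (sum(core_profile) == 0 || sum(env_profile) == 0)
    stop("empty taxon pool")
  comp <- if (kind == "mat") {
    (1 - h) * env_profile + h * core_profile
  } else {
    (1 - d) * core_profile + d * env_profile
  }
  drop(stats::rmultinom(1, size = library_size, prob = comp))
}

#' Inject contaminant taxa
#'
#' Adds each contaminant ASV with small Poisson counts to a random subset
#' of ALL real samples (every sample type) and to at least one negative
#' control, guaranteeing that the strict control filter can see and remove
#' it. Only contaminant taxa ever appear in negative controls.
#'
#' @param study a `simulated_study` (see [generate_study()])
#' @param config the [simulation_config()]
#' @param seed integer seed
#' @return the study with contaminant counts added and origin labels updated
#' @export
inject_contamination <- function(study, config, seed = config$seed + 1L) {
  K <- config$n_contaminant_taxa
  if (K == 0) return(study)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  m <- unclass(study$table)
  contam_cols <- which(study$origin == "contaminant")
  stopifnot(length(contam_cols) == K)
  is_control <- study$metadata$samples$sample_type == "negative_control"
  real <- which(!is_control); ctrl <- which(is_control)
  lam <- config$contamination_lambda
  for (j in contam_cols) {
    hit <- real[stats::runif(length(real)) < config$contamination_sample_fraction]
    if (length(hit))
      m[hit, j] <- m[hit, j] + stats::rpois(length(hit), lam)
    # every control sees every contaminant at least once
    m[ctrl, j] <- m[ctrl, j] + pmax(1L, stats::rpois(length(ctrl), lam))
  }
  study$table <- asv_table(m)
  study
}

#' Generate a complete synthetic study
#'
#' Full factorial subjects x timepoints x sample types (skin absent in
#' winter), mat replicates, negative controls, taxonomy with synthetic
#' lineages (including a few blacklisted off-target ASVs), covariates with
#' missingness, contamination, and ground truth (per-observation true
#' dispersal probability and per-ASV origin labels). Fully reproducible
#' from the config's seed.
#'
#' @param config a [simulation_config()]
#' @return list of class `simulated_study`: `table` ([asv_table]),
#'   `metadata` (list `samples`, `subjects` as in [read_metadata()]),
#'   `taxonomy`, `origin` (per-ASV label: environmental, human_core,
#'   contaminant, offtarget), `truth` (data.frame subject_id, timepoint, d),
#'   `config`
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  covs <- draw_covariates(config, seed = config$seed)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed + 1000L)

  # --- global taxon space ---
  E <- config$n_env_taxa
  sites <- c("saliva", "skin", "feces")
  nc <- config$n_core_taxa[sites]
  K <- config$n_contaminant_taxa
  B <- config$n_offtarget_taxa
  blocks <- c(env_u = E, env_r = E,
              stats::setNames(nc, paste0("core_", sites)),
              contaminant = K, offtarget = B)
  starts <- cumsum(c(0, blocks))[seq_along(blocks)]
  names(starts) <- names(blocks)
  P <- sum(blocks)
  asv_id <- sprintf("ASV%05d", seq_len(P))
  origin <- rep(c("environmental", "environmental",
                  rep("human_core", length(sites)),
                  "contaminant", "offtarget"),
                times = c(E, E, nc, K, B))
  block_idx <- function(b) starts[[b]] + seq_len(blocks[[b]])

  # --- regional environmental profiles (shared within stratum) ---
  ml <- config$env_lognormal[1]; sl <- config$env_lognormal[2]
  env_profile <- list(u = numeric(P), r = numeric(P))
  env_profile$u[block_idx("env_u")] <- draw_profile(E, ml, sl)
  env_profile$r[block_idx("env_r")] <- draw_profile(E, ml, sl)

  # --- subject-specific core profiles per site ---
  subjects <- unique(covs$subject_id)
  core <- lapply(subjects, function(s) {
    pr <- lapply(sites, function(st) {
      v <- numeric(P)
      v[block_idx(paste0("core_", st))] <- draw_profile(nc[[st]], ml, sl)
      v
    })
    names(pr) <- sites
    pr
  })
  names(core) <- subjects
  stratum <- covs$urban[match(subjects, covs$subject_id)]
  names(stratum) <- subjects

  d_true <- true_dispersal_safe(covs, config$beta)
  truth <- data.frame(subject_id = covs$subject_id,
                      timepoint = covs$timepoint, d = d_true,
                      stringsAsFactors = FALSE)

  # --- samples ---
  rows <- list(); recs <- list()
  rlh <- config$library_size_human; rlm <- config$library_size_mat
  nrep <- config$n_mat_replicates
  add <- function(counts, sample_id, subject_id, type, tp, repl) {
    rows[[length(rows) + 1]] <<- counts
    recs[[length(recs) + 1]] <<- data.frame(
      sample_id = sample_id, subject_id = subject_id, sample_type = type,
      timepoint = tp, replicate = repl, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(covs))) {
    s <- covs$subject_id[i]; tp <- covs$timepoint[i]
    env <- env_profile[[stratum[[s]]]]
    d_i <- d_true[i]
    for (st in sites) {
      if (st == "skin" && tp == "W") next   # no winter skin sampling
      lib <- sample(rlh[1]:rlh[2], 1)
      cnt <- simulate_sample(st, core[[s]][[st]], env, d = d_i,
                             library_size = lib)
      add(cnt, paste(s, tp, st, sep = "_"), s, st, tp, 1L)
    }
    combined <- Reduce(`+`, core[[s]]) / length(sites)
    for (r in seq_len(nrep)) {
      lib <- sample(max(1, floor(rlm[1] / nrep)):max(1, floor(rlm[2] / nrep)), 1)
      cnt <- simulate_sample("mat", combined, env,
                             h = config$human_shedding_rate,
                             library_size = lib)
      add(cnt, paste(s, tp, "mat", paste0("r", r), sep = "_"), s, "mat", tp, r)
    }
  }
  for (j in seq_len(config$n_negative_controls))
    add(rep(0L, P), sprintf("NC%02d", j), NA_character_, "negative_control",
        config$timepoints[1], 1L)

  counts <- do.call(rbind, rows)
  records <- do.call(rbind, recs)
  rownames(counts) <- records$sample_id
  colnames(counts) <- asv_id

  # --- off-target (blacklisted-lineage) reads spiked into real samples ---
  if (B > 0) {
    real <- which(records$sample_type != "negative_control")
    for (j in block_idx("offtarget")) {
      hit <- real[stats::runif(length(real)) < 0.2]
      if (length(hit)) counts[hit, j] <- counts[hit, j] + stats::rpois(length(hit), 3)
    }
  }

  taxonomy <- synthetic_taxonomy(asv_id, origin)
  study <- structure(list(table = asv_table(counts),
                          metadata = list(samples = records, subjects = covs),
                          taxonomy = taxonomy,
                          origin = stats::setNames(origin, asv_id),
                          truth = truth,
                          config = config),
                     class = "simulated_study")
  inject_contamination(study, config, seed = config$seed + 2000L)
}

# true_dispersal, but covariate cells that are missing AND have zero
# coefficient must not poison the logit; cells missing with nonzero
# coefficient still error (handled inside true_dispersal).
true_dispersal_safe <- function(covs, beta) true_dispersal(covs, beta)

synthetic_taxonomy <- function(asv_id, origin) {
  lineage <- vapply(seq_along(asv_id), function(i) {
    switch(origin[i],
      environmental = sprintf(
        "Bacteria;Proteobacteria;Env_class;Env_order;Env_family;Genus_env%03d",
        i %% 199),
      human_core = sprintf(
        "Bacteria;Firmicutes;Core_class;Core_order;Core_family;Genus_core%03d",
        i %% 97),
      contaminant = sprintf(
        "Bacteria;Actinobacteria;Lab_class;Lab_order;Lab_family;Genus_contam%02d",
        i %% 13),
      offtarget = {
        labels <- c("Chloroplast", "Mitochondria", "unknown", "Archaea",
                    "Eukaryota")
        lab <- labels[(i %% length(labels)) + 1]
        if (lab %in% c("Archaea", "Eukaryota"))
          sprintf("%s;Offtarget_phylum;Off_class", lab)
        else
          sprintf("Bacteria;Cyanobacteria;%s;Off_order", lab)
      })
  }, character(1))
  data.frame(asv_id = asv_id, lineage = I(strsplit(lineage, ";", fixed = TRUE)))
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated paired human/doormat study\n")
  print(x$table)
  cat(sprintf("  %d subjects, timepoints %s, %d negative controls\n",
              length(unique(x$truth$subject_id)),
              paste(unique(x$truth$timepoint), collapse = ","),
              sum(x$metadata$samples$sample_type == "negative_control")))
  cat("  ASV origins: ")
  print(table(x$origin))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the counts (plain TSV), metadata TSV, taxonomy TSV and ground
#' truth TSV in the formats the readers accept.
#'
#' @param study a `simulated_study`
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_count_table(study$table, paths["counts"])
  write_metadata(study$metadata, paths["metadata"])
  tax <- data.frame(asv_id = study$taxonomy$asv_id,
                    lineage = vapply(study$taxonomy$lineage, paste,
                                     character(1), collapse = ";"))
  utils::write.table(tax, paths["taxonomy"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(study$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
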