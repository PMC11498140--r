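#' @name dispersal_models
#' @title Binomial GLMMs for the shared proportion and forward selection
#'
#' @description
#' The shared proportion is modeled as binomial successes/trials
#' (shared count `k` out of human richness `n`) with a logit link, a fixed
#' timepoint effect, and a random intercept per subject. Forward selection
#' follows a two-phase protocol: the first variable enters if it has the
#' lowest (and below 0.05) p value after a per-candidate interaction screen
#' against timepoint; subsequent variables enter one at a time by lowest
#' AIC, accepted only when AIC drops by at least 3. Missing data are handled
#' per phase: candidate-wise complete rows in phase 1, all-variable complete
#' rows afterwards, and a final refit on rows complete for the selected
#' variables only.
NULL

#' Prepare a modeling data frame
#'
#' Joins one human type's shared-taxa records with the per-(subject,
#' timepoint) covariates, applies factor codings (reference levels:
#' timepoint S, gardening rarely, pets no, handwashing max_once_a_day), and
#' optionally drops observations with antibiotic use in the previous six
#' months (default on).
#'
#' @param shared a [shared_table()] result
#' @param subjects covariates data.frame (see [read_metadata()])
#' @param human_type `"saliva"`, `"skin"` or `"feces"`
#' @param exclude_antibiotics drop rows with `antibiotics_last_6mo = TRUE`
#' @return data.frame with `k`, `n`, `subject_id`, `timepoint` (factor) and
#'   the covariates
#' @export
prepare_model_data <- function(shared, subjects, human_type,
                               exclude_antibiotics = TRUE) {
  stopifnot(human_type %in% c("saliva", "skin", "feces"))
  df <- shared[shared$human_type == human_type,
               c("subject_id", "timepoint", "k", "n"), drop = FALSE]
  df <- merge(df, subjects, by = c("subject_id", "timepoint"),
              all.x = TRUE, sort = FALSE)
  if (exclude_antibiotics && "antibiotics_last_6mo" %in% names(df))
    df <- df[!(df$antibiotics_last_6mo %in% TRUE), , drop = FALSE]
  df$timepoint <- factor(df$timepoint, levels = timepoint_levels)
  df$timepoint <- droplevels(df$timepoint)
  if ("gardening" %in% names(df))
    df$gardening <- factor(df$gardening, c("rarely", "at_least_monthly"))
  if ("pets" %in% names(df))
    df$pets <- factor(df$pets, c("no", "yes"))
  if ("handwashing" %in% names(df))
    df$handwashing <- factor(df$handwashing,
                             c("max_once_a_day", "many_times_a_day"))
  rownames(df) <- NULL
  df
}

glmm_formula <- function(fixed_terms = character(0),
                         interactions = character(0),
                         include_timepoint = TRUE) {
  rhs <- character(0)
  if (include_timepoint) rhs <- "timepoint"
  rhs <- c(rhs, fixed_terms)
  if (length(interactions)) {
    if (!include_timepoint)
      stop("interactions with timepoint require the timepoint main effect")
    miss <- setdiff(interactions, fixed_terms)
    if (length(miss))
      stop("interaction without main effect (marginality violated): ",
           paste(miss, collapse = ", "))
    rhs <- c(rhs, paste0(interactions, ":timepoint"))
  }
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste("cbind(k, n - k) ~", paste(rhs, collapse = " + "),
                          "+ (1 | subject_id)"))
}

#' Fit a binomial random-intercept GLMM
#'
#' Maximizes the Laplace-approximated marginal likelihood of a
#' binomial-logit model with a subject random intercept (via
#' `lme4::glmer`). If the default optimizer fails to converge, the fit is
#' retried with the derivative-free `bobyqa` optimizer. Complete separation
#' is flagged (huge |estimate| with huge SE), not raised.
#'
#' @param data data.frame with `k`, `n`, `subject_id`, `timepoint` and any
#'   covariates named in the terms; no missing values allowed in used terms
#' @param fixed_terms character vector of covariate names
#' @param interactions subset of `fixed_terms` to interact with timepoint
#' @param include_timepoint keep the timepoint fixed effect (drop only for
#'   single-timepoint strata)
#' @param nagq number of adaptive Gauss-Hermite quadrature points
#'   (1 = Laplace, the default)
#' @return object of class `glmm_fit`: list with `coefficients` (data.frame
#'   term/estimate/se/z/p), `ranef_sd`, `loglik`, `aic`, `n_obs`,
#'   `converged`, `separation`, `optimizer`, `formula` and the underlying
#'   `fit`
#' @export
fit_glmm <- function(data, fixed_terms = character(0),
                     interactions = character(0), include_timepoint = TRUE,
                     nagq = 1L) {
  used <- unique(c("k", "n", "subject_id",
                   if (include_timepoint) "timepoint", fixed_terms))
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[, used, drop = FALSE]))
    stop("missing values in modeling columns; handle missingness before fitting")
  if (length(unique(data$subject_id)) < 2)
    stop("need at least 2 subjects for a random intercept")
  if (any(data$n < 1) || any(data$k < 0) || any(data$k > data$n))
    stop("response must satisfy 0 <= k <= n, n >= 1")
  for (tm in fixed_terms) {
    if (length(unique(data[[tm]])) < 2)
      stop("term '", tm,
           "' has a single observed value: design is rank-deficient")
  }
  if (include_timepoint && length(unique(data$timepoint)) < 2)
    stop("timepoint has a single observed level; drop it via include_timepoint = FALSE")
  form <- glmm_formula(fixed_terms, interactions, include_timepoint)
  # a constant response (e.g. all k/n equal) is a legitimate degenerate input
  try_fit <- function(optimizer, nagq_i) {
    ctrl <- if (is.null(optimizer))
      lme4::glmerControl(check.response.not.const = "ignore")
    else
      lme4::glmerControl(optimizer = optimizer,
                         check.response.not.const = "ignore")
    tryCatch(suppressMessages(suppressWarnings(
      lme4::glmer(form, data = data, family = stats::binomial(),
                  nAGQ = nagq_i, control = ctrl))),
      error = function(e) e)
  }
  # default first; on failure retry with the derivative-free bobyqa; as a
  # last resort drop to nAGQ = 0 (degenerate responses can defeat the PIRLS
  # inner loop at nAGQ >= 1)
  attempts <- list(list(opt = NULL, nagq = nagq, label = "default"),
                   list(opt = "bobyqa", nagq = nagq, label = "bobyqa"),
                   list(opt = "bobyqa", nagq = 0L, label = "bobyqa/nAGQ0"))
  fit <- NULL; optimizer <- NA_character_; conv <- FALSE
  for (at in attempts) {
    cand <- try_fit(at$opt, at$nagq)
    if (inherits(cand, "error")) next
    if (is.null(fit)) { fit <- cand; optimizer <- at$label }
    if (is_converged(cand)) {
      fit <- cand; optimizer <- at$label; conv <- TRUE
      break
    }
  }
  if (is.null(fit)) {
    # zero-variance limit: degenerate responses (e.g. exactly constant k/n)
    # defeat glmer's PIRLS loop, but their MLE is the plain binomial GLM
    # with the random-intercept SD at its boundary 0
    rhs <- deparse(form[[3]])
    rhs <- trimws(sub("\\+\\s*\\(1 \\| subject_id\\)\\s*$", "", rhs))
    gfit <- stats::glm(stats::as.formula(paste("cbind(k, n - k) ~", rhs)),
                       data = data, family = stats::binomial())
    sm <- summary(gfit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        z = sm[, 3], p = sm[, 4], row.names = NULL,
                        stringsAsFactors = FALSE)
    ll <- as.numeric(stats::logLik(gfit))
    n_par <- attr(stats::logLik(gfit), "df") + 1  # + boundary variance par
    return(structure(list(coefficients = coefs, ranef_sd = 0,
                          loglik = ll, aic = 2 * n_par - 2 * ll,
                          n_par = n_par, n_obs = nrow(data),
                          converged = gfit$converged,
                          separation = any(abs(coefs$estimate) > 15 &
                                             coefs$se > 50),
                          optimizer = "glm_boundary_fallback",
                          fixed_terms = fixed_terms,
                          interactions = interactions,
                          include_timepoint = include_timepoint,
                          formula = form, fit = gfit),
                     class = "glmm_fit"))
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], z = sm[, "z value"],
                      p = sm[, "Pr(>|z|)"], row.names = NULL,
                      stringsAsFactors = FALSE)
  separation <- any(abs(coefs$estimate) > 15 & coefs$se > 50)
  ll <- as.numeric(stats::logLik(fit))
  structure(list(coefficients = coefs,
                 ranef_sd = sqrt(unname(lme4::VarCorr(fit)$subject_id[1, 1])),
                 loglik = ll,
                 aic = stats::AIC(fit),
                 n_par = attr(stats::logLik(fit), "df"),
                 n_obs = nrow(data),
                 converged = conv,
                 separation = separation,
                 optimizer = optimizer,
                 fixed_terms = fixed_terms,
                 interactions = interactions,
                 include_timepoint = include_timepoint,
                 formula = form,
                 fit = fit),
            class = "glmm_fit")
}

is_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  code <- fit@optinfo$conv$opt
  is.null(msgs) && (is.null(code) || code == 0)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial random-intercept GLMM:",
      deparse(x$formula), "\n")
  cat(sprintf("n = %d, logLik = %.3f, AIC = %.3f, subject SD = %.3f (%s%s)\n",
              x$n_obs, x$loglik, x$aic, x$ranef_sd,
              if (x$converged) "converged" else "NOT converged",
              if (x$separation) "; possible separation" else ""))
  co <- x$coefficients
  co[, -1] <- round(co[, -1], 4)
  print(co, row.names = FALSE)
  invisible(x)
}

# likelihood-ratio test of nested glmm_fits (chi-square reference)
lrt_glmm <- function(full, reduced) {
  stat <- 2 * (full$loglik - reduced$loglik)
  df <- full$n_par - reduced$n_par
  if (df < 1) stop("models are not nested with positive df")
  list(statistic = stat, df = df,
       p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
}

# Wald p for a candidate's main-effect coefficient(s); factors with 2 levels
# have a single coefficient. Multi-coefficient terms fall back to the LRT.
candidate_entry_p <- function(fit, reduced, candidate) {
  co <- fit$coefficients
  hit <- co$term == candidate |
    startsWith(co$term, candidate) & !grepl(":", co$term)
  hit <- hit & co$term != "(Intercept)"
  if (sum(hit) == 1) {
    list(p = co$p[hit], type = "wald", estimate = co$estimate[hit])
  } else {
    lt <- lrt_glmm(fit, reduced)
    list(p = lt$p, type = "lrt",
         estimate = if (any(hit)) co$estimate[which(hit)[1]] else NA_real_)
  }
}

#' Screen one candidate for a timepoint interaction
#'
#' Fits `timepoint + candidate + candidate:timepoint` on rows complete for
#' the candidate and tests the interaction block with a likelihood-ratio
#' test. If the interaction is not significant (p >= 0.05) the model is
#' refit without it.
#'
#' @param data modeling data frame (see [prepare_model_data()])
#' @param candidate covariate name
#' @param alpha significance level for the interaction LRT
#' @param min_rows minimum complete rows required
#' @return list: `keep_interaction`, `model` (the retained `glmm_fit`),
#'   `interaction_p`, `entry_p` (candidate p value for the entry gate),
#'   `entry_p_type`, `n_used`, `rows_dropped`
#' @export
screen_interaction <- function(data, candidate, alpha = 0.05, min_rows = 10) {
  if (!candidate %in% names(data)) stop("unknown candidate: ", candidate)
  keep <- !is.na(data[[candidate]])
  sub <- data[keep, , drop = FALSE]
  if (nrow(sub) < min_rows)
    stop(sprintf("candidate '%s' has %d complete rows (< %d)",
                 candidate, nrow(sub), min_rows))
  if (length(unique(sub$timepoint)) < 2)
    stop("interaction with timepoint is inestimable: only one timepoint level in the data")
  main <- fit_glmm(sub, fixed_terms = candidate)
  withx <- fit_glmm(sub, fixed_terms = candidate, interactions = candidate)
  lt <- lrt_glmm(withx, main)
  keep_int <- lt$p < alpha
  model <- if (keep_int) withx else main
  base <- fit_glmm(sub)   # timepoint-only, for the entry gate
  # the entry gate always uses the candidate's marginal (no-interaction)
  # p value; gating on the interaction block conditional on a significant
  # screen would inflate the null entry rate well above the nominal 5%
  ep <- candidate_entry_p(main, base, candidate)
  list(keep_interaction = keep_int, model = model,
       interaction_p = lt$p,
       entry_p = ep$p, entry_p_type = ep$type, entry_estimate = ep$estimate,
       n_used = nrow(sub), rows_dropped = sum(!keep))
}

#' Forward selection of dispersal covariates
#'
#' Implements the two-phase protocol described in [dispersal_models].
#' Ties on AIC are broken by fewer parameters, then candidate input order.
#'
#' @param data modeling data frame (see [prepare_model_data()])
#' @param candidates character vector of covariate names to consider
#' @param alpha entry significance gate for the first variable
#' @param aic_threshold minimum AIC decrease for accepting a later variable
#' @param include_timepoint `FALSE` for single-timepoint strata (also
#'   disables interaction screening)
#' @param min_rows minimum complete rows for a candidate to be screened
#' @return list: `model` (final `glmm_fit`), `trace` (a `selection_trace`:
#'   list of per-step records), `selected`, `interactions`
#' @export
forward_select <- function(data, candidates, alpha = 0.05, aic_threshold = 3,
                           include_timepoint = TRUE, min_rows = 10) {
  if (!length(candidates)) stop("candidate list is empty")
  trace <- list()
  screen_int <- include_timepoint && length(unique(data$timepoint)) > 1
  # --- phase 1: candidate-wise complete rows, interaction screen, p gate ---
  step1 <- lapply(candidates, function(cand) {
    keep <- !is.na(data[[cand]])
    sub <- data[keep, , drop = FALSE]
    if (nrow(sub) < min_rows || length(unique(sub$subject_id)) < 2)
      return(list(candidate = cand, skipped = TRUE,
                  reason = sprintf("only %d complete rows", nrow(sub))))
    if (screen_int) {
      sc <- try(screen_interaction(data, cand, alpha = alpha,
                                   min_rows = min_rows), silent = TRUE)
      if (inherits(sc, "try-error"))
        return(list(candidate = cand, skipped = TRUE,
                    reason = conditionMessage(attr(sc, "condition"))))
      list(candidate = cand, skipped = FALSE,
           keep_interaction = sc$keep_interaction,
           interaction_p = sc$interaction_p,
           entry_p = sc$entry_p, entry_p_type = sc$entry_p_type,
           estimate = sc$entry_estimate, n_used = sc$n_used,
           rows_dropped = sc$rows_dropped)
    } else {
      res <- try({
        main <- fit_glmm(sub, fixed_terms = cand,
                         include_timepoint = include_timepoint)
        base <- fit_glmm(sub, include_timepoint = include_timepoint)
        ep <- candidate_entry_p(main, base, cand)
        list(candidate = cand, skipped = FALSE, keep_interaction = FALSE,
             interaction_p = NA_real_,
             entry_p = ep$p, entry_p_type = ep$type, estimate = ep$estimate,
             n_used = nrow(sub), rows_dropped = sum(!keep))
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        res <- list(candidate = cand, skipped = TRUE,
                    reason = conditionMessage(attr(res, "condition")))
      res
    }
  })
  names(step1) <- candidates
  ok <- !vapply(step1, `[[`, logical(1), "skipped")
  ps <- vapply(step1[ok], `[[`, numeric(1), "entry_p")
  trace[[1]] <- list(step = 1L, phase = "p_gate", candidates = step1,
                     decision = NA_character_)
  interactions_kept <- character(0)
  if (!any(ok) || min(ps) >= alpha) {
    trace[[1]]$decision <- "none below alpha: timepoint-only model"
    final <- fit_glmm(data, include_timepoint = include_timepoint)
    return(structure(list(model = final, trace = trace,
                          selected = character(0),
                          interactions = character(0)),
                     class = "forward_selection"))
  }
  first <- names(ps)[order(ps, match(names(ps), candidates))][1]
  if (isTRUE(step1[[first]]$keep_interaction))
    interactions_kept <- first
  trace[[1]]$decision <- sprintf("enter '%s' (p = %.4g)", first, ps[first])
  selected <- first
  remaining <- setdiff(candidates, first)

  # --- phase >= 2: all-candidate complete rows, AIC gate ---
  cc <- stats::complete.cases(data[, candidates, drop = FALSE])
  data_cc <- data[cc, , drop = FALSE]
  if (!nrow(data_cc)) stop("no rows complete for all candidates")
  current <- fit_glmm(data_cc, fixed_terms = selected,
                      interactions = interactions_kept,
                      include_timepoint = include_timepoint)
  step_no <- 1L
  while (length(remaining)) {
    step_no <- step_no + 1L
    cand_fits <- lapply(remaining, function(cand) {
      ints <- interactions_kept
      if (screen_int && isTRUE(step1[[cand]]$keep_interaction))
        ints <- c(ints, cand)
      # a candidate can be degenerate on the complete-case rows (e.g. a
      # factor collapsing to one level); such candidates are unavailable
      try(fit_glmm(data_cc, fixed_terms = c(selected, cand),
                   interactions = ints,
                   include_timepoint = include_timepoint), silent = TRUE)
    })
    names(cand_fits) <- remaining
    failed <- vapply(cand_fits, inherits, logical(1), "try-error")
    cand_fits <- cand_fits[!failed]
    remaining_ok <- remaining[!failed]
    if (!length(cand_fits)) {
      trace[[step_no]] <- list(step = step_no, phase = "aic_gate",
                               decision = "stop: no estimable candidates left",
                               n_used = nrow(data_cc))
      break
    }
    aics <- vapply(cand_fits, `[[`, numeric(1), "aic")
    npars <- vapply(cand_fits, `[[`, numeric(1), "n_par")
    ord <- order(aics, npars, match(remaining_ok, candidates))
    best <- remaining_ok[ord[1]]
    accepted <- current$aic - aics[best] >= aic_threshold
    trace[[step_no]] <- list(
      step = step_no, phase = "aic_gate",
      current_aic = current$aic,
      candidate_aic = aics,
      decision = if (accepted)
        sprintf("enter '%s' (AIC %.3f -> %.3f)", best, current$aic, aics[best])
      else
        sprintf("stop: best candidate '%s' improves AIC by %.3f < %g",
                best, current$aic - aics[best], aic_threshold),
      n_used = nrow(data_cc))
    if (!accepted) break
    selected <- c(selected, best)
    if (screen_int && isTRUE(step1[[best]]$keep_interaction))
      interactions_kept <- c(interactions_kept, best)
    current <- cand_fits[[best]]
    remaining <- setdiff(remaining, best)
  }

  # --- final refit: drop only rows missing in SELECTED variables ---
  cc_sel <- stats::complete.cases(data[, selected, drop = FALSE])
  final <- fit_glmm(data[cc_sel, , drop = FALSE], fixed_terms = selected,
                    interactions = interactions_kept,
                    include_timepoint = include_timepoint)
  trace[[length(trace) + 1]] <- list(
    step = length(trace) + 1L, phase = "final_refit",
    decision = sprintf("refit on %d rows complete for {%s}",
                       sum(cc_sel), paste(selected, collapse = ", ")))
  structure(list(model = final, trace = trace, selected = selected,
                 interactions = interactions_kept),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("Forward selection: selected {",
      paste(x$selected, collapse = ", "), "}",
      if (length(x$interactions))
        paste0(" with timepoint interaction(s): ",
               paste(x$interactions, collapse = ", ")),
      "\n", sep = "")
  for (st in x$trace)
    if (!is.na(st$decision)) cat(sprintf("  step %d [%s]: %s\n",
                                         st$step, st$phase, st$decision))
  print(x$model)
  invisible(x)
}

#' Per-timepoint forward selection
#'
#' Reruns [forward_select()] within each timepoint's rows, with timepoint
#' removed from the fixed effects and the subject random intercept
#' retained. Strata with fewer than `min_obs` rows are skipped with a
#' logged reason.
#'
#' @inheritParams forward_select
#' @param min_obs minimum rows per timepoint stratum (default 15)
#' @return named list per timepoint: either a `forward_selection` or a
#'   list with `skipped = TRUE` and `reason`
#' @export
per_timepoint_models <- function(data, candidates, alpha = 0.05,
                                 aic_threshold = 3, min_obs = 15,
                                 min_rows = 10) {
  out <- list()
  for (tp in levels(droplevels(factor(data$timepoint)))) {
    sub <- data[data$timepoint == tp, , drop = FALSE]
    if (nrow(sub) < min_obs) {
      out[[tp]] <- list(skipped = TRUE,
                        reason = sprintf("only %d observations (< %d)",
                                         nrow(sub), min_obs))
      next
    }
    out[[tp]] <- forward_select(sub, candidates, alpha = alpha,
                                aic_threshold = aic_threshold,
                                include_timepoint = FALSE,
                                min_rows = min_rows)
  }
  out
}

#' Simulation-based residual diagnostics
#'
#' Simulates `n_sim` response vectors from the fitted model (new binomial
#' noise, random intercepts redrawn from the fitted SD), converts each
#' observation to a scaled quantile residual
#' `(#\{sim < obs\} + U (#\{sim = obs\} + 1)) / (n_sim + 1)` with
#' `U ~ Uniform(0, 1)`, and tests uniformity with a Kolmogorov-Smirnov test.
#' The dispersion ratio compares the variance of observed Pearson residuals
#' with its simulated distribution (two-sided empirical p).
#'
#' @param fit a converged `glmm_fit`
#' @param data the data the model was fit on
#' @param n_sim number of simulations (>= 100; default 250)
#' @param seed integer seed
#' @return list of class `residual_diagnostics`: `scaled_residuals`,
#'   `ks_statistic`, `ks_p`, `dispersion_ratio`, `dispersion_p`, `n_sim`,
#'   `seed`
#' @export
simulate_residuals <- function(fit, data, n_sim = 250, seed = 1L) {
  if (!inherits(fit, "glmm_fit")) stop("fit must be a glmm_fit")
  if (!fit$converged) stop("residual simulation requires a converged fit")
  if (n_sim < 100) stop("n_sim must be >= 100")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sims <- stats::simulate(fit$fit, nsim = n_sim, use.u = FALSE,
                          allow.new.levels = TRUE)
  k_sim <- vapply(sims, function(s) s[, 1], numeric(fit$n_obs))  # successes
  k_obs <- data$k
  n_tr <- data$n
  u <- stats::runif(fit$n_obs)
  below <- rowSums(k_sim < k_obs)
  ties <- rowSums(k_sim == k_obs)
  scaled <- (below + u * (ties + 1)) / (n_sim + 1)
  ks <- suppressWarnings(stats::ks.test(scaled, "punif"))
  # dispersion: variance of Pearson residuals vs its simulated distribution.
  # Population-level expectations (random effects marginalized out), so the
  # observed and simulated residuals are referenced to the same mean.
  p_hat <- stats::predict(fit$fit, re.form = NA, type = "response")
  pearson <- function(k) (k - n_tr * p_hat) / sqrt(n_tr * p_hat * (1 - p_hat))
  v_obs <- stats::var(pearson(k_obs))
  v_sim <- apply(k_sim, 2, function(k) stats::var(pearson(k)))
  ratio <- v_obs / mean(v_sim)
  p_hi <- (1 + sum(v_sim >= v_obs)) / (1 + n_sim)
  p_lo <- (1 + sum(v_sim <= v_obs)) / (1 + n_sim)
  structure(list(scaled_residuals = scaled,
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
                 dispersion_ratio = ratio,
                 dispersion_p = min(1, 2 * min(p_hi, p_lo)),
                 n_sim = n_sim, seed = seed),
            class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf("Scaled-residual diagnostics (%d simulations)\n", x$n_sim))
  cat(sprintf("  KS uniformity: D = %.4f, p = %.4g\n", x$ks_statistic, x$ks_p))
  cat(sprintf("  dispersion ratio = %.3f, p = %.4g\n",
              x$dispersion_ratio, x$dispersion_p))
  invisible(x)
}
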