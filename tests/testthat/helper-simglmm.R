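# Direct simulator of binomial random-intercept GLMM data, used for
# model-level operating-characteristic tests (independent of the full
# community generator).
#
# beta_x: slope on a standard-normal subject-level covariate "x";
# beta_int: extra per-timepoint slope offsets (named A/W) creating a true
# x:timepoint interaction when nonzero.
sim_glmm_data <- function(seed, n_subjects = 34, timepoints = c("S", "A", "W"),
                          intercept = -2, beta_x = 0, sd_subject = 0.5,
                          n_trials = 100, tp_offsets = c(A = 0.2, W = 0.5),
                          beta_int = c(A = 0, W = 0)) {
  set.seed(seed)
  b <- rnorm(n_subjects, 0, sd_subject)
  x <- rnorm(n_subjects)
  df <- expand.grid(subject = seq_len(n_subjects), timepoint = timepoints,
                    stringsAsFactors = FALSE)
  df$subject_id <- sprintf("s%03d", df$subject)
  df$x <- x[df$subject]
  off <- c(S = 0, tp_offsets)[df$timepoint]
  slope <- beta_x + c(S = 0, beta_int)[df$timepoint]
  eta <- intercept + slope * df$x + off + b[df$subject]
  df$n <- n_trials
  df$k <- rbinom(nrow(df), n_trials, plogis(eta))
  df$timepoint <- factor(df$timepoint, levels = c("S", "A", "W"))
  df$timepoint <- droplevels(df$timepoint)
  df[, c("k", "n", "subject_id", "timepoint", "x")]
}
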