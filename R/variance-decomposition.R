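#' Participant/trial/residual variance decomposition
#'
#' ANOVA-style partition of per-timepoint index values into three nested
#' components: across-participant (variance of participant means about the
#' grand mean), across-trial (group-size-weighted variance of trial means
#' about their participant means), and residual (within-trial variance).
#' With group-size weights the three sums of squares add up to the total sum
#' of squares exactly (law of total variance), so the three reported
#' proportions sum to 1 to machine precision on any input.
#'
#' @param values Numeric vector of per-timepoint values.
#' @param participant Participant label per value.
#' @param trial Trial label per value (unique within participant, or jointly
#'   with `participant`).
#' @return A `variance_components` object: the three proportions
#'   (`prop_participants`, `prop_trials`, `prop_residual`), the raw variance
#'   components (sums of squares over n), `sigma2_total`, and group counts.
#' @export
decompose_variance <- function(values, participant, trial) {
  n <- length(values)
  stopifnot(length(participant) == n, length(trial) == n)
  if (anyNA(values)) stop("values must not contain NA")
  dt <- data.table::data.table(v = values,
                               p = as.character(participant),
                               tr = paste(participant, trial, sep = "\r"))
  if (length(unique(dt$p)) < 2L) stop("need at least 2 participants")
  trials_per_p <- dt[, .(k = length(unique(tr))), by = p]$k
  if (any(trials_per_p < 2L))
    warning("a participant with a single trial contributes no trial component")
  gm <- mean(dt$v)
  pm <- dt[, .(m = mean(v), n = .N), by = p]
  tm <- dt[, .(m = mean(v), n = .N, p = p[1]), by = tr]
  tm <- merge(tm, pm[, .(p, pmean = m)], by = "p")
  ss_p <- sum(pm$n * (pm$m - gm)^2)
  ss_t <- sum(tm$n * (tm$m - tm$pmean)^2)
  wt <- dt[, .(resid = v - mean(v)), by = tr]
  ss_r <- sum(wt$resid^2)
  ss_tot <- sum((dt$v - gm)^2)
  if (ss_tot <= 0) stop("total variance is zero; decomposition undefined")
  structure(list(
    prop_participants = ss_p / ss_tot,
    prop_trials = ss_t / ss_tot,
    prop_residual = ss_r / ss_tot,
    sigma2_participants = ss_p / n,
    sigma2_trials = ss_t / n,
    sigma2_residual = ss_r / n,
    sigma2_total = ss_tot / n,
    n = n, n_participants = nrow(pm), n_trials = nrow(tm)
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance decomposition (proportions of total variance)\n")
  cat(sprintf("  participants: %6.2f%%\n", 100 * x$prop_participants))
  cat(sprintf("  trials:       %6.2f%%\n", 100 * x$prop_trials))
  cat(sprintf("  residual:     %6.2f%%\n", 100 * x$prop_residual))
  cat(sprintf("  (%d values, %d participants, %d trials; total sigma^2 = %.4g)\n",
              x$n, x$n_participants, x$n_trials, x$sigma2_total))
  invisible(x)
}

#' Permutation null for the variance decomposition
#'
#' Jointly shuffles the (participant, trial) label pair across data points
#' `n_perm` times, recomputing the decomposition each time. Because the
#' grand mean and total sum of squares are invariant under permutation, the
#' null distributions concern only the participant- and trial-level
#' proportions; one-sided p-values use the add-one convention
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param values,participant,trial As in [decompose_variance()].
#' @param n_perm Number of permutations. Default `1000`.
#' @param seed Integer seed.
#' @return A `variance_permutation` object: the observed decomposition,
#'   matrices of null proportions, p-values, and summary means of the null
#'   proportions (including `mean_null_combined`, the mean of the
#'   participant- and trial-level null proportions).
#' @export
permutation_test <- function(values, participant, trial, n_perm = 1000L,
                             seed = 1L) {
  stopifnot(n_perm >= 1L)
  obs <- decompose_variance(values, participant, trial)
  n <- length(values)
  # jointly permuting the (participant, trial) label pair across points is
  # the same as permuting the values over the fixed label structure, so the
  # group index vectors can be prepared once
  t_key <- paste(participant, trial, sep = "\r")
  t_id <- as.integer(factor(t_key, levels = unique(t_key)))
  p_of_t <- as.integer(factor(participant[!duplicated(t_key)]))
  n_t <- tabulate(t_id)
  n_p <- drop(rowsum(n_t, p_of_t))
  gm <- mean(values)
  ss_tot <- sum((values - gm)^2) # permutation-invariant
  null_p <- numeric(n_perm)
  null_t <- numeric(n_perm)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_perm)) {
      v <- values[sample.int(n)]
      sum_t <- drop(rowsum(v, t_id))
      tm <- sum_t / n_t
      pm <- drop(rowsum(sum_t, p_of_t)) / n_p
      null_p[b] <- sum(n_p * (pm - gm)^2) / ss_tot
      null_t[b] <- sum(n_t * (tm - pm[p_of_t])^2) / ss_tot
    }
  })
  structure(list(
    observed = obs,
    null_participants = null_p,
    null_trials = null_t,
    p_participants = (1 + sum(null_p >= obs$prop_participants)) / (n_perm + 1),
    p_trials = (1 + sum(null_t >= obs$prop_trials)) / (n_perm + 1),
    mean_null_participants = mean(null_p),
    mean_null_trials = mean(null_t),
    mean_null_combined = mean(c(mean(null_p), mean(null_t))),
    n_perm = n_perm
  ), class = "variance_permutation")
}

#' @export
print.variance_permutation <- function(x, ...) {
  print(x$observed)
  cat(sprintf("Permutation null (%d joint label shuffles):\n", x$n_perm))
  cat(sprintf("  participants: null mean %.3f%%, p = %.4g\n",
              100 * x$mean_null_participants, x$p_participants))
  cat(sprintf("  trials:       null mean %.3f%%, p = %.4g\n",
              100 * x$mean_null_trials, x$p_trials))
  invisible(x)
}

#' Variance decomposition table for sensitivity indices
#'
#' Applies [decompose_variance()] (and optionally [permutation_test()]) to
#' each index column of a [sensitivity_records()] data.frame.
#'
#' @param records Sensitivity records (or any data.frame with
#'   `participant_id`, `trial_id`, and numeric index columns).
#' @param columns Index columns; defaults to every `nu_*` column plus
#'   `varsigma`.
#' @param n_perm Permutations per column (0 to skip the null).
#' @param seed Integer seed.
#' @return A data.frame with one row per index: the three proportions and,
#'   if requested, permutation p-values.
#' @export
decompose_indices <- function(records, columns = NULL, n_perm = 0L, seed = 1L) {
  if (is.null(columns))
    columns <- c(grep("^nu_", names(records), value = TRUE),
                 intersect("varsigma", names(records)))
  rows <- lapply(columns, function(cl) {
    v <- records[[cl]]
    if (n_perm > 0L) {
      pt <- permutation_test(v, records$participant_id, records$trial_id,
                             n_perm = n_perm, seed = seed)
      d <- pt$observed
      data.frame(index = cl,
                 prop_participants = d$prop_participants,
                 prop_trials = d$prop_trials,
                 prop_residual = d$prop_residual,
                 p_participants = pt$p_participants,
                 p_trials = pt$p_trials)
    } else {
      d <- decompose_variance(v, records$participant_id, records$trial_id)
      data.frame(index = cl,
                 prop_participants = d$prop_participants,
                 prop_trials = d$prop_trials,
                 prop_residual = d$prop_residual)
    }
  })
  do.call(rbind, rows)
}
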