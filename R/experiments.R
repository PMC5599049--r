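#' Sweep the branching parameter of a target cistrome
#'
#' The criticality-curve protocol: for each value of `m`, run an ensemble
#' (default 200 runs of 1000 timesteps) with the target cistrome started
#' fully saturated (`s0 = r`) and any partner cistromes held at fixed
#' branching values, and record the fraction of runs in which the target is
#' still active at the final timestep.
#'
#' The system passed in should contain exactly the target plus the held
#' partners (use [subset_system()] to carve these out of a larger system).
#' The same master seed is reused across `m` values (common random numbers),
#' which makes the survival curve monotone checks well behaved.
#'
#' @param system A [cistrome_system()] containing `target` and all held
#'   partners.
#' @param target Name of the swept cistrome.
#' @param m_values Strictly increasing integer branching values to sweep.
#' @param held List of partner settings, each
#'   `list(cistrome = , m = , s0 = )` (`s0 = NULL` means `r`).
#' @param n_runs,timesteps Ensemble size and horizon per `m`.
#' @param seed Master seed.
#' @param mode Transfer mode (see [sim_config()]).
#' @param s0_target Initial activation of the target (`NULL` = `r`).
#' @param layout_seed Seed for the segment-index assignment.
#' @param stop_at_first_survivor If `TRUE`, sweep upward and stop after the
#'   first `m` with a nonzero survival fraction (the remaining values are
#'   not run); the result still brackets the critical value.
#' @return A `sweep_result`: list with `result` (data.frame of `m`,
#'   `survival_fraction`, `n_runs`), `target`, `held`, `timesteps`, `mode`,
#'   `seed`.
#' @examples
#' sw <- sweep_m(cistrome_preset("tiny_single"), "TfA", m_values = 1:4,
#'               n_runs = 50, timesteps = 200, seed = 1)
#' sw$result
#' @export
sweep_m <- function(system, target, m_values, held = list(),
                    n_runs = 200L, timesteps = 1000L, seed = 1L,
                    mode = c("meanfield", "two_site"), s0_target = NULL,
                    layout_seed = 1L, stop_at_first_survivor = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(system, "cistrome_system"), target %in% system$names,
            length(m_values) >= 1L, !is.unsorted(m_values, strictly = TRUE))
  held_names <- vapply(held, `[[`, character(1), "cistrome")
  if (target %in% held_names)
    stop("held cistromes must be distinct from the target", call. = FALSE)
  stopifnot(all(held_names %in% system$names))

  layout <- generate_layout(system, seed = layout_seed)
  r <- system$r
  m_base <- setNames(numeric(length(system$names)), system$names)
  s0 <- setNames(as.numeric(r), system$names)
  for (h in held) {
    m_base[[h$cistrome]] <- h$m
    s0[[h$cistrome]] <- if (is.null(h$s0)) r[[h$cistrome]] else h$s0
  }
  s0[[target]] <- if (is.null(s0_target)) r[[target]] else s0_target

  rows <- list()
  for (m in m_values) {
    mv <- m_base
    mv[[target]] <- m
    en <- run_ensemble(layout,
                       sim_config(m = mv, s0 = s0, timesteps = timesteps,
                                  mode = mode),
                       n_runs = n_runs, seed = seed)
    frac <- en$survival_fraction[[target]]
    rows[[length(rows) + 1L]] <- data.frame(m = m, survival_fraction = frac,
                                            n_runs = n_runs)
    if (stop_at_first_survivor && frac > 0) break
  }
  structure(list(result = do.call(rbind, rows), target = target,
                 held = held, timesteps = as.integer(timesteps),
                 n_runs = as.integer(n_runs), mode = mode,
                 seed = seed, system = system),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> target %s (%d runs x %d steps, mode %s)\n",
              x$target, x$n_runs, x$timesteps, x$mode))
  if (length(x$held))
    for (h in x$held) cat(sprintf("  held: %s at m = %g\n", h$cistrome, h$m))
  print(x$result, row.names = FALSE)
  invisible(x)
}

#' Estimate the critical branching value from a sweep
#'
#' Applies a detection rule to a survival-fraction curve.  The default
#' `any_survivor` rule defines the critical value as the smallest swept `m`
#' at which at least one run survives to the final timestep, matching the
#' operational definition used for the criticality-curve figures (all runs
#' dissipate below the critical value).  The `fraction` rule instead
#' requires `survival_fraction >= threshold` and is exposed for sensitivity
#' analysis.
#'
#' The sweep must bracket the transition: at least one swept `m` must fail
#' the rule below the estimate.  All-zero or all-passing sweeps are an
#' error, not an extrapolation.
#'
#' @param sweep A [sweep_m()] result.
#' @param rule `"any_survivor"` (default) or `"fraction"`.
#' @param threshold Survival-fraction cut-off for the `"fraction"` rule.
#' @return A `criticality_estimate`: list with `m_crit` (integer), `rule`,
#'   and the supporting `sweep`.
#' @examples
#' sw <- sweep_m(cistrome_preset("tiny_single"), "TfA", m_values = 1:4,
#'               n_runs = 50, timesteps = 200, seed = 1)
#' estimate_mcrit(sw)$m_crit
#' @export
estimate_mcrit <- function(sweep, rule = c("any_survivor", "fraction"),
                           threshold = 0.5) {
  rule <- match.arg(rule)
  stopifnot(inherits(sweep, "sweep_result"))
  df <- sweep$result
  pass <- if (rule == "any_survivor") df$survival_fraction > 0
          else df$survival_fraction >= threshold
  if (!any(pass))
    stop("sweep does not bracket the critical value: no swept m passes the rule",
         call. = FALSE)
  first <- which(pass)[1]
  if (first == 1L)
    stop("sweep does not bracket the critical value: the smallest swept m ",
         "already passes the rule", call. = FALSE)
  structure(list(m_crit = as.integer(df$m[first]), rule = rule,
                 threshold = if (rule == "fraction") threshold else NA_real_,
                 sweep = sweep),
            class = "criticality_estimate")
}

#' @export
print.criticality_estimate <- function(x, ...) {
  cat(sprintf("<criticality_estimate> m_crit = %d (rule: %s) for %s\n",
              x$m_crit, x$rule, x$sweep$target))
  invisible(x)
}

#' Ignition of a dissipated cistrome by an active partner
#'
#' Starts the driver cistrome fully saturated (`s0 = r`) at its branching
#' value and the driven cistrome fully dissipated (`s0 = 0`), and records,
#' per run, whether the driven cistrome ever became active (via TF
#' transferred through shared segments), the first timestep at which it did,
#' and whether it was still active at the end.
#'
#' @param system A [cistrome_system()] containing both cistromes.
#' @param driver `list(cistrome = , m = )` for the igniting cistrome.
#' @param driven `list(cistrome = , m = )` for the initially dissipated one.
#' @param timesteps,n_runs,seed Ensemble settings.
#' @param mode Transfer mode.
#' @param layout_seed Seed for the segment-index assignment.
#' @return An `ignition_result`: list with per-run data.frame `runs`
#'   (`ignited`, `time_to_ignition`, `survived`), summary fractions, and the
#'   settings.
#' @examples
#' ig <- ignition_experiment(cistrome_preset("tiny_coupled"),
#'                           driver = list(cistrome = "TfA", m = 4),
#'                           driven = list(cistrome = "TfB", m = 3),
#'                           timesteps = 200, n_runs = 20, seed = 1)
#' ig$fraction_ignited
#' @export
ignition_experiment <- function(system, driver, driven, timesteps = 1000L,
                                n_runs = 200L, seed = 1L,
                                mode = c("meanfield", "two_site"),
                                layout_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(system, "cistrome_system"),
            driver$cistrome %in% system$names,
            driven$cistrome %in% system$names,
            driver$cistrome != driven$cistrome)
  sub <- subset_system(system, c(driver$cistrome, driven$cistrome))
  layout <- generate_layout(sub, seed = layout_seed)
  m <- setNames(c(driver$m, driven$m), c(driver$cistrome, driven$cistrome))
  s0 <- setNames(c(sub$r[[driver$cistrome]], 0),
                 c(driver$cistrome, driven$cistrome))
  en <- run_ensemble(layout,
                     sim_config(m = m, s0 = s0, timesteps = timesteps,
                                mode = mode),
                     n_runs = n_runs, seed = seed)
  tti <- en$first_active[, driven$cistrome]
  runs <- data.frame(run = seq_len(n_runs),
                     ignited = tti >= 0L,
                     time_to_ignition = ifelse(tti >= 0L, tti, NA_integer_),
                     survived = en$survived[, driven$cistrome])
  structure(list(runs = runs,
                 fraction_ignited = mean(runs$ignited),
                 fraction_survived = mean(runs$survived),
                 median_time_to_ignition =
                   stats::median(runs$time_to_ignition, na.rm = TRUE),
                 driver = driver, driven = driven, sigma =
                   sub$sigma[driver$cistrome, driven$cistrome],
                 timesteps = as.integer(timesteps),
                 n_runs = as.integer(n_runs), mode = mode, seed = seed,
                 ensemble = en),
            class = "ignition_result")
}

#' @export
print.ignition_result <- function(x, ...) {
  cat(sprintf("<ignition_result> %s (m = %g, s0 = r) driving %s (m = %g, s0 = 0), sigma = %d\n",
              x$driver$cistrome, x$driver$m, x$driven$cistrome, x$driven$m,
              x$sigma))
  cat(sprintf("  ignited %.0f%% of %d runs (median time to ignition %s); survived to T: %.0f%%\n",
              100 * x$fraction_ignited, x$n_runs,
              format(x$median_time_to_ignition),
              100 * x$fraction_survived))
  invisible(x)
}

#' Reduction of the critical branching value under coupling
#'
#' Sweeps the target cistrome's branching value while the partners are held
#' at fixed values (their own observed critical values, in the classic
#' protocol) with `s0 = r`, estimates the coupled critical value with
#' [estimate_mcrit()], and reports the change relative to the uncoupled
#' value.
#'
#' @param system A [cistrome_system()] containing the target and partners.
#' @param target Name of the target cistrome.
#' @param partners List of `list(cistrome = , m = )` held partners.
#' @param m_values Integer sweep values for the target (must bracket).
#' @param uncoupled_mcrit The target's single-cistrome critical value, for
#'   the delta; if `NULL` it is estimated here with a single-cistrome sweep
#'   over the same `m_values`.
#' @param rule,threshold Passed to [estimate_mcrit()].
#' @inheritParams sweep_m
#' @return A `coupling_reduction` object: list with `sweep`, `estimate`,
#'   `coupled_mcrit`, `uncoupled_mcrit`, `reduction`.
#' @export
coupling_reduction <- function(system, target, partners, m_values,
                               uncoupled_mcrit = NULL,
                               n_runs = 200L, timesteps = 1000L, seed = 1L,
                               mode = c("meanfield", "two_site"),
                               rule = c("any_survivor", "fraction"),
                               threshold = 0.5, layout_seed = 1L,
                               stop_at_first_survivor = FALSE) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  pnames <- vapply(partners, `[[`, character(1), "cistrome")
  sub <- subset_system(system, c(target, pnames))
  sw <- sweep_m(sub, target, m_values, held = partners, n_runs = n_runs,
                timesteps = timesteps, seed = seed, mode = mode,
                layout_seed = layout_seed,
                stop_at_first_survivor = stop_at_first_survivor)
  est <- estimate_mcrit(sw, rule = rule, threshold = threshold)
  if (is.null(uncoupled_mcrit)) {
    sw0 <- sweep_m(subset_system(system, target), target, m_values,
                   n_runs = n_runs, timesteps = timesteps, seed = seed,
                   mode = mode, layout_seed = layout_seed,
                   stop_at_first_survivor = stop_at_first_survivor)
    uncoupled_mcrit <- estimate_mcrit(sw0, rule = rule,
                                      threshold = threshold)$m_crit
  }
  structure(list(sweep = sw, estimate = est,
                 coupled_mcrit = est$m_crit,
                 uncoupled_mcrit = as.integer(uncoupled_mcrit),
                 reduction = as.integer(uncoupled_mcrit) - est$m_crit,
                 target = target, partners = partners, mode = mode),
            class = "coupling_reduction")
}

#' @export
print.coupling_reduction <- function(x, ...) {
  held <- paste(vapply(x$partners, function(h)
    sprintf("%s@%g", h$cistrome, h$m), character(1)), collapse = " + ")
  cat(sprintf("<coupling_reduction> %s coupled to %s: m_crit %d -> %d (reduction %d)\n",
              x$target, held, x$uncoupled_mcrit, x$coupled_mcrit, x$reduction))
  invisible(x)
}
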