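#' Simulation configuration
#'
#' Bundles the per-cistrome branching parameters and initial activations with
#' the horizon and transfer mode.
#'
#' @param m Branching parameter(s): TF units emitted per active segment per
#'   timestep.  A single value is recycled; otherwise a vector named by
#'   cistrome.  Values are integers in all the classic sweeps; a fractional
#'   part is honoured by emitting `floor(m)` units plus one more with
#'   probability `m - floor(m)` per active segment.
#' @param s0 Initial number of active producing segments per cistrome, `0 <=
#'   s0 <= r`.  Default `NULL` means fully saturated (`s0 = r`).  A single
#'   value is recycled; use a named vector for per-cistrome values (e.g. a
#'   driver at `r` and a driven cistrome at 0).
#' @param timesteps Number of timesteps `T` (the trajectory has `T + 1`
#'   entries including `t = 0`).
#' @param mode Transfer mode for shared segments.  `"meanfield"` (default):
#'   a TF landing on a shared segment transfers to a partner and activates
#'   the counterpart segment there, without activating the source segment;
#'   the step expectation then matches the infinite-limit recursion.
#'   `"two_site"`: each segment has a primary site for own-cistrome TF and a
#'   single secondary site for one incoming foreign TF; occupied primaries on
#'   shared segments copy a TF to a free counterpart secondary, and a segment
#'   with either site occupied is active next step.
#' @return A `sim_config` object.
#' @export
sim_config <- function(m, s0 = NULL, timesteps = 1000L,
                       mode = c("meanfield", "two_site")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(m), all(m >= 0), timesteps >= 1L)
  if (!is.null(s0)) stopifnot(is.numeric(s0), all(s0 >= 0))
  structure(list(m = m, s0 = s0, timesteps = as.integer(timesteps),
                 mode = mode),
            class = "sim_config")
}

# resolve recycled / named per-cistrome parameter vectors against a layout
resolve_per_cistrome <- function(x, nms, what, default = NULL) {
  if (is.null(x)) {
    if (is.null(default)) stop("missing '", what, "'", call. = FALSE)
    return(setNames(default, nms))
  }
  if (length(x) == 1L && is.null(names(x))) return(setNames(rep(x, length(nms)), nms))
  if (!is.null(names(x))) {
    missing <- setdiff(nms, names(x))
    if (length(missing))
      stop(what, " missing for cistrome(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    return(x[nms])
  }
  if (length(x) == length(nms)) return(setNames(x, nms))
  stop("'", what, "' must be length 1, named, or one per cistrome", call. = FALSE)
}

resolve_config <- function(layout, config) {
  stopifnot(inherits(layout, "segment_layout"), inherits(config, "sim_config"))
  nms <- layout$system$names
  r <- layout$system$r
  m <- resolve_per_cistrome(config$m, nms, "m")
  s0 <- resolve_per_cistrome(config$s0, nms, "s0", default = unname(r))
  s0 <- floor(s0)
  if (any(s0 > r))
    stop("s0 exceeds r for cistrome(s): ",
         paste(nms[s0 > r], collapse = ", "), call. = FALSE)
  list(m = as.numeric(m), s0 = as.integer(s0), T = config$timesteps,
       mode_int = match(config$mode, c("meanfield", "two_site")) - 1L)
}

#' Draw an initial active-segment state
#'
#' Chooses, for each cistrome, `s0` producing segments uniformly at random
#' without replacement (all of them when `s0 = r`, none when `s0 = 0`) and
#' returns the explicit segment ids.  The engine itself only tracks active
#' counts — which particular segments start active does not affect the
#' distribution of any trajectory — so this function mainly serves the
#' brute-force reference simulator and introspection.
#'
#' @param layout A [generate_layout()] result.
#' @param s0 Initial activation count(s), recycled or named per cistrome.
#' @param seed Integer seed.
#' @return Named list of active producing-segment id vectors.
#' @export
init_state <- function(layout, s0, seed = 1L) {
  stopifnot(inherits(layout, "segment_layout"))
  nms <- layout$system$names
  s0 <- floor(resolve_per_cistrome(s0, nms, "s0"))
  r <- layout$system$r
  if (any(s0 > r))
    stop("s0 exceeds r for cistrome(s): ",
         paste(nms[s0 > r], collapse = ", "), call. = FALSE)
  with_local_seed(seed, {
    out <- lapply(nms, function(nm) {
      prod <- layout$assign[[nm]]$producing
      n <- s0[[nm]]
      if (n == length(prod)) prod
      else prod[sample.int(length(prod), n)]
    })
    setNames(out, nms)
  })
}

#' Run one branching-process trajectory
#'
#' Applies `timesteps` synchronous steps of the TF branching process to a
#' segment layout and records the per-cistrome active-segment counts
#' \eqn{s_t}.  Extinction is absorbing: once every cistrome is at zero the
#' remaining steps are zero (and, unless accounting is recorded, are skipped).
#'
#' @param layout A [generate_layout()] result.
#' @param config A [sim_config()].
#' @param seed Master seed (integer).  Together with `run_index` it
#'   determines every random draw bit-exactly, via per-(run, cistrome)
#'   substreams.
#' @param run_index Substream index of this run (1 for a standalone run;
#'   [run_ensemble()] uses `1:n_runs`).
#' @param record_accounting If `TRUE`, per-step TF bookkeeping is recorded
#'   (and early exit is disabled so every step is audited): units emitted,
#'   landings on own producing segments, transfers to partners, absorptions,
#'   and activations collapsed by multiple hits.  In `meanfield` mode the
#'   exact conservation `emitted = own_hits + transferred + absorbed` holds
#'   per step and cistrome; in `two_site` mode transfers are copies of
#'   already-landed TFs, so the landing balance is
#'   `emitted = own_hits + absorbed` with transfers reported separately.
#' @param early_exit Skip simulation after global extinction (zero-padded).
#' @return A `tfbp_trajectory`: list with `s` (a `(timesteps+1) x k` integer
#'   matrix of active counts, columns named by cistrome), `survived`
#'   (named logical, `s_T > 0`), the resolved `m`/`s0`, `mode`, `seed`, and
#'   (optionally) `accounting`.
#' @examples
#' lay <- generate_layout(cistrome_preset("tiny_single"), seed = 1)
#' tr <- run_branching(lay, sim_config(m = 3, timesteps = 100), seed = 42)
#' tr$survived
#' @export
run_branching <- function(layout, config, seed, run_index = 1L,
                          record_accounting = FALSE, early_exit = TRUE) {
  rc <- resolve_config(layout, config)
  desc <- engine_desc(layout)
  res <- cpp_run(desc, rc$m, rc$s0, rc$T, rc$mode_int,
                 as.double(seed), as.double(run_index),
                 record_accounting, early_exit)
  nms <- layout$system$names
  s <- res$s
  colnames(s) <- nms
  out <- list(s = s,
              survived = setNames(s[nrow(s), ] > 0L, nms),
              m = setNames(rc$m, nms), s0 = setNames(rc$s0, nms),
              mode = config$mode, timesteps = rc$T,
              seed = seed, run_index = run_index)
  if (record_accounting) {
    acct <- lapply(res[c("emitted", "own_hits", "transferred",
                         "absorbed", "collapsed")],
                   function(mt) { colnames(mt) <- nms; mt })
    tt <- res$transfer_totals
    dimnames(tt) <- list(from = nms, to = nms)
    acct$transfer_totals <- tt
    out$accounting <- acct
  }
  class(out) <- "tfbp_trajectory"
  out
}

#' @export
print.tfbp_trajectory <- function(x, ...) {
  cat(sprintf("<tfbp_trajectory> %d steps, mode %s\n", x$timesteps, x$mode))
  fin <- x$s[nrow(x$s), ]
  for (nm in colnames(x$s))
    cat(sprintf("  %s: m = %g, s0 = %d, s_T = %d (%s)\n", nm, x$m[[nm]],
                x$s0[[nm]], fin[[nm]],
                if (fin[[nm]] > 0) "survived" else "dissipated"))
  invisible(x)
}

#' Run an ensemble of independent trajectories
#'
#' Repeats [run_branching()] `n_runs` times with per-run substreams derived
#' deterministically from `seed` (run indices `1:n_runs`), and summarises
#' survival.  Results are bit-exactly reproducible given `seed` and do not
#' depend on R's global RNG state.
#'
#' @inheritParams run_branching
#' @param n_runs Number of independent runs.
#' @param return_trajectories If `TRUE`, keep every full trajectory (memory
#'   permitting); otherwise only final states and first-activation times.
#' @return A `tfbp_ensemble`: list with `final_s` (`n_runs x k`), `survived`
#'   (logical matrix), `survival_fraction` (named), `first_active`
#'   (`n_runs x k`, first `t` with `s_t > 0`, `-1` if never active), the
#'   resolved config fields and `seed`; plus `trajectories` if requested.
#' @examples
#' lay <- generate_layout(cistrome_preset("tiny_single"), seed = 1)
#' en <- run_ensemble(lay, sim_config(m = 3, timesteps = 100),
#'                    n_runs = 50, seed = 7)
#' en$survival_fraction
#' @export
run_ensemble <- function(layout, config, n_runs, seed,
                         return_trajectories = FALSE, early_exit = TRUE) {
  stopifnot(n_runs >= 1L)
  rc <- resolve_config(layout, config)
  desc <- engine_desc(layout)
  nms <- layout$system$names
  res <- cpp_ensemble(desc, rc$m, rc$s0, rc$T, rc$mode_int,
                      as.double(seed), as.integer(n_runs), early_exit)
  final_s <- res$final_s
  colnames(final_s) <- nms
  first_active <- res$first_active
  colnames(first_active) <- nms
  survived <- final_s > 0L
  out <- list(final_s = final_s, survived = survived,
              survival_fraction = colMeans(survived),
              first_active = first_active,
              n_runs = as.integer(n_runs),
              m = setNames(rc$m, nms), s0 = setNames(rc$s0, nms),
              mode = config$mode, timesteps = rc$T, seed = seed)
  if (return_trajectories)
    out$trajectories <- lapply(seq_len(n_runs), function(i)
      run_branching(layout, config, seed, run_index = i,
                    early_exit = early_exit))
  class(out) <- "tfbp_ensemble"
  out
}

#' @export
print.tfbp_ensemble <- function(x, ...) {
  cat(sprintf("<tfbp_ensemble> %d runs x %d steps, mode %s\n",
              x$n_runs, x$timesteps, x$mode))
  for (nm in names(x$survival_fraction))
    cat(sprintf("  %s: m = %g, s0 = %d, survival fraction %.3f\n",
                nm, x$m[[nm]], x$s0[[nm]], x$survival_fraction[[nm]]))
  invisible(x)
}

#' Replicate a single step from a fixed state
#'
#' Draws `n_reps` independent realisations of \eqn{s_{t+1}} from the given
#' active counts (the one-step distribution depends on the state only through
#' the counts).  This is the workhorse for distribution-level checks of the
#' engine against closed forms and the brute-force reference simulator.
#'
#' @inheritParams run_branching
#' @param s Named (or positional) active counts per cistrome.
#' @param m Branching parameter(s).
#' @param mode Transfer mode, as in [sim_config()].
#' @param n_reps Number of replicates.
#' @return Integer matrix `n_reps x k` of next-step active counts.
#' @export
step_replicates <- function(layout, s, m, mode = c("meanfield", "two_site"),
                            n_reps = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  nms <- layout$system$names
  s <- as.integer(floor(resolve_per_cistrome(s, nms, "s")))
  r <- layout$system$r
  if (any(s > r)) stop("s exceeds r", call. = FALSE)
  m <- as.numeric(resolve_per_cistrome(m, nms, "m"))
  desc <- engine_desc(layout)
  out <- cpp_step_replicates(desc, s, m,
                             match(mode, c("meanfield", "two_site")) - 1L,
                             as.integer(n_reps), as.double(seed))
  colnames(out) <- nms
  out
}
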