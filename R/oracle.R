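#' Brute-force reference step (per-segment, per-TF-unit)
#'
#' A deliberately naive, pure-R implementation of one timestep: every TF
#' unit is sampled and classified individually against the layout's explicit
#' segment ids, with no count-level shortcuts.  It serves as an independent
#' reference for the compiled engine in distribution-level tests and is
#' guarded to small layouts.  Randomness comes from R's RNG (`set.seed()`
#' before calling for reproducibility), entirely separate from the engine's
#' substream RNG.
#'
#' @param layout A [generate_layout()] result with `sum(p) <= 2000`.
#' @param active Named list of currently active producing-segment ids (as
#'   from [init_state()]).
#' @param m Branching parameter(s), recycled or named.
#' @param mode `"meanfield"` or `"two_site"` (see [sim_config()]).
#' @return Named list of active segment ids at the next step.
#' @examples
#' lay <- generate_layout(cistrome_preset("tiny_coupled"), seed = 1)
#' st <- init_state(lay, s0 = c(TfA = 20, TfB = 0), seed = 1)
#' set.seed(99)
#' brute_force_step(lay, st, m = 2)
#' @export
brute_force_step <- function(layout, active, m,
                             mode = c("meanfield", "two_site")) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "segment_layout"))
  sys <- layout$system
  if (sum(sys$p) > 2000)
    stop("brute-force reference is restricted to small layouts (sum(p) <= 2000)",
         call. = FALSE)
  nms <- sys$names
  m <- resolve_per_cistrome(m, nms, "m")
  stopifnot(is.list(active), all(nms %in% names(active)))
  for (nm in nms)
    stopifnot(all(active[[nm]] %in% layout$assign[[nm]]$producing))

  # id -> (pool, position) lookup per cistrome
  pool_pos <- lapply(setNames(nms, nms), function(nm) {
    ids <- layout$assign[[nm]]$pool_ids
    if (!length(ids)) return(NULL)
    do.call(rbind, lapply(names(ids), function(q)
      data.frame(id = ids[[q]], pool = as.integer(q),
                 pos = seq_along(ids[[q]]))))
  })

  emit_count <- function(nm) {
    s <- length(active[[nm]])
    mf <- floor(m[[nm]]); fr <- m[[nm]] - mf
    n <- s * mf
    if (fr > 0 && s > 0) n <- n + sum(runif(s) < fr)
    n
  }

  if (mode == "meanfield") {
    nxt <- setNames(lapply(nms, function(nm) integer(0)), nms)
    for (nm in nms) {
      n_tf <- emit_count(nm)
      p <- sys$p[[nm]]
      own <- layout$assign[[nm]]$own_only
      pp <- pool_pos[[nm]]
      for (u in seq_len(n_tf)) {
        j <- sample.int(p, 1L)
        if (j %in% own) {
          nxt[[nm]] <- union(nxt[[nm]], j)
        } else if (!is.null(pp) && j %in% pp$id) {
          row <- pp[pp$id == j, ]
          pl <- layout$pools[[row$pool]]
          others <- setdiff(pl$members, nm)
          partner <- if (length(others) == 1L) others else sample(others, 1L)
          cj <- layout$assign[[partner]]$pool_ids[[as.character(row$pool)]][row$pos]
          nxt[[partner]] <- union(nxt[[partner]], cj)
        }  # else absorbed (or non-producing)
      }
    }
    return(nxt)
  }

  # two_site: phase 1, own landings occupy primary sites of producing segments
  prim <- setNames(lapply(nms, function(nm) integer(0)), nms)
  sec <- setNames(lapply(nms, function(nm) integer(0)), nms)
  for (nm in nms) {
    n_tf <- emit_count(nm)
    p <- sys$p[[nm]]
    producing <- layout$assign[[nm]]$producing
    for (u in seq_len(n_tf)) {
      j <- sample.int(p, 1L)
      if (j %in% producing) prim[[nm]] <- union(prim[[nm]], j)
    }
  }
  # phase 2: occupied primaries on shared segments copy to a free counterpart
  # secondary, at most one foreign TF per segment, random resolution order
  for (q in seq_along(layout$pools)) {
    pl <- layout$pools[[q]]
    for (t in seq_len(pl$sigma)) {
      mem <- if (length(pl$members) > 2L) sample(pl$members) else pl$members
      for (nm in mem) {
        id <- layout$assign[[nm]]$pool_ids[[as.character(q)]][t]
        if (!(id %in% prim[[nm]])) next
        targets <- Filter(function(mm) {
          cid <- layout$assign[[mm]]$pool_ids[[as.character(q)]][t]
          !(cid %in% sec[[mm]])
        }, setdiff(pl$members, nm))
        if (!length(targets)) next
        tgt <- if (length(targets) == 1L) targets[[1]] else sample(targets, 1L)
        cid <- layout$assign[[tgt]]$pool_ids[[as.character(q)]][t]
        sec[[tgt]] <- c(sec[[tgt]], cid)
      }
    }
  }
  setNames(lapply(nms, function(nm) union(prim[[nm]], sec[[nm]])), nms)
}
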