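# run code with a private, restored RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Materialise a segment layout for a cistrome system
#'
#' Turns the count-level description (`p`, `r`, `sigma`) into an explicit
#' assignment of segment indices: for every cistrome, which of its `p`
#' segments are producing, which producing segments are shared with which
#' partner, and how shared segments pair up across cistromes (position `t` of
#' a shared pool in cistrome X is the counterpart of position `t` in each
#' partner).  The assignment is drawn uniformly at random given `seed` and is
#' recorded in the returned object; the branching dynamics depend on the
#' layout only through its partition counts, so any relabelling of segment
#' indices yields statistically identical trajectories.
#'
#' By default each pairwise overlap `sigma[X, Y]` becomes its own two-member
#' pool and pools are mutually disjoint within a cistrome (no segment shared
#' by three cistromes).  Overlap counts for three or more cistromes at once
#' are not usually available from pairwise ChIP-seq intersections; when they
#' are, pass `pools` explicitly, e.g.
#' `list(list(members = c("X","Y","Z"), sigma = 10), ...)`, and the pairwise
#' sums implied by the pools must reproduce `sigma` exactly.
#'
#' @param system A [cistrome_system()].
#' @param seed Integer seed controlling the (irrelevant-to-dynamics) index
#'   assignment.
#' @param pools Optional explicit shared-pool specification (see Details).
#' @return An object of class `segment_layout`.
#' @examples
#' sys <- cistrome_preset("tiny_coupled")
#' lay <- generate_layout(sys, seed = 1)
#' layout_params(lay)$sigma
#' @export
generate_layout <- function(system, seed = 1L, pools = NULL) {
  stopifnot(inherits(system, "cistrome_system"))
  nms <- system$names
  if (is.null(pools)) {
    pools <- list()
    k <- length(nms)
    if (k >= 2L) for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      s <- system$sigma[i, j]
      if (s > 0L) pools[[length(pools) + 1L]] <-
          list(members = c(nms[i], nms[j]), sigma = as.integer(s))
    }
  } else {
    for (pl in pools) {
      stopifnot(is.character(pl$members), length(pl$members) >= 2L,
                all(pl$members %in% nms), pl$sigma >= 0)
    }
    implied <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
    for (pl in pools) {
      mem <- pl$members
      for (a in seq_along(mem)) for (b in seq_along(mem)) if (a != b)
        implied[mem[a], mem[b]] <- implied[mem[a], mem[b]] + as.integer(pl$sigma)
    }
    if (!identical(implied, system$sigma))
      stop("explicit pools do not reproduce the system's sigma matrix",
           call. = FALSE)
  }

  shared_per <- setNames(integer(length(nms)), nms)
  for (pl in pools) for (mem in pl$members)
    shared_per[mem] <- shared_per[mem] + as.integer(pl$sigma)
  bad <- shared_per > system$r
  if (any(bad))
    stop("infeasible disjoint assignment: total shared counts exceed r for ",
         paste(nms[bad], collapse = ", "), call. = FALSE)

  assign <- with_local_seed(seed, {
    out <- list()
    cursor <- setNames(integer(length(nms)), nms)
    for (nm in nms) {
      p <- system$p[[nm]]; r <- system$r[[nm]]
      producing <- if (p > 0L) sample.int(p, r) else integer(0)  # random order
      out[[nm]] <- list(producing = producing,
                        own_only = integer(0), pool_ids = list())
    }
    for (q in seq_along(pools)) {
      pl <- pools[[q]]
      for (mem in pl$members) {
        idx <- seq_len(pl$sigma) + cursor[[mem]]
        out[[mem]]$pool_ids[[as.character(q)]] <- out[[mem]]$producing[idx]
        cursor[[mem]] <- cursor[[mem]] + pl$sigma
      }
    }
    for (nm in nms) {
      r <- system$r[[nm]]
      out[[nm]]$own_only <-
        out[[nm]]$producing[setdiff(seq_len(r), seq_len(cursor[[nm]]))]
    }
    out
  })

  structure(list(system = system, seed = as.integer(seed),
                 pools = pools, assign = assign),
            class = "segment_layout")
}

#' @export
print.segment_layout <- function(x, ...) {
  cat(sprintf("<segment_layout> seed %d over:\n", x$seed))
  print(x$system)
  if (length(x$pools))
    for (pl in x$pools)
      cat(sprintf("  pool {%s}: %d shared segments\n",
                  paste(pl$members, collapse = ", "), pl$sigma))
  invisible(x)
}

#' Recompute count parameters from a layout
#'
#' Recovers (`p`, `r`, `sigma`) from the explicit segment assignment; by
#' construction this is the inverse of [generate_layout()], which the test
#' suite exercises as a round-trip property.
#'
#' @param layout A [generate_layout()] result.
#' @return A list with named vectors `p`, `r` and the `sigma` matrix.
#' @export
layout_params <- function(layout) {
  stopifnot(inherits(layout, "segment_layout"))
  nms <- layout$system$names
  p <- layout$system$p
  r <- setNames(vapply(layout$assign, function(a) length(a$producing),
                       integer(1)), nms)
  sigma <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
  for (q in seq_along(layout$pools)) {
    pl <- layout$pools[[q]]
    n <- length(layout$assign[[pl$members[1]]]$pool_ids[[as.character(q)]])
    mem <- pl$members
    for (a in seq_along(mem)) for (b in seq_along(mem)) if (a != b)
      sigma[mem[a], mem[b]] <- sigma[mem[a], mem[b]] + n
  }
  list(p = p, r = r, sigma = sigma)
}

# count-level descriptor handed to the compiled engine
engine_desc <- function(layout) {
  sys <- layout$system
  pools <- lapply(layout$pools, function(pl)
    list(members = match(pl$members, sys$names) - 1L,
         sigma = as.integer(pl$sigma)))
  list(names = sys$names, p = unname(sys$p), r = unname(sys$r), pools = pools)
}
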