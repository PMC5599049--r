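#' Define a single cistrome
#'
#' A cistrome is the genome-wide set of DNA segments carrying at least one
#' binding site for a given transcription factor (TF).  Two counts
#' parameterise its branching process: `p`, the total number of segments in
#' the cistrome, and `r`, the number of those segments that can be
#' transcribed into further TF product ("producing" segments).  The remaining
#' `p - r` segments bind and absorb TF without producing any.
#'
#' @param name Cistrome label (e.g. the TF name), unique within a system.
#' @param p Total number of genome segments containing a binding site.
#' @param r Number of producing segments, `0 <= r <= p`.
#' @return An object of class `cistrome_spec`.
#' @examples
#' cistrome("Nanog", p = 4316, r = 631)
#' @export
cistrome <- function(name, p, r) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  p <- as.integer(p)
  r <- as.integer(r)
  if (length(p) != 1L || is.na(p) || p < 0L)
    stop("'p' must be a single non-negative count", call. = FALSE)
  if (length(r) != 1L || is.na(r) || r < 0L || r > p)
    stop("'r' must satisfy 0 <= r <= p", call. = FALSE)
  structure(list(name = name, p = p, r = r), class = "cistrome_spec")
}

#' @export
print.cistrome_spec <- function(x, ...) {
  cat(sprintf("<cistrome> %s: p = %d, r = %d (p/r = %s)\n", x$name, x$p, x$r,
              if (x$r > 0) format(x$p / x$r, digits = 3) else "Inf"))
  invisible(x)
}

#' Assemble a system of coupled cistromes
#'
#' Packages a set of cistromes together with the symmetric matrix `sigma` of
#' shared producing-segment counts.  `sigma[X, Y]` is the number of producing
#' segments shared between cistromes X and Y; shared segments are producing
#' in both cistromes, so `sigma[X, Y] <= min(r_X, r_Y)`.  Shared segments are
#' the conduit for TF transfer between cistromes.
#'
#' The matrix is validated here for symmetry, non-negativity and the
#' `sigma <= min(r)` bound.  Whether a *pairwise-disjoint* assignment of
#' shared segments exists (i.e. `sum(sigma[X, ]) <= r_X`) is checked by
#' [generate_layout()], not here: a system can be a perfectly valid container
#' of published pairwise overlap counts (and be analysed in the mean-field
#' limit) even when no single disjoint layout realises all pairs at once.
#'
#' @param cistromes A list of [cistrome()] objects (unique names).
#' @param sigma Symmetric numeric matrix of shared producing-segment counts,
#'   with dimnames matching the cistrome names (diagonal ignored, forced to
#'   zero).  `NULL` means no coupling.
#' @return An object of class `cistrome_system`.
#' @examples
#' sys <- cistrome_system(
#'   list(cistrome("Nanog", 4316, 631), cistrome("Oct4", 2540, 466)),
#'   sigma = matrix(c(0, 194, 194, 0), 2, 2,
#'                  dimnames = list(c("Nanog", "Oct4"), c("Nanog", "Oct4"))))
#' sys
#' @seealso [cistrome_preset()] for ready-made systems, [generate_layout()],
#'   [import_bed()].
#' @export
cistrome_system <- function(cistromes, sigma = NULL) {
  if (inherits(cistromes, "cistrome_spec")) cistromes <- list(cistromes)
  stopifnot(is.list(cistromes), length(cistromes) >= 1L)
  if (!all(vapply(cistromes, inherits, logical(1), "cistrome_spec")))
    stop("'cistromes' must be a list of cistrome() objects", call. = FALSE)
  nms <- unname(vapply(cistromes, `[[`, character(1), "name"))
  if (anyDuplicated(nms))
    stop("duplicate cistrome names: ", paste(nms[duplicated(nms)], collapse = ", "),
         call. = FALSE)
  k <- length(nms)
  p <- setNames(vapply(cistromes, `[[`, integer(1), "p"), nms)
  r <- setNames(vapply(cistromes, `[[`, integer(1), "r"), nms)

  if (is.null(sigma)) {
    sigma <- matrix(0L, k, k, dimnames = list(nms, nms))
  } else {
    stopifnot(is.matrix(sigma), nrow(sigma) == k, ncol(sigma) == k)
    if (is.null(dimnames(sigma))) dimnames(sigma) <- list(nms, nms)
    if (!setequal(rownames(sigma), nms) || !setequal(colnames(sigma), nms))
      stop("dimnames of 'sigma' must match cistrome names", call. = FALSE)
    sigma <- sigma[nms, nms, drop = FALSE]
    if (any(is.na(sigma)) || any(sigma < 0))
      stop("'sigma' must be non-negative counts", call. = FALSE)
    if (any(sigma != round(sigma)))
      stop("'sigma' must contain integer counts", call. = FALSE)
    if (!isTRUE(all.equal(sigma, t(sigma), check.attributes = FALSE)))
      stop("'sigma' must be symmetric", call. = FALSE)
    storage.mode(sigma) <- "integer"
    diag(sigma) <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i < j && sigma[i, j] > min(r[i], r[j]))
        stop(sprintf("sigma[%s, %s] = %d exceeds min(r) = %d",
                     nms[i], nms[j], sigma[i, j], min(r[i], r[j])), call. = FALSE)
    }
  }
  structure(list(cistromes = setNames(cistromes, nms), names = nms,
                 p = p, r = r, sigma = sigma),
            class = "cistrome_system")
}

#' @export
print.cistrome_system <- function(x, ...) {
  cat(sprintf("<cistrome_system> %d cistrome(s)\n", length(x$names)))
  df <- data.frame(name = x$names, p = x$p, r = x$r,
                   `p/r` = round(x$p / pmax(x$r, 1L), 2), check.names = FALSE,
                   row.names = NULL)
  print(df)
  off <- x$sigma[upper.tri(x$sigma)]
  if (any(off > 0)) {
    cat("shared producing segments (sigma):\n")
    print(x$sigma)
  } else {
    cat("no coupling (all sigma = 0)\n")
  }
  invisible(x)
}

#' Subset a cistrome system
#'
#' Keeps the named cistromes and the corresponding submatrix of shared
#' counts.  Used by the experiment drivers to carve the pair or triple under
#' study out of a larger system.
#'
#' @param system A [cistrome_system()].
#' @param names Cistrome names to keep (order preserved as given).
#' @return A `cistrome_system` over the selected cistromes.
#' @export
subset_system <- function(system, names) {
  stopifnot(inherits(system, "cistrome_system"))
  missing <- setdiff(names, system$names)
  if (length(missing))
    stop("unknown cistrome(s): ", paste(missing, collapse = ", "), call. = FALSE)
  cistrome_system(unname(system$cistromes[names]),
                  system$sigma[names, names, drop = FALSE])
}
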