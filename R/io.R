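#' Read and write cistrome system specifications
#'
#' A system is serialised either as one JSON file (cistrome names, `p`, `r`,
#' and the `sigma` matrix) or as a pair of TSVs: one row per cistrome
#' (`name`, `p`, `r`) plus a long-format overlap table (`cistrome_a`,
#' `cistrome_b`, `sigma`).  Both formats round-trip exactly.
#'
#' @param system A [cistrome_system()].
#' @param path JSON file path.
#' @return `write_system_json()` returns `path` invisibly;
#'   `read_system_json()` returns a [cistrome_system()].
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_system_json(cistrome_preset("tiny_coupled"), f)
#' read_system_json(f)
#' @export
write_system_json <- function(system, path) {
  stopifnot(inherits(system, "cistrome_system"))
  obj <- list(
    cistromes = lapply(unname(system$cistromes), function(cs)
      list(name = cs$name, p = cs$p, r = cs$r)),
    sigma = lapply(which(upper.tri(system$sigma) & system$sigma > 0),
                   function(idx) {
                     ij <- arrayInd(idx, dim(system$sigma))
                     list(a = system$names[ij[1]], b = system$names[ij[2]],
                          sigma = system$sigma[idx])
                   })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_system_json
#' @export
read_system_json <- function(path) {
  obj <- jsonlite::read_json(path)
  specs <- lapply(obj$cistromes, function(cs) cistrome(cs$name, cs$p, cs$r))
  nms <- vapply(specs, `[[`, character(1), "name")
  sig <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
  for (ov in obj$sigma) {
    sig[ov$a, ov$b] <- as.integer(ov$sigma)
    sig[ov$b, ov$a] <- as.integer(ov$sigma)
  }
  cistrome_system(specs, sigma = sig)
}

#' @rdname write_system_json
#' @param cistrome_file,overlap_file TSV paths for the per-cistrome table and
#'   the pairwise overlap table.
#' @export
write_system_tsv <- function(system, cistrome_file, overlap_file) {
  stopifnot(inherits(system, "cistrome_system"))
  df <- data.frame(name = system$names, p = unname(system$p),
                   r = unname(system$r))
  write.table(df, cistrome_file, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(upper.tri(system$sigma), arr.ind = TRUE)
  ov <- data.frame(cistrome_a = system$names[idx[, 1]],
                   cistrome_b = system$names[idx[, 2]],
                   sigma = system$sigma[idx])
  ov <- ov[ov$sigma > 0, , drop = FALSE]
  write.table(ov, overlap_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cistrome_file)
}

#' @rdname write_system_json
#' @export
read_system_tsv <- function(cistrome_file, overlap_file) {
  df <- read.delim(cistrome_file, sep = "\t", stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(df)), function(i)
    cistrome(df$name[i], df$p[i], df$r[i]))
  nms <- df$name
  sig <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
  if (file.exists(overlap_file)) {
    ov <- read.delim(overlap_file, sep = "\t", stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ov))) {
      sig[ov$cistrome_a[i], ov$cistrome_b[i]] <- as.integer(ov$sigma[i])
      sig[ov$cistrome_b[i], ov$cistrome_a[i]] <- as.integer(ov$sigma[i])
    }
  }
  cistrome_system(specs, sigma = sig)
}

#' Write trajectories and ensemble summaries to CSV
#'
#' `write_trajectory_csv()` writes one or more trajectories in long format
#' (`run_id`, `t`, `cistrome`, `s_t`); `write_ensemble_csv()` writes one
#' summary row per cistrome (`cistrome`, `m`, `survival_fraction`, `n_runs`,
#' `timesteps`, `seed`).  Both echo the configuration into a JSON sidecar
#' (`<path>.json`) for provenance.
#'
#' @param x A `tfbp_trajectory`, a list of them, or a `tfbp_ensemble`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON config sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path, sidecar = TRUE) {
  trajs <- if (inherits(x, "tfbp_trajectory")) list(x)
           else if (inherits(x, "tfbp_ensemble")) {
             if (is.null(x$trajectories))
               stop("ensemble was run without return_trajectories = TRUE",
                    call. = FALSE)
             x$trajectories
           } else x
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    k <- ncol(tr$s)
    data.frame(run_id = tr$run_index,
               t = rep(0:(nrow(tr$s) - 1L), k),
               cistrome = rep(colnames(tr$s), each = nrow(tr$s)),
               s_t = as.vector(tr$s))
  }))
  write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    tr <- trajs[[1]]
    jsonlite::write_json(list(m = as.list(tr$m), s0 = as.list(tr$s0),
                              timesteps = tr$timesteps, mode = tr$mode,
                              seed = tr$seed, n_runs = length(trajs)),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_ensemble_csv <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "tfbp_ensemble"))
  df <- data.frame(cistrome = names(x$survival_fraction),
                   m = unname(x$m),
                   survival_fraction = unname(x$survival_fraction),
                   n_runs = x$n_runs, timesteps = x$timesteps, seed = x$seed)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(list(m = as.list(x$m), s0 = as.list(x$s0),
                              timesteps = x$timesteps, mode = x$mode,
                              seed = x$seed, n_runs = x$n_runs),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
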