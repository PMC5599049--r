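# small systems and conveniences shared across the test files

nanog_oct4_system <- function() {
  nms <- c("Nanog", "Oct4")
  sig <- matrix(c(0L, 194L, 194L, 0L), 2, 2, dimnames = list(nms, nms))
  cistrome_system(list(cistrome("Nanog", 4316, 631),
                       cistrome("Oct4", 2540, 466)), sigma = sig)
}

# a 3-cistrome toy with pairwise overlaps, small enough for the brute force
tiny_triple_system <- function() {
  nms <- c("TfA", "TfB", "TfC")
  sig <- matrix(0L, 3, 3, dimnames = list(nms, nms))
  sig["TfA", "TfB"] <- 4L; sig["TfA", "TfC"] <- 3L; sig["TfB", "TfC"] <- 2L
  sig <- sig + t(sig)
  cistrome_system(list(cistrome("TfA", 40, 20), cistrome("TfB", 30, 15),
                       cistrome("TfC", 25, 12)), sigma = sig)
}

quick_mcrit <- function(system, target, m_values, n_runs = 100,
                        timesteps = 300, seed = 1, ...) {
  sw <- sweep_m(system, target, m_values, n_runs = n_runs,
                timesteps = timesteps, seed = seed,
                stop_at_first_survivor = TRUE, ...)
  estimate_mcrit(sw)$m_crit
}

# two-sample chi-squared comparison of discrete count samples, pooling
# sparse cells; returns the p-value
compare_count_samples <- function(a, b, min_cell = 10) {
  lo <- min(a, b); hi <- max(a, b)
  breaks <- lo:(hi + 1L)
  ta <- tabulate(a - lo + 1L, nbins = hi - lo + 1L)
  tb <- tabulate(b - lo + 1L, nbins = hi - lo + 1L)
  # pool adjacent sparse cells
  grp <- integer(length(ta)); g <- 1L; acc <- 0
  for (i in seq_along(ta)) {
    grp[i] <- g
    acc <- acc + ta[i] + tb[i]
    if (acc >= 2 * min_cell && i < length(ta)) { g <- g + 1L; acc <- 0 }
  }
  ca <- tapply(ta, grp, sum); cb <- tapply(tb, grp, sum)
  keep <- (ca + cb) > 0
  suppressWarnings(stats::chisq.test(rbind(ca[keep], cb[keep]))$p.value)
}
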