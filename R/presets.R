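#' Ready-made cistrome systems
#'
#' Deterministic preset systems used throughout the examples and tests.
#'
#' * `"mouse_esc"` — the four mouse embryonic stem cell cistromes with their
#'   ChIP-seq-derived segment counts: Nanog (p 4316, r 631), Sox2 (3330,
#'   542), Oct4 (2540, 466), cMyc (2961, 864), and pairwise shared producing
#'   segments Nanog–Sox2 287, Nanog–Oct4 194, Nanog–cMyc 265, Sox2–Oct4 237,
#'   Sox2–cMyc 252, Oct4–cMyc 268.  Note the full four-way system admits no
#'   pairwise-disjoint layout (Nanog's overlaps sum to 746 > r = 631);
#'   simulation experiments couple at most three of them at a time, while
#'   mean-field analysis uses all pairs directly.
#' * `"tiny_single"` — one toy cistrome TfA (p 40, r 20), for fast tests.
#' * `"tiny_coupled"` — TfA (40, 20) and TfB (30, 15) sharing 5 segments.
#' * `"scaled_nanog"` — Nanog scaled tenfold (p 43160, r 6310); with `p / r`
#'   fixed the dynamics are statistically unchanged, which the scale
#'   invariance tests exercise.
#'
#' @param name One of `"mouse_esc"`, `"tiny_single"`, `"tiny_coupled"`,
#'   `"scaled_nanog"`.
#' @return A [cistrome_system()].
#' @examples
#' cistrome_preset("mouse_esc")
#' @export
cistrome_preset <- function(name = c("mouse_esc", "tiny_single",
                                     "tiny_coupled", "scaled_nanog")) {
  name <- match.arg(name)
  switch(name,
    mouse_esc = {
      nms <- c("Nanog", "Sox2", "Oct4", "cMyc")
      sig <- matrix(0L, 4, 4, dimnames = list(nms, nms))
      sig["Nanog", "Sox2"] <- 287L
      sig["Nanog", "Oct4"] <- 194L
      sig["Nanog", "cMyc"] <- 265L
      sig["Sox2", "Oct4"] <- 237L
      sig["Sox2", "cMyc"] <- 252L
      sig["Oct4", "cMyc"] <- 268L
      sig <- sig + t(sig)
      cistrome_system(list(cistrome("Nanog", 4316, 631),
                           cistrome("Sox2", 3330, 542),
                           cistrome("Oct4", 2540, 466),
                           cistrome("cMyc", 2961, 864)),
                      sigma = sig)
    },
    tiny_single = cistrome_system(list(cistrome("TfA", 40, 20))),
    tiny_coupled = {
      nms <- c("TfA", "TfB")
      sig <- matrix(c(0L, 5L, 5L, 0L), 2, 2, dimnames = list(nms, nms))
      cistrome_system(list(cistrome("TfA", 40, 20), cistrome("TfB", 30, 15)),
                      sigma = sig)
    },
    scaled_nanog = cistrome_system(list(cistrome("Nanog", 43160, 6310)))
  )
}

#' Write a toy BED fixture set
#'
#' Generates a small deterministic pair of BED3 interval sets (binding and
#' producing intervals for two toy cistromes) under `dir`, for exercising
#' [import_bed()] without any external data.  With the default 50 kb bin the
#' resulting system is TfA (p 3, r 1) and TfB (p 2, r 2) with one shared
#' producing bin.
#'
#' @param dir Directory to write into (created if needed).
#' @return A list with `binding` and `producing` named path vectors.
#' @export
toy_bed_fixture <- function(dir = tempfile("bedtoy")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(file, lines) writeLines(lines, file.path(dir, file))
  # TfA binding: bins 0,1,2 of chr1; producing: bin 0
  w("TfA_binding.bed", c("chr1\t0\t49999", "chr1\t50000\t99999",
                         "chr1\t100000\t149999"))
  w("TfA_producing.bed", "chr1\t0\t49999")
  # TfB binding: bins 0,1 of chr1; producing: bins 0 and 1
  w("TfB_binding.bed", c("chr1\t10000\t60000"))
  w("TfB_producing.bed", c("chr1\t10000\t20000", "chr1\t55000\t60000"))
  list(binding = c(TfA = file.path(dir, "TfA_binding.bed"),
                   TfB = file.path(dir, "TfB_binding.bed")),
       producing = c(TfA = file.path(dir, "TfA_producing.bed"),
                     TfB = file.path(dir, "TfB_producing.bed")))
}
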