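# round half away from zero (presentation rounding for 1-d.p. tables)
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Infinite-limit critical branching value of a single cistrome
#'
#' In the noiseless infinite limit every TF lands on a producing segment with
#' probability `r/p`, so the process is critical when `m*r/p = 1`,
#' i.e. at `m = p / r`.  Finite, noisy systems tip at a somewhat larger
#' integer value (see [estimate_mcrit()]).
#'
#' @param p Total segment count of the cistrome.
#' @param r Producing segment count (`> 0`).
#' @return The critical branching value `p / r` (full precision).
#' @examples
#' single_critical_m(4316, 631)  # Nanog, ~6.8
#' @export
single_critical_m <- function(p, r) {
  stopifnot(p > 0)
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  p / r
}

#' One deterministic update of two coupled cistromes
#'
#' The infinite-limit recursion for active-site counts of coupled cistromes
#' X and Y sharing `sigma` producing segments:
#' \deqn{s'_X = s_X m_X (r_X - \sigma)/p_X + s_Y m_Y \sigma / p_Y}
#' and symmetrically for Y.  The own-activation term uses the non-shared
#' producing fraction; the cross term is TF transferred in through the
#' partner's shared segments.
#'
#' @param s Numeric length-2 state `(s_X, s_Y)`.
#' @param p,r,m Numeric length-2 parameter vectors for (X, Y).
#' @param sigma Shared producing-segment count.
#' @return Numeric length-2 updated state.
#' @examples
#' coupled_update(c(10, 20), p = c(100, 200), r = c(20, 40),
#'                m = c(5, 5), sigma = 5)
#' @export
coupled_update <- function(s, p, r, m, sigma) {
  stopifnot(length(s) == 2L, length(p) == 2L, length(r) == 2L, length(m) == 2L,
            all(r - sigma >= 0), all(p > 0), all(s >= 0))
  M <- coupled_matrix(p, r, m, sigma)
  as.numeric(M %*% s)
}

# the 2x2 linear map of the coupled recursion
coupled_matrix <- function(p, r, m, sigma) {
  matrix(c(m[1] * (r[1] - sigma) / p[1], m[2] * sigma / p[2],
           m[1] * sigma / p[1],          m[2] * (r[2] - sigma) / p[2]),
         nrow = 2, byrow = TRUE)
}

#' Infinite-limit critical branching value under coupling
#'
#' Given cistrome Y held at branching value `mY`, returns the value of `mX`
#' at which the coupled two-cistrome linear recursion is exactly critical
#' (dominant eigenvalue 1):
#' \deqn{m_X = \frac{p_X (p_Y - m_Y r_Y + m_Y \sigma)}
#'                   {(p_Y - m_Y r_Y)(r_X - \sigma) + m_Y r_X \sigma}}
#' Two identities follow: with `sigma = 0`, or with Y at its own critical
#' value `mY = pY / rY`, the result is the uncoupled value `pX / rX`.  When Y
#' runs *above* its critical value the surplus TF flux lowers `mX` below
#' `pX / rX`.
#'
#' @param pX,rX Target cistrome X parameters.
#' @param pY,rY Partner cistrome Y parameters.
#' @param mY Branching value at which Y is held.
#' @param sigma Shared producing-segment count (`<= min(rX, rY)`).
#' @return Critical `mX` (full precision; present tables at 1 d.p.).
#' @examples
#' coupled_critical_m(4316, 631, 2961, 864, mY = 4, sigma = 265)  # ~5.0
#' @export
coupled_critical_m <- function(pX, rX, pY, rY, mY, sigma) {
  stopifnot(pX > 0, pY > 0, rX - sigma >= 0, rY - sigma >= 0, sigma >= 0)
  num <- pX * (pY - mY * rY + mY * sigma)
  den <- (pY - mY * rY) * (rX - sigma) + mY * rX * sigma
  if (abs(den) < 1e-12 * max(1, abs(num)))
    stop("coupled critical value is singular for these parameters",
         call. = FALSE)
  num / den
}

#' Table of predicted coupled critical values
#'
#' For every ordered pair (held cistrome Y, target cistrome X) evaluates
#' [coupled_critical_m()] with Y held at `held_m[Y]` and the pairwise shared
#' count `sigma[X, Y]` of the system.  Rows are the held cistrome, columns
#' the target.  Computation is full precision; set `digits` to present at
#' 1 d.p. (half-up), the conventional table format.
#'
#' @param system A [cistrome_system()].
#' @param held_m Named vector: branching value at which each cistrome is held
#'   when acting as the partner (typically its observed critical value).
#' @param digits Rounding for presentation, or `NULL` for full precision.
#' @return Numeric matrix with `NA` on the diagonal.
#' @examples
#' critical_table(cistrome_preset("mouse_esc"),
#'                held_m = c(Nanog = 8, Sox2 = 7, Oct4 = 6, cMyc = 4))
#' @export
critical_table <- function(system, held_m, digits = 1L) {
  stopifnot(inherits(system, "cistrome_system"))
  nms <- system$names
  held_m <- resolve_per_cistrome(held_m, nms, "held_m")
  out <- matrix(NA_real_, length(nms), length(nms),
                dimnames = list(held = nms, target = nms))
  for (Y in nms) for (X in nms) {
    if (X == Y) next
    out[Y, X] <- coupled_critical_m(system$p[[X]], system$r[[X]],
                                    system$p[[Y]], system$r[[Y]],
                                    mY = held_m[[Y]],
                                    sigma = system$sigma[X, Y])
  }
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Mean-field linear map of a multi-cistrome system
#'
#' Generalises the two-cistrome recursion to any number of cistromes with
#' pairwise shared counts: `M[i, i] = m_i (r_i - sum_j sigma_ij) / p_i` and
#' `M[i, j] = m_j sigma_ij / p_j` for `i != j`, so that `s' = M s`.  The
#' system is critical when the spectral radius of `M` is 1.  For three or
#' more cistromes no closed form for a critical `m` is published; use
#' [critical_m_spectral()] to solve numerically.
#'
#' @param system A [cistrome_system()].
#' @param m Branching values, recycled or named per cistrome.
#' @return A `k x k` numeric matrix.
#' @export
meanfield_matrix <- function(system, m) {
  stopifnot(inherits(system, "cistrome_system"))
  nms <- system$names
  m <- resolve_per_cistrome(m, nms, "m")
  k <- length(nms)
  M <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    own <- system$r[[i]] - sum(system$sigma[i, ])
    stopifnot(own >= 0)
    M[i, i] <- m[[i]] * own / system$p[[i]]
    for (j in seq_len(k)) if (j != i)
      M[i, j] <- m[[j]] * system$sigma[i, j] / system$p[[j]]
  }
  M
}

#' Spectral radius of a matrix
#'
#' @param M A square numeric matrix.
#' @return The largest eigenvalue modulus.
#' @export
spectral_radius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

#' Numerically solve for a critical branching value
#'
#' Finds the `m` of `target` at which the mean-field map of the whole system
#' (partners held at `held_m`) has spectral radius 1, by root-finding on the
#' dominant eigenvalue.  For two cistromes this is an independent check of
#' the closed form [coupled_critical_m()]; for three or more it is the
#' natural extension (criticality = spectral radius 1).
#'
#' @param system A [cistrome_system()].
#' @param target Name of the cistrome whose critical `m` is sought.
#' @param held_m Named branching values for the other cistromes.
#' @param interval Search interval for `m`.
#' @return The critical `m` (full precision).
#' @export
critical_m_spectral <- function(system, target, held_m,
                                interval = c(1e-9, 1e3)) {
  stopifnot(inherits(system, "cistrome_system"), target %in% system$names)
  others <- setdiff(system$names, target)
  held_m <- resolve_per_cistrome(held_m, others, "held_m")
  f <- function(mX) {
    m <- setNames(numeric(length(system$names)), system$names)
    m[others] <- held_m[others]
    m[target] <- mX
    spectral_radius(meanfield_matrix(system, m)) - 1
  }
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo * hi > 0)
    stop("no critical m in the search interval (partners may already ",
         "sustain the system, or can never)", call. = FALSE)
  uniroot(f, interval, tol = 1e-10)$root
}
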