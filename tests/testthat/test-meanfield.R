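esc_params <- list(
  p = c(Nanog = 4316, Sox2 = 3330, Oct4 = 2540, cMyc = 2961),
  r = c(Nanog = 631, Sox2 = 542, Oct4 = 466, cMyc = 864),
  mcrit = c(Nanog = 8, Sox2 = 7, Oct4 = 6, cMyc = 4))

test_that("single-cistrome infinite-limit critical values reproduce p/r", {
  got <- single_critical_m(esc_params$p, esc_params$r)
  expect_equal(unname(floor(got * 10 + 0.5) / 10), c(6.8, 6.1, 5.5, 3.4))
  expect_equal(single_critical_m(10, 10), 1.0)
  expect_error(single_critical_m(10, 0), "positive")
})

test_that("the coupled update matches hand arithmetic and fixes (0, 0)", {
  expect_equal(coupled_update(c(0, 0), p = c(100, 200), r = c(20, 40),
                              m = c(5, 5), sigma = 5), c(0, 0))
  expect_equal(coupled_update(c(10, 20), p = c(100, 200), r = c(20, 40),
                              m = c(5, 5), sigma = 5)[1], 10.0)
})

test_that("coupled critical values reproduce the four-cistrome table at 1 d.p.", {
  sys <- cistrome_preset("mouse_esc")
  tab <- critical_table(sys, held_m = esc_params$mcrit, digits = 1)
  expected <- matrix(c(NA, 4.9, 4.0, 2.9,
                       6.0, NA, 4.6, 3.1,
                       6.3, 5.6, NA, 3.2,
                       5.0, 4.2, 3.6, NA),
                     4, 4, byrow = TRUE,
                     dimnames = list(held = names(esc_params$p),
                                     target = names(esc_params$p)))
  expect_equal(tab, expected)
})

test_that("limit identities hold to machine precision", {
  p <- esc_params$p; r <- esc_params$r
  for (X in names(p)) for (Y in names(p)) {
    if (X == Y) next
    sigma <- cistrome_preset("mouse_esc")$sigma[X, Y]
    # sigma = 0: isolated cistromes recover p/r
    expect_equal(coupled_critical_m(p[[X]], r[[X]], p[[Y]], r[[Y]],
                                    mY = 3, sigma = 0),
                 p[[X]] / r[[X]])
    # partner exactly at its own infinite-limit critical value: unchanged
    expect_equal(coupled_critical_m(p[[X]], r[[X]], p[[Y]], r[[Y]],
                                    mY = p[[Y]] / r[[Y]], sigma = sigma),
                 p[[X]] / r[[X]])
  }
})

test_that("the closed form agrees with the spectral-radius root", {
  sys <- cistrome_preset("mouse_esc")
  for (pair in list(c("Nanog", "cMyc"), c("Oct4", "Nanog"),
                    c("Sox2", "Oct4"))) {
    X <- pair[1]; Y <- pair[2]
    mY <- esc_params$mcrit[[Y]]
    closed <- coupled_critical_m(sys$p[[X]], sys$r[[X]], sys$p[[Y]],
                                 sys$r[[Y]], mY = mY,
                                 sigma = sys$sigma[X, Y])
    sub <- subset_system(sys, c(X, Y))
    spectral <- critical_m_spectral(sub, target = X,
                                    held_m = setNames(mY, Y))
    expect_equal(spectral, closed, tolerance = 1e-7)
    # at the critical mX the 2x2 map has dominant eigenvalue 1
    M <- meanfield_matrix(sub, m = setNames(c(closed, mY), c(X, Y)))
    expect_equal(spectral_radius(M), 1, tolerance = 1e-10)
  }
})

test_that("an overdriven partner always lowers the predicted critical value", {
  # with Y held above pY/rY it is self-supercritical in isolation, so a
  # critical mX only exists once sigma exceeds the boundary where Y's own
  # term drops below 1 (sigma > rY - pY/mY); on that feasible range the
  # prediction rises from 0 with sigma but always stays below pX/rX
  p <- esc_params$p; r <- esc_params$r
  pX <- p[["Nanog"]]; rX <- r[["Nanog"]]
  pY <- p[["Oct4"]]; rY <- r[["Oct4"]]; mY <- 6
  boundary <- rY - pY / mY
  sigmas <- seq(ceiling(boundary) + 1, min(rX, rY), by = 25)
  vals <- vapply(sigmas, function(s)
    coupled_critical_m(pX, rX, pY, rY, mY = mY, sigma = s), numeric(1))
  expect_true(all(vals > 0 & vals < pX / rX))
  # at the ignition boundary Y alone sustains the pair: critical mX -> 0
  eps_val <- coupled_critical_m(pX, rX, pY, rY, mY = mY,
                                sigma = boundary + 1e-6)
  expect_lt(eps_val, 1e-3)
  # cross-check one interior point against the spectral-radius oracle
  sub <- subset_system(cistrome_preset("mouse_esc"), c("Nanog", "Oct4"))
  expect_equal(critical_m_spectral(sub, "Nanog", held_m = c(Oct4 = 6)),
               coupled_critical_m(pX, rX, pY, rY, mY = 6, sigma = 194),
               tolerance = 1e-7)
})

test_that("deterministic iteration dies below criticality and grows above", {
  p <- c(4316, 2961); r <- c(631, 864); sigma <- 265
  mx_crit <- coupled_critical_m(p[1], r[1], p[2], r[2], mY = 4, sigma = sigma)
  iterate <- function(mX, n = 2500) {
    s <- c(10, 10)
    for (i in seq_len(n))
      s <- coupled_update(s, p, r, m = c(mX, 4), sigma = sigma)
    s
  }
  expect_true(all(iterate(mx_crit * 0.95) < 1e-6))
  expect_true(all(iterate(mx_crit * 1.05) > 1e3))
})

test_that("singular coupled denominators are reported", {
  # (pY - mY rY)(rX - sigma) exactly cancels mY rX sigma here
  expect_error(coupled_critical_m(100, 10, 100, 20, mY = 10, sigma = 5),
               "singular")
})
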