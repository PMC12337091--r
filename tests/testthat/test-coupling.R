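# Orientation factors, point-dipole couplings and class-pair averaging.

test_that("orientation factor reproduces the canonical geometries", {
  z <- c(0, 0, 1); x <- c(1, 0, 0); y <- c(0, 1, 0)
  expect_equal(orientation_factor(z, z, c(0, 0, 5)), -2)
  expect_equal(orientation_factor(x, x, c(0, 0, 5)), 1)
  expect_equal(orientation_factor(x, y, c(0, 0, 5)), 0)
  expect_error(orientation_factor(x, y, c(0, 0, 0)), "zero separation")
})

test_that("kappa stays within [-2, 2] over random orientations", {
  set.seed(11)
  for (i in 1:500) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    r <- rnorm(3)
    k <- orientation_factor(u, v, r)
    expect_gte(k, -2 - 1e-12)
    expect_lte(k, 2 + 1e-12)
  }
})

test_that("the dipole kernel matches the first-principles SI oracle", {
  # oracle: mu^2 / (4 pi eps0 R^3) in J, converted to cm^-1 by hc
  si_oracle <- function(kappa, mu1_d, mu2_d, n, r_nm) {
    d <- 3.33564095e-30; eps0 <- 8.8541878128e-12
    h <- 6.62607015e-34; c_cm <- 2.99792458e10
    e_j <- kappa * (mu1_d * d) * (mu2_d * d) /
      (4 * pi * eps0 * n^2 * (r_nm * 1e-9)^3)
    e_j / (h * c_cm)
  }
  dip <- function(mu, origin, dir = c(1, 0, 0))
    transition_dipole("s", "Q", dir, mu, origin)
  # kappa = 1: parallel dipoles perpendicular to r
  v <- point_dipole_coupling(dip(1, c(0, 0, 0)), dip(1, c(0, 0, 10)), n = 1)
  expect_equal(v, si_oracle(1, 1, 1, 1, 1), tolerance = 1e-10)
  expect_equal(v, 5.034, tolerance = 1e-3)  # C_dip to 4 s.f.
  v2 <- point_dipole_coupling(dip(6.45, c(0, 0, 0)), dip(6.45, c(0, 0, 15)),
                              n = 1.4)
  expect_equal(v2, si_oracle(1, 6.45, 6.45, 1.4, 1.5), tolerance = 1e-10)
  expect_equal(v2, 31.7, tolerance = 1e-2)  # inside the Q-band Chl a range
  # R^-3 law
  v_far <- point_dipole_coupling(dip(1, c(0, 0, 0)), dip(1, c(0, 0, 20)),
                                 n = 1)
  expect_equal(v_far, v / 8, tolerance = 1e-12)
  expect_error(point_dipole_coupling(dip(1, c(0, 0, 0)), dip(1, c(0, 0, 0))),
               "coincident")
  db <- transition_dipole("s", "B", c(1, 0, 0), 1, c(0, 0, 5))
  expect_error(point_dipole_coupling(dip(1, c(0, 0, 0)), db), "band mismatch")
})

test_that("coupling is invariant under joint sign flips through kappa", {
  set.seed(5)
  for (i in 1:20) {
    u <- rnorm(3); v <- rnorm(3); o1 <- rnorm(3); o2 <- o1 + rnorm(3)
    d1 <- transition_dipole("a", "Q", u, 2, o1)
    d2 <- transition_dipole("b", "Q", v, 3, o2)
    d1f <- transition_dipole("a", "Q", -u, 2, o1)
    d2f <- transition_dipole("b", "Q", -v, 3, o2)
    vab <- point_dipole_coupling(d1, d2)
    expect_equal(point_dipole_coupling(d1f, d2f), vab, tolerance = 1e-12)
    expect_equal(point_dipole_coupling(d1f, d2), -vab, tolerance = 1e-12)
  }
})

test_that("coupling_matrix matches per-pair kernel calls on small fixtures", {
  pigs <- fx_pigments[1:6]
  dip <- dipoles_from_library(pigs, fx_library, "Q")
  cm <- coupling_matrix(pigs, dip, "Q")
  expect_true(isSymmetric(cm$V))
  expect_true(all(diag(cm$V) == 0))
  for (i in 1:5) for (j in (i + 1):6)
    expect_identical(cm$V[i, j],
                     point_dipole_coupling(dip[[i]], dip[[j]], n = 1.4))
})

test_that("coupling_matrix permutes consistently and counts pairs", {
  pigs <- fx_pigments[1:11]
  dip <- dipoles_from_library(pigs, fx_library, "Q")
  cm <- coupling_matrix(pigs, dip, "Q")
  expect_equal(sum(upper.tri(cm$V)), 55)
  perm <- c(4, 1, 11, 2, 3, 5, 10, 6, 9, 7, 8)
  cm_p <- coupling_matrix(pigs[perm], dip[perm], "Q")
  expect_equal(cm_p$V, cm$V[perm, perm], tolerance = 1e-12)
  expect_error(coupling_matrix(pigs, dip[-1], "Q"), "missing transition dipole")
})

test_that("single-cross-pair class average is the pair value", {
  pigs <- list(toy_chl("1", c(0, 0, 0), class = "CHL_A"),
               toy_chl("2", c(0, 0, 12), class = "CHL_B"))
  dip <- dipoles_from_library(pigs, fx_library, "Q")
  cm <- coupling_matrix(pigs, dip, "Q")
  ca <- class_pair_averages(cm, q = 1)
  row <- ca[ca$class_1 == "CHL_A" & ca$class_2 == "CHL_B", ]
  expect_equal(row$mean_v, abs(cm$V[1, 2]), tolerance = 1e-12)
  expect_equal(row$n_pairs, 1L)
  expect_equal(row$sem, 0)
})

test_that("multimer scaling obeys the exact combinatorial identity", {
  # q mutually non-interacting monomer copies, n same-class pigments per
  # copy: scaled average = monomer average * q(n-1)/(qn-1)
  make_assembly <- function(q, n, spacing = 12, copy_gap = 1e4) {
    pigs <- list(); k <- 0L
    for (c_i in seq_len(q)) for (s in seq_len(n)) {
      k <- k + 1L
      pigs[[k]] <- toy_chl(sprintf("%d", k),
                           c(s * spacing, 0, c_i * copy_gap))
    }
    pigs
  }
  for (case in list(c(3, 3), c(4, 2), c(2, 4))) {
    q <- case[1]; n <- case[2]
    pigs <- make_assembly(q, n)
    dip <- dipoles_from_library(pigs, fx_library, "Q")
    cm_full <- coupling_matrix(pigs, dip, "Q")
    mono <- seq_len(n)
    cm_mono <- coupling_matrix(pigs[mono], dip[mono], "Q")
    # brute-force oracle: enumerate every pair in the full assembly
    vals <- abs(cm_full$V[upper.tri(cm_full$V)])
    expect_equal(mean(vals) * q,
                 class_pair_averages(cm_full, q = q)$mean_v)
    mono_avg <- class_pair_averages(cm_mono, q = 1)$mean_v
    expect_equal(class_pair_averages(cm_full, q = q)$mean_v,
                 mono_avg * q * (n - 1) / (q * n - 1),
                 tolerance = 1e-6)
  }
})

test_that("Soret couplings scale as the squared dipole ratio on fixed geometry", {
  # Soret dipoles are twice the Q dipoles for every Chl class; on shared
  # geometry the class-pair averages come out ~4x, up to the different
  # orientation-factor draws of the two band axes
  dq <- dipoles_from_library(fx_pigments, fx_library, "Q")
  db <- dipoles_from_library(fx_pigments, fx_library, "B")
  ca_q <- class_pair_averages(coupling_matrix(fx_pigments, dq, "Q"))
  ca_b <- class_pair_averages(coupling_matrix(fx_pigments, db, "B"))
  chl <- !grepl("CRT", paste(ca_q$class_1, ca_q$class_2))
  ratio <- ca_b$mean_v[chl] / ca_q$mean_v[chl]
  expect_true(all(ratio > 2.5 & ratio < 5.5))
  # with identical axes for both bands the 4x is exact
  db_same_axis <- lapply(dq, function(d)
    transition_dipole(d$site_id, "B", d$direction, 2 * d$magnitude,
                      d$origin))
  ca_b2 <- class_pair_averages(
    coupling_matrix(fx_pigments, db_same_axis, "B"))
  expect_equal(ca_b2$mean_v[chl] / ca_q$mean_v[chl], rep(4, sum(chl)),
               tolerance = 1e-9)
})

test_that("absolute-mode averages dominate signed-mode in magnitude", {
  dip <- dipoles_from_library(fx_pigments, fx_library, "B")
  cm <- coupling_matrix(fx_pigments, dip, "B")
  a <- class_pair_averages(cm, mode = "absolute")
  s <- class_pair_averages(cm, mode = "signed")
  expect_true(all(a$mean_v >= abs(s$mean_v) - 1e-12))
  # canonical report order: CRT first
  expect_equal(a$class_1[1], "CRT")
})
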