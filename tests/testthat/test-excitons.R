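# Site energies, Hamiltonians, diagonalization, IPR and configuration
# perturbations.

test_that("site energies follow the band-maximum-plus-shift rule", {
  lib <- fx_library
  e <- site_energy("CHL_A", "Q", lib, shift_cm1 = 0)
  expect_equal(e, 1e7 / 662, tolerance = 1e-9)
  expect_equal(site_energy("CHL_A", "Q", lib, shift_cm1 = shift_to_cm1(0.05, "eV")) - e,
               403.2772, tolerance = 1e-4)
  # Crt: B energy at the bright band, Q = B - 0.8 eV under the rule
  e_b <- site_energy("CRT", "B", lib)
  e_q <- site_energy("CRT", "Q", lib)
  expect_equal(e_b - e_q, 0.8 * 8065.544, tolerance = 1e-6)
  expect_equal(site_energy("CRT", "Q", lib, crt_rule = FALSE), e_b)
})

test_that("shift tables convert units, warn above 0.1 eV, fall back B->Q", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site_id\tband\tshift\tunit",
               "601\tQ\t-0.05\teV",
               "602\tQ\t100\tcm1",
               "603\tQ\t0.15\teV"), path)
  expect_warning(tab <- read_shift_table(path), "0.1 eV")
  expect_equal(tab$shift_cm1[1], -0.05 * 8065.544, tolerance = 1e-9)
  expect_equal(tab$shift_cm1[2], 100)
  expect_equal(pigmentnet:::lookup_shift(tab, "601", "B"),
               tab$shift_cm1[1])     # B falls back to the Q shift
  expect_equal(pigmentnet:::lookup_shift(tab, "999", "Q"), 0)
})

test_that("Hamiltonian assembly places energies and couplings", {
  pigs <- fx_pigments[1:3]
  dip <- dipoles_from_library(pigs, fx_library, "Q")
  cm <- coupling_matrix(pigs, dip, "Q")
  eps <- c(15000, 15100, 15200)
  h <- build_hamiltonian(eps, cm)
  expect_equal(unname(diag(h$H)), eps)
  expect_equal(h$H[1, 2], cm$V[1, 2])
  expect_true(isSymmetric(h$H))
  expect_error(build_hamiltonian(eps[1:2], cm), "site order")
  # permutation equivariance
  perm <- c(3, 1, 2)
  cm_p <- coupling_matrix(pigs[perm], dip[perm], "Q")
  h_p <- build_hamiltonian(eps[perm], cm_p)
  expect_equal(unname(h_p$H), unname(h$H[perm, perm]), tolerance = 1e-12)
})

test_that("the textbook dimer and decoupled limits diagonalize exactly", {
  pigs <- list(toy_chl("1", c(0, 0, 0)), toy_chl("2", c(12, 0, 0)))
  dip <- dipoles_from_library(pigs, fx_library, "Q")
  cm <- coupling_matrix(pigs, dip, "Q")
  v <- cm$V[1, 2]
  res <- diagonalize(build_hamiltonian(c(15000, 15000), cm))
  expect_equal(res$energies, c(15000 - abs(v), 15000 + abs(v)),
               tolerance = 1e-9)
  expect_equal(unname(res$weights), matrix(0.5, 2, 2), tolerance = 1e-9)
  expect_equal(unname(res$ipr_inv), c(2, 2), tolerance = 1e-9)
  # zero coupling: localized excitons at the site energies
  cm0 <- cm; cm0$V[] <- 0
  res0 <- diagonalize(build_hamiltonian(c(15000, 15500), cm0))
  expect_equal(res0$energies, c(15000, 15500))
  expect_equal(unname(res0$ipr_inv), c(1, 1), tolerance = 1e-12)
})

test_that("eigen-decomposition conserves trace and weight normalization", {
  dip <- dipoles_from_library(fx_pigments, fx_library, "B")
  cm <- coupling_matrix(fx_pigments, dip, "B")
  eps <- vapply(fx_pigments, function(p)
    site_energy(p$pigment_class, "B", fx_library), numeric(1))
  h <- build_hamiltonian(eps, cm)
  res <- diagonalize(h)
  expect_equal(sum(res$energies), sum(diag(h$H)), tolerance = 1e-6)
  # doubly stochastic weight matrix (orthonormal eigenvectors)
  expect_equal(unname(rowSums(res$weights)), rep(1, length(eps)),
               tolerance = 1e-9)
  expect_equal(unname(colSums(res$weights)), rep(1, length(eps)),
               tolerance = 1e-9)
  expect_true(all(res$ipr_inv >= 1 - 1e-9 &
                    res$ipr_inv <= length(eps) + 1e-9))
  expect_true(!is.unsorted(res$energies))
})

test_that("uniform degenerate ring matches the circulant closed form", {
  # equal energies, equal nearest-neighbour coupling on a ring: the two
  # band-edge excitons are uniform (IPR^-1 = N), all eigenvalues are
  # eps + 2 V cos(2 pi k / N)
  N <- 6; eps0 <- 15000; v <- 50
  H <- matrix(0, N, N)
  for (i in seq_len(N)) {
    H[i, i %% N + 1] <- v
    H[i %% N + 1, i] <- v
  }
  diag(H) <- eps0
  fake_cm <- structure(list(V = H - diag(eps0, N), band = "Q",
                            site_ids = as.character(1:N),
                            classes = rep("CHL_A", N)),
                       class = "pn_coupling")
  res <- diagonalize(build_hamiltonian(rep(eps0, N), fake_cm))
  expected <- sort(eps0 + 2 * v * cos(2 * pi * (0:(N - 1)) / N))
  expect_equal(res$energies, expected, tolerance = 1e-9)
  # non-degenerate band edges are fully delocalized
  expect_equal(unname(res$ipr_inv[1]), N, tolerance = 1e-6)
  expect_equal(unname(res$ipr_inv[N]), N, tolerance = 1e-6)
})

test_that("IPR^-1 hits its bounds and the dimer value", {
  expect_equal(ipr_inverse(c(1, 0, 0)), 1)
  expect_equal(ipr_inverse(rep(1 / 11, 11)), 11, tolerance = 1e-12)
  expect_equal(ipr_inverse(c(0.5, 0.5, 0)), 2)
  expect_error(ipr_inverse(c(0.5, 0.4)), "sum to 1")
})

test_that("mean IPR^-1 is invariant under site relabeling", {
  dip <- dipoles_from_library(fx_pigments, fx_library, "Q")
  cm <- coupling_matrix(fx_pigments, dip, "Q")
  eps <- vapply(fx_pigments, function(p)
    site_energy(p$pigment_class, "Q", fx_library), numeric(1))
  r1 <- diagonalize(build_hamiltonian(eps, cm))
  set.seed(9)
  perm <- sample(length(fx_pigments))
  cm_p <- coupling_matrix(fx_pigments[perm], dip[perm], "Q")
  r2 <- diagonalize(build_hamiltonian(eps[perm], cm_p))
  expect_equal(mean(r1$ipr_inv), mean(r2$ipr_inv), tolerance = 1e-9)
  expect_equal(r1$energies, r2$energies, tolerance = 1e-8)
})

test_that("band-edge excitons sit on the energetically extreme classes", {
  fit <- eet_model(fx_pigments, fx_library)
  # lowest B excitons live on the red-shifted accessory pigments
  # (Crt bright band and Chl b Soret), not on Chl a
  low_b <- exciton_sites(fit$bands$B$excitons, 1, threshold = 0.1)
  cls_b <- fit$bands$B$excitons$classes[
    match(low_b, fit$bands$B$excitons$site_ids)]
  expect_true(all(cls_b %in% c("CRT", "CHL_B", "CHL_C1")))
  # highest Q excitons live on the blue-shifted accessory classes
  nq <- length(fit$bands$Q$excitons$energies)
  hi_q <- exciton_sites(fit$bands$Q$excitons, nq, threshold = 0.1)
  cls_q <- fit$bands$Q$excitons$classes[
    match(hi_q, fit$bands$Q$excitons$site_ids)]
  expect_true(all(cls_q %in% c("CHL_B", "CHL_C1", "CRT")))
})

test_that("configuration perturbations substitute and remove correctly", {
  cfg <- standard_configurations()
  no_crt <- apply_configuration(fx_pigments, cfg$NO_CRT)
  expect_length(no_crt, 11)
  expect_false(any(vapply(no_crt, function(p) p$pigment_class, "") == "CRT"))
  all_a <- apply_configuration(fx_pigments, cfg$ALL_CHL_A)
  expect_length(all_a, 14)  # geometry kept
  expect_true(all(vapply(all_a, function(p) p$pigment_class, "") %in%
                    c("CHL_A", "CRT")))
  # substituted sites keep their centers
  expect_equal(all_a[[7]]$center, fx_pigments[[7]]$center)
  expect_error(apply_configuration(fx_pigments,
                                   list(label = "bad",
                                        substitute = c(CHL_A = "CHL_A"),
                                        remove = character())),
               "itself")
  expect_error(apply_configuration(fx_pigments,
                                   list(label = "empty", substitute = NULL,
                                        remove = c("CHL_A", "CHL_B",
                                                   "CHL_C1", "CRT"))),
               "every pigment")
})

test_that("an all-Chl-a network is more delocalized in the Soret band", {
  fit <- eet_model(fx_pigments, fx_library)
  fit_a <- refit_configuration(fit, standard_configurations()$ALL_CHL_A)
  expect_gte(mean(fit_a$bands$B$excitons$ipr_inv),
             mean(fit$bands$B$excitons$ipr_inv))
})
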