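test_that("complex mixing rules reduce and grow as they should", {
  pA <- pr_pure(320, clemastine())
  pB <- pr_pure(320, co2())
  # kappa = 0: the complex is the bare solute
  c0 <- cluster_ab(0, pA, pB)
  expect_equal(c0$a, pA$a); expect_equal(c0$b, pA$b)
  # A = B, kappa = 1: doubled covolume, doubled energy parameter
  c1 <- cluster_ab(1, pB, pB)
  expect_equal(c1$b, 2 * pB$b, tolerance = 1e-12)
  expect_equal(c1$a, 2 * pB$a, tolerance = 1e-12)
  # covolume is monotone non-decreasing in kappa for any pair; the energy
  # parameter is monotone for comparable species (it can dip when the
  # solute's sqrt(a b) dwarfs the solvent's, as it does here)
  ks <- seq(0, 2, by = 0.1)
  ab <- t(vapply(ks, function(k) unlist(cluster_ab(k, pA, pB)), numeric(2)))
  expect_true(all(diff(ab[, "b"]) >= 0))
  aa_same <- vapply(ks, function(k) cluster_ab(k, pB, pB)$a, numeric(1))
  expect_true(all(diff(aa_same) >= 0))
  expect_error(cluster_ab(-0.1, pA, pB), "non-negative")
})

test_that("Gibbs-energy forms evaluate to hand arithmetic and nest", {
  # published Chen constants at 323 K (b' enters as -b'T with b' = -70.319)
  expect_equal(delta_f_rxn(323, c(0.10794, 6093.7, -70.319), "chen"),
               6093.7 + 70.319 * 323, tolerance = 1e-12)
  # published extended-form constants at 323 K
  expect_equal(delta_f_rxn(323, c(0.10756, 443590, 1357.1, -9115.7), "new"),
               443590 + 1357.1 * 323 * log(323) - 9115.7 * 323,
               tolerance = 1e-12)
  # b'' = 0 reduces the extended form to the linear one
  Tg <- seq(300, 345, by = 5)
  expect_equal(delta_f_rxn(Tg, c(0.1, 3e4, 0, -80), "new"),
               delta_f_rxn(Tg, c(0.1, 3e4, 80), "chen"))
})

test_that("apparent and complex mole fractions interconvert", {
  expect_equal(y_from_z(0, 0.5), 0)
  expect_equal(y_from_z(0.3, 0), 0.3)
  expect_equal(y_from_z(0.01, 0.1), 0.01 / 1.001, tolerance = 1e-12)
  z <- c(1e-6, 1e-3, 0.05)
  expect_equal(z_from_y(y_from_z(z, 0.2), 0.2), z, tolerance = 1e-12)
})

test_that("extended model with b'' = 0 equals the Chen model bit-for-bit", {
  set.seed(11)
  for (conv in c("unity", "dilute")) {
    for (k in seq_len(if (conv == "unity") 100 else 10)) {
      Tk <- runif(1, 305, 345)
      P <- runif(1, 8e6, 3e7)
      kap <- runif(1, 0, 0.5)
      a0 <- runif(1, 1e4, 6e4); b0 <- runif(1, -120, 120)
      yn <- y_cluster(Tk, P, c(kap, a0, 0, -b0), "new", complex_phi = conv)
      yc <- y_cluster(Tk, P, c(kap, a0, b0), "chen", complex_phi = conv)
      expect_identical(yn, yc)
    }
  }
})

test_that("the closed form honours its algebraic boundary y(X=0) = 1/(1+2k)", {
  # choose the Gibbs term so the whole exponent cancels at one state
  Tk <- 318; P <- 18e6; kap <- 0.25
  tm <- sccosol:::.cluster_terms(
    data.frame(T_K = Tk, P_MPa = P / 1e6, rho_kg_m3 = 700, y2 = 1e-6),
    kap, clemastine(), co2(), "unity"
  )
  aF <- 8.314 * Tk * (kap * tm$L + tm$Poy - tm$M)
  y <- y_cluster(Tk, P, c(kap, aF, 0), "chen")
  expect_equal(y, 1 / (1 + 2 * kap), tolerance = 1e-9)
})

test_that("solubility rises with the Poynting driving force", {
  # at fixed T the exponent grows with P through the solid-volume term;
  # check monotonicity of the model along an isobar sweep
  ys <- vapply(seq(10e6, 28e6, length.out = 8), function(P) {
    y_cluster(318, P, c(0.1, 4.5e4, 0, -90), "new")
  }, numeric(1))
  expect_true(all(diff(ys) > 0))
})

test_that("reaction thermodynamics follow Gibbs-Helmholtz identifications", {
  th <- reaction_thermo(c(0.108, 6093.7, -70.319), 323, "chen")
  expect_equal(th$dH_J_mol, 6093.7)
  expect_equal(th$dS_J_mol_K, -70.319)

  # extended form with b'' = 0 matches the linear identification
  th2 <- reaction_thermo(c(0.1, 3e4, 0, 80), 323, "new")
  expect_equal(th2$dH_J_mol, 3e4)
  expect_equal(th2$dS_J_mol_K, -80)

  # published constants: modest positive (endothermic) enthalpy at 323 K
  th3 <- reaction_thermo(c(0.10756, 443590, 1357.1, -9115.7), 323, "new")
  expect_equal(th3$dH_J_mol, 443590 - 1357.1 * 323, tolerance = 1e-12)
  expect_gt(th3$dH_J_mol, 0)
})
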