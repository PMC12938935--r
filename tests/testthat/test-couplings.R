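# Frozen oracle values for the dipole kernels:
#  * parallel dipoles perpendicular to the separation axis at alpha = pi:
#    Delta/gamma = (3/4)(1/pi - 1/pi^3) = 0.21454382156...
#    (direct evaluation of the bracket; the projection term vanishes)
ALPHA_PI_DELTA <- 0.75 * (1 / pi - 1 / pi^3)

pair_net <- function(sep, d1 = c(1, 0, 0), d2 = c(1, 0, 0)) {
  trp_network(data.frame(x = 0, y = 0, z = c(0, sep),
                         dx = c(d1[1], d2[1]), dy = c(d1[2], d2[2]),
                         dz = c(d1[3], d2[3])),
              allow_coincident = sep == 0)
}

test_that("Delta matches the bracket oracle and limiting cases", {
  sep_pi <- pi / k0_per_angstrom(280)   # alpha = pi
  D <- coupling_delta(pair_net(sep_pi))
  expect_close(D[1, 2], ALPHA_PI_DELTA, 1e-12)
  expect_equal(D[1, 2], D[2, 1])
  expect_equal(diag(D), c(0, 0))

  # mutually orthogonal dipoles, both perpendicular to the axis
  D0 <- coupling_delta(pair_net(sep_pi, c(1, 0, 0), c(0, 1, 0)))
  expect_close(D0[1, 2], 0, 1e-14)

  # far zone: all 1/alpha terms die off
  Dfar <- coupling_delta(pair_net(1e11))
  expect_lt(abs(Dfar[1, 2]), 1e-8)

  expect_error(coupling_delta(pair_net(0)), "coincident")
  expect_equal(coupling_delta(pair_net(0), mask_coincident = TRUE)[1, 2], 0)
})

test_that("decay matrix: Dicke limit, orthogonal zero, series continuity", {
  # parallel dipoles, r -> 0: G_nm -> gamma
  G <- decay_matrix(pair_net(1e-6))
  expect_close(G[1, 2], 1, 1e-10)
  expect_equal(diag(G), c(1, 1))

  # coincident parallel pair: eigenvalues exactly {2 gamma, 0}
  Gd <- decay_matrix(pair_net(0))
  expect_close(eigen(Gd, symmetric = TRUE)$values, c(2, 0), 1e-12)

  # orthogonal dipoles perpendicular to the axis: G_nm = 0 exactly
  Go <- decay_matrix(pair_net(100, c(1, 0, 0), c(0, 1, 0)))
  expect_close(Go[1, 2], 0, 1e-14)

  # series and direct formula agree across the switchover alpha
  k0 <- k0_per_angstrom(280)
  for (alpha in c(0.049, 0.0501, 0.05, 0.02, 0.08)) {
    g1 <- decay_matrix(pair_net(alpha / k0))[1, 2]
    # independent high-precision route: evaluate the bracket from its
    # trigonometric form using the angle-doubled compensated expression
    b <- (alpha^2 * sin(alpha) + alpha * cos(alpha) - sin(alpha)) / alpha^3
    expect_close(g1, 1.5 * b, 1e-9)
  }
})

test_that("Delta and G are invariant under rigid rotation and translation", {
  net <- make_fixture("pseudo_dimer")
  D0 <- coupling_delta(net); G0 <- decay_matrix(net)
  # rotation by random orthogonal matrix + translation
  set.seed(3)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_); if (det(R) < 0) R[, 1] <- -R[, 1]
  s <- net$sites
  pos <- as.matrix(s[, 1:3]) %*% t(R)
  dip <- as.matrix(s[, 4:6]) %*% t(R)
  s$x <- pos[, 1] + 50; s$y <- pos[, 2] - 20; s$z <- pos[, 3] + 7
  s$dx <- dip[, 1]; s$dy <- dip[, 2]; s$dz <- dip[, 3]
  # renormalize against rounding in the rotation
  nn <- sqrt(s$dx^2 + s$dy^2 + s$dz^2)
  s$dx <- s$dx / nn; s$dy <- s$dy / nn; s$dz <- s$dz / nn
  rot <- trp_network(s)
  expect_close(coupling_delta(rot), D0, 1e-9)
  expect_close(decay_matrix(rot), G0, 1e-9)
})

test_that("eigenmodes: Dicke pair, trivial G, trace identity, biorthogonality", {
  dk <- make_fixture("dicke_pair")
  cs <- coupling_set(dk, mask_coincident = TRUE)
  m <- eigenmodes(cs)
  expect_close(m$rates, c(2, 0), 1e-10)

  # G = gamma I (independent emitters): no bright/dark split
  ip <- independent_pair()
  mi <- eigenmodes(coupling_set(ip))
  expect_close(mi$rates, c(1, 1), 1e-12)
  expect_true(all(!mi$bright))

  # sum rule and biorthogonality on the pseudo-dimer
  m8 <- pseudo_dimer_modes()
  expect_lt(abs(sum(m8$rates) - 8) / 8, 1e-8)
  gram <- Conj(t(m8$left)) %*% m8$right
  expect_close(gram, diag(1 + 0i, 8), 1e-8)
  # ordering: descending rates
  expect_true(all(diff(m8$rates) <= 0))
})

test_that("rate ordering ties break by ascending energy", {
  # two independent emitters with different site energies: equal rates
  ip <- independent_pair()
  ip$sites$epsilon_cm1 <- c(5, -5)
  m <- suppressWarnings(eigenmodes(coupling_set(ip)))
  expect_close(m$rates, c(1, 1), 1e-12)
  expect_true(m$energies[1] < m$energies[2])
})

test_that("lifetimes follow the spectroscopic reciprocal law", {
  # Gamma = 1 cm^-1  ->  tau = 1/(2 pi c) = 5.30884e-12 s
  expect_close(lifetime_s_from_rate_cm1(1), 5.308837e-12, 1e-17)
  expect_equal(lifetime_s_from_rate_cm1(2), lifetime_s_from_rate_cm1(1) / 2)
  expect_identical(lifetime_s_from_rate_cm1(0), Inf)

  dk <- make_fixture("dicke_pair", gamma = 1e-3, gamma_unit = "cm-1")
  m <- eigenmodes(coupling_set(dk, mask_coincident = TRUE))
  lt <- mode_lifetimes(m)
  expect_identical(lt$tau_max, Inf)
  expect_true(lt$dark_flag[2])
  expect_close(lt$tau_min, 1 / (2 * pi * 2.99792458e10 * 2e-3), 1e-18)
  # unit guard
  expect_error(mode_lifetimes(pseudo_dimer_modes()), "cm-1")
})

test_that("static disorder has uniform support and moments", {
  cs <- coupling_set(make_fixture("pseudo_dimer", gamma = 1e-3,
                                  gamma_unit = "cm-1"))
  expect_error(apply_static_disorder(cs, -1), "nonnegative")
  same <- apply_static_disorder(cs, 0, seed = 2)
  expect_equal(same$H0, cs$H0)

  W <- 200
  eps <- unlist(lapply(1:1250, function(s) {
    apply_static_disorder(cs, W, seed = s)$H0 - cs$H0
  }))
  expect_length(eps, 10000L)
  expect_true(all(abs(eps) <= W / 2))
  expect_lt(abs(sd(eps) - W / sqrt(12)), 0.02 * W / sqrt(12))
  # determinism
  expect_identical(apply_static_disorder(cs, W, seed = 9)$H0,
                   apply_static_disorder(cs, W, seed = 9)$H0)
})

test_that("ordered spiral growth strengthens bright and dark extremes", {
  tmpl <- build_dimer_template()
  rates <- lapply(c(1, 2, 4, 8), function(ns) {
    m <- eigenmodes(coupling_set(build_assembly(tmpl, "spiral",
                                                n_spirals = ns)),
                    vectors = FALSE)
    c(max = max(m$rates), min = min(m$rates))
  })
  gmax <- vapply(rates, `[[`, numeric(1), "max")
  gmin <- vapply(rates, `[[`, numeric(1), "min")
  expect_true(all(diff(gmax) >= 0))
  expect_true(all(diff(gmin) <= 0))
})

test_that("effective Hamiltonian assembles blocks in one unit system", {
  cs <- pseudo_dimer_cs()
  H <- effective_hamiltonian(cs)
  expect_close(H - Conj(t(H)), -1i * cs$G, 1e-12)   # anti-Hermitian part
  expect_close(sum(Im(diag(H))), -8 / 2, 1e-10)     # Tr Im = -(N/2) gamma
  # single site: H_eff = omega0 - (i/2) gamma in the carrier frame
  n1 <- trp_network(data.frame(x = 0, y = 0, z = 0, dx = 0, dy = 0, dz = 1),
                    gamma = 1e-3, gamma_unit = "cm-1")
  H1 <- effective_hamiltonian(coupling_set(n1, frame = "carrier"))
  expect_close(H1[1, 1], complex(real = omega0_cm1(280),
                                 imaginary = -0.5e-3), 1e-12)
})
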