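test_that("the five preparations have the stated structure", {
  m <- pseudo_dimer_modes()
  uc <- make_initial_state("uniform_coherent", N = 8)
  expect_close(uc[-1], rep(1 / sqrt(8), 8), 1e-14)
  um <- make_initial_state("uniform_mixed", N = 8)
  expect_close(diag(um)[-1], rep(1 / 8, 8), 1e-14)
  expect_close(um - diag(diag(um)), matrix(0, 9, 9), 1e-15)
  lo <- make_initial_state("localized", N = 8, site = 4)
  expect_equal(which(Mod(lo) > 0), 5L)
  expect_error(make_initial_state("localized", N = 8, site = 9), "1..8")

  sup <- make_initial_state("superradiant", N = 8, modes = m)
  sub <- make_initial_state("subradiant", N = 8, modes = m)
  expect_close(sum(Mod(sup)^2), 1, 1e-12)
  expect_close(sum(Mod(sub)^2), 1, 1e-12)
  # eigen-preparation decays at its own collective rate
  Heff <- effective_hamiltonian(pseudo_dimer_cs())
  resid <- Heff %*% sup[-1] -
    (m$energies[1] - 0.5i * m$rates[1]) * sup[-1]
  expect_close(as.vector(resid), complex(8), 1e-8)
})

test_that("contrast pairs are orthonormal and tubulin-confined", {
  sp <- build_assembly(build_dimer_template(), "two_tubulin")
  part <- partition_network(sp, "tubulin")
  pop <- contrast_pair_states(part, 2, "population", N = 16)
  expect_close(sum(Conj(pop[[1]]) * pop[[2]]), 0, 1e-14)
  expect_close(sum(Mod(pop[[1]][part$groups[[1]] + 1])^2), 1, 1e-14)
  expect_close(sum(Mod(pop[[2]][part$groups[[2]] + 1])^2), 1, 1e-14)
  ph <- contrast_pair_states(part, 2, "phase", N = 16)
  gram <- outer(ph, ph, Vectorize(function(a, b) sum(Conj(a) * b)))
  expect_close(gram, diag(2), 1e-14)
})

test_that("jump operators decompose the decay matrix completely", {
  cs <- pseudo_dimer_cs()
  j <- jump_operators(cs)
  expect_true(all(j$rates >= 0))
  expect_close(sum(j$rates), 8, 1e-10)
  A <- Reduce(`+`, lapply(j$operators, function(L) Conj(t(L)) %*% L))
  expect_close(A[-1, -1], cs$G + 0i, 1e-8)
  expect_close(A[1, ], complex(9), 1e-12)
})

test_that("single emitter relaxes exponentially; ground state is fixed", {
  n1 <- trp_network(data.frame(x = 0, y = 0, z = 0, dx = 0, dy = 0, dz = 1))
  cs <- coupling_set(n1)
  ts <- seq(0, 4, 0.1)
  tr <- lindblad_propagate(cs, make_initial_state("localized", N = 1,
                                                  site = 1), ts)
  p <- site_populations(tr)
  expect_close(p[, "site_1"], exp(-ts), 1e-8)
  expect_close(rowSums(p), rep(1, length(ts)), 1e-10)

  g <- complex(2); g[1] <- 1
  trg <- lindblad_propagate(cs, g, ts)
  expect_close(site_populations(trg)[, "ground"], rep(1, length(ts)), 1e-10)

  # the non-Hermitian route agrees on the scalar exponential
  nh <- nonhermitian_propagate(cs, 1 + 0i, ts)
  expect_close(nh$survival, exp(-ts), 1e-10)
})

test_that("Dicke pair: symmetric decays at 2 gamma, antisymmetric is dark", {
  cs <- coupling_set(make_fixture("dicke_pair"), mask_coincident = TRUE)
  ts <- seq(0, 2, 0.05)
  sym <- c(0, 1, 1) / sqrt(2)
  asym <- c(0, 1, -1) / sqrt(2)
  expect_close(excited_population(lindblad_propagate(cs, sym, ts)),
               exp(-2 * ts), 1e-6)
  expect_close(excited_population(lindblad_propagate(cs, asym, ts)),
               rep(1, length(ts)), 1e-6)
})

test_that("excited-sector equivalence of Lindblad and non-Hermitian routes", {
  cs <- pseudo_dimer_cs()
  ts <- seq(0, 0.01, length.out = 21)
  set.seed(101)
  for (rep in 1:5) {
    psi <- complex(real = rnorm(8), imaginary = rnorm(8))
    psi <- psi / sqrt(sum(Mod(psi)^2))
    tl <- lindblad_propagate(cs, c(0, psi), ts)
    tn <- nonhermitian_propagate(cs, psi, ts)
    err <- max(vapply(seq_along(ts), function(i) {
      max(Mod(tl$rhos[[i]][-1, -1] - outer(tn$psi[i, ], Conj(tn$psi[i, ]))))
    }, numeric(1)))
    expect_lt(err, 1e-6)
  }
})

test_that("trace conservation and monotone excited decay hold along runs", {
  cs <- pseudo_dimer_cs()
  ts <- seq(0, 0.5, length.out = 51)
  tr <- lindblad_propagate(cs, make_initial_state("uniform_coherent", N = 8),
                           ts)
  p <- site_populations(tr)
  expect_close(rowSums(p), rep(1, length(ts)), 1e-8)
  expect_true(all(diff(excited_population(tr)) <= 1e-10))
})

test_that("norm decay of the non-Hermitian run is flagged, unitary when G=0", {
  cs <- pseudo_dimer_cs()
  expect_false(nonhermitian_propagate(
    cs, make_initial_state("uniform_coherent", N = 8),
    c(0, 0.1))$provenance$trace_preserving)
  cs0 <- cs
  cs0$G <- matrix(0, 8, 8)
  nh <- nonhermitian_propagate(cs0, make_initial_state("uniform_coherent",
                                                       N = 8), seq(0, 1, 0.1))
  expect_close(nh$survival, rep(1, 11), 1e-9)
})

test_that("mode projections: quadratic form at t=0, constancy when G=0", {
  cs <- pseudo_dimer_cs()
  m <- pseudo_dimer_modes()
  ts <- seq(0, 0.05, length.out = 11)
  tr <- lindblad_propagate(cs, make_initial_state("uniform_mixed", N = 8), ts)
  proj <- mode_projections(tr, m)
  # direct quadratic-form oracle at t = 0: w_j = sum_n |r_jn|^2 / N
  w0 <- colSums(Mod(m$right)^2) / 8
  expect_close(proj$weights[1, ], w0, 1e-8)

  # superradiant preparation starts almost fully in the top mode
  tr2 <- lindblad_propagate(cs, make_initial_state("superradiant", N = 8,
                                                   modes = m), ts)
  proj2 <- mode_projections(tr2, m)
  expect_gt(proj2$weights[1, 1], 0.9)

  # Hermitian limit: weights constant in time
  csh <- cs
  csh$G <- matrix(0, 8, 8)
  mh <- eigenmodes(csh)
  trh <- lindblad_propagate(csh, make_initial_state("uniform_coherent",
                                                    N = 8), ts)
  projh <- mode_projections(trh, mh)
  expect_close(apply(projh$weights, 2, function(w) max(abs(w - w[1]))),
               rep(0, 8), 1e-7)

  # biorthogonal variant is exposed and normalized differently
  projb <- mode_projections(tr2, m, method = "biorthogonal")
  expect_true(is.matrix(projb$weights))
})

test_that("bright-to-dark crossover is detected for the coherent preparation", {
  cs <- pseudo_dimer_cs()
  m <- pseudo_dimer_modes()
  ts <- seq(0, 2, length.out = 81)
  tr <- lindblad_propagate(cs, make_initial_state("uniform_coherent", N = 8),
                           ts)
  proj <- mode_projections(tr, m)
  # bright weight decays faster; dark eventually dominates
  expect_false(is.na(proj$crossover_time))
  expect_gt(proj$crossover_time, 0)
})

test_that("superradiant and subradiant half-decay times differ by >= 10x", {
  cs <- pseudo_dimer_cs()
  m <- pseudo_dimer_modes()
  half_time <- function(kind, t_max) {
    ts <- seq(0, t_max, length.out = 200)
    tr <- lindblad_propagate(cs, make_initial_state(kind, N = 8, modes = m),
                             ts, rtol = 1e-10, atol = 1e-12,
                             method = "bdf")
    pe <- excited_population(tr)
    i <- which(pe <= 0.5)[1]
    stats::approx(pe[c(i - 1, i)], ts[c(i - 1, i)], xout = 0.5)$y
  }
  t_sup <- half_time("superradiant", 3 * log(2) / max(m$rates))
  t_sub <- half_time("subradiant", 3 * log(2) / min(m$rates))
  expect_close(t_sup, log(2) / max(m$rates), 1e-3)
  expect_gt(t_sub / t_sup, 10)
})
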