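fake_traj <- function(rhos, times = seq_along(rhos) - 1) {
  structure(list(times = times, rhos = rhos, n = nrow(rhos[[1]]) - 1,
                 provenance = list(generator = "constructed")),
            class = "exc_trajectory")
}

test_that("L1 coherence closed forms", {
  uc <- make_initial_state("uniform_coherent", N = 8)
  expect_close(l1_coherence(uc), 7, 1e-12)          # N - 1 for uniform phase
  um <- make_initial_state("uniform_mixed", N = 8)
  expect_close(l1_coherence(um), 0, 1e-15)
  psi <- complex(9); psi[2] <- psi[5] <- 1 / sqrt(2)
  expect_close(pairwise_coherence(psi, 1, 4), 1, 1e-12)
  # subset restriction
  expect_close(l1_coherence(uc, subset = c(1, 2)), 2 / 8, 1e-12)
})

test_that("correlated coherence: closed form, support and mixtures", {
  A <- c(1, 2); B <- c(3, 4)
  psi <- complex(9); psi[c(A, B) + 1] <- 1 / 2
  expect_close(correlated_coherence(psi, A, B), 2, 1e-12)

  onlyA <- complex(9); onlyA[A + 1] <- 1 / sqrt(2)
  expect_close(correlated_coherence(onlyA, A, B), 0, 1e-12)

  um <- make_initial_state("uniform_mixed", N = 8)
  expect_close(correlated_coherence(um, A, B), 0, 1e-12)

  expect_error(correlated_coherence(psi, c(1, 2), c(2, 3)), "overlap")

  # closed form 2 (sum_A |psi|)(sum_B |psi|) on random pure states
  set.seed(7)
  for (i in 1:25) {
    v <- complex(real = rnorm(8), imaginary = rnorm(8))
    v <- v / sqrt(sum(Mod(v)^2))
    psi <- c(0, v)
    got <- correlated_coherence(psi, A, B)
    want <- 2 * sum(Mod(v[A])) * sum(Mod(v[B]))
    expect_close(got, want, 1e-9)
  }
})

test_that("log negativity: Bell value, PPT states, sector bound", {
  psi <- complex(9); psi[2] <- psi[3] <- 1 / sqrt(2)
  expect_close(log_negativity(psi, 1, 2), 1, 1e-10)

  um <- make_initial_state("uniform_mixed", N = 8)
  expect_close(log_negativity(um, 1, 2), 0, 1e-12)

  # brute-force over random single-excitation pure states: 0 <= E_N <= 1
  set.seed(11)
  en <- replicate(200, {
    v <- complex(real = rnorm(8), imaginary = rnorm(8))
    v <- v / sqrt(sum(Mod(v)^2))
    log_negativity(c(0, v), 2, 6)
  })
  expect_true(all(en >= 0 & en <= 1 + 1e-12))
})

test_that("mutual information: product zero, shared excitation = 2 bits", {
  onlyA <- complex(9); onlyA[2] <- 1
  expect_close(mutual_information(onlyA, c(1, 2), c(3, 4)), 0, 1e-10)

  bell <- complex(9); bell[2] <- bell[4] <- 1 / sqrt(2)
  expect_close(mutual_information(bell, c(1, 2), c(3, 4)), 2, 1e-10)

  set.seed(13)
  for (i in 1:10) {
    v <- complex(real = rnorm(8), imaginary = rnorm(8))
    v <- v / sqrt(sum(Mod(v)^2))
    expect_gte(mutual_information(c(0, v), c(1, 3), c(2, 5)), -1e-10)
  }
})

test_that("trace distance: limits and arithmetic", {
  a <- complex(3); a[2] <- 1
  b <- complex(3); b[3] <- 1
  expect_close(trace_distance(a, a), 0, 1e-14)
  expect_close(trace_distance(a, b), 1, 1e-12)
  r1 <- diag(c(1, 0)) + 0i
  r2 <- diag(c(0.5, 0.5)) + 0i
  expect_close(trace_distance(r1, r2), 0.5, 1e-14)
})

test_that("backflow is the discrete total positive variation", {
  # diagonal states engineered so D(t) = d_t exactly
  mk <- function(d) diag(c(1 - d, d, 0)) + 0i
  mk2 <- function() diag(c(1, 0, 0)) + 0i
  dser <- c(1, 0.5, 0.7, 0.6)
  t1 <- fake_traj(lapply(dser, mk))
  t2 <- fake_traj(lapply(dser, function(d) mk2()))
  bf <- backflow_measure(t1, t2)
  expect_close(bf$D, dser, 1e-14)
  expect_close(bf$N, 0.2, 1e-14)
  expect_equal(bf$backflow_intervals, c(FALSE, TRUE, FALSE))

  mono <- c(1, 0.8, 0.5, 0.1)
  bf2 <- backflow_measure(fake_traj(lapply(mono, mk)),
                          fake_traj(lapply(mono, function(d) mk2())))
  expect_equal(bf2$N, 0)

  t3 <- fake_traj(lapply(dser, mk), times = c(0, 1, 2, 4))
  expect_error(backflow_measure(t1, t3), "time grids")
})

test_that("full-system Lindblad evolution is contractive (no backflow)", {
  cs <- pseudo_dimer_cs()
  ts <- seq(0, 0.2, length.out = 41)
  tr1 <- lindblad_propagate(cs, make_initial_state("uniform_coherent", N = 8),
                            ts)
  tr2 <- lindblad_propagate(cs, make_initial_state("localized", N = 8,
                                                   site = 3), ts)
  bf <- backflow_measure(tr1, tr2)
  expect_lt(bf$N, 1e-6)
})

test_that("top_pairs ranks by peak coherence with lexicographic ties", {
  # constructed trajectory: pair (1,2) peaks at 0.8, pair (2,3) at 0.4
  base <- matrix(0 + 0i, 4, 4)
  diag(base) <- c(0, 0.4, 0.4, 0.2)
  r1 <- base; r1[2, 3] <- r1[3, 2] <- 0.1; r1[3, 4] <- r1[4, 3] <- 0.2
  r2 <- base; r2[2, 3] <- r2[3, 2] <- 0.4; r2[3, 4] <- r2[4, 3] <- 0.1
  tp <- top_pairs(fake_traj(list(r1, r2)), k = 2)
  expect_equal(tp$i, c(1, 2))
  expect_equal(tp$j, c(2, 3))
  expect_close(tp$peak, c(0.8, 0.4), 1e-12)
  expect_equal(tp$t_peak, c(1, 0))
  # k larger than available pairs returns all pairs
  tp_all <- top_pairs(fake_traj(list(r1, r2)), k = 99)
  expect_equal(nrow(tp_all), 3L)
})

test_that("metrics are invariant under a global phase", {
  set.seed(5)
  v <- complex(real = rnorm(8), imaginary = rnorm(8))
  v <- v / sqrt(sum(Mod(v)^2))
  psi <- c(0, v)
  phi <- exp(1i * 0.73) * psi
  expect_close(l1_coherence(phi), l1_coherence(psi), 1e-12)
  expect_close(log_negativity(phi, 2, 5), log_negativity(psi, 2, 5), 1e-12)
  expect_close(correlated_coherence(phi, c(1, 2), c(5, 6)),
               correlated_coherence(psi, c(1, 2), c(5, 6)), 1e-12)
  expect_close(mutual_information(phi, c(1, 2), c(5, 6)),
               mutual_information(psi, c(1, 2), c(5, 6)), 1e-10)
})

test_that("phase-contrast backflow dominates population contrast on the spiral", {
  bf <- spiral_backflow()
  expect_gte(bf$phase$reduced$N, bf$population$reduced$N)
})
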