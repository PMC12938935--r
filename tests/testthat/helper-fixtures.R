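# Shared fixtures.  Expensive objects (the single-spiral backflow runs) are
# computed once per test session and cached, since several properties are
# checked on the same trajectories.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

pseudo_dimer_cs <- function() cached("pd_cs", {
  coupling_set(make_fixture("pseudo_dimer"))
})

pseudo_dimer_modes <- function() cached("pd_modes", {
  eigenmodes(pseudo_dimer_cs())
})

# a two-site fixture whose dipoles are mutually orthogonal and both
# perpendicular to the separation axis: Delta and the off-diagonal of G
# vanish exactly, i.e. two independent emitters
independent_pair <- function() {
  trp_network(data.frame(x = 0, y = 0, z = c(0, 50),
                         dx = c(1, 0), dy = c(0, 1), dz = 0))
}

# Single-spiral (13 tubulins, 104 sites) backflow protocol for neighbor
# k = 2: both contrast pairs propagated under the same Liouvillian over
# about two exchange periods of the strongest inter-tubulin coupling
# (|Delta|max ~ 8e2 gamma, period 2 pi / 8e2 ~ 8e-3 / gamma).
spiral_backflow <- function() cached("spiral_bf", {
  sp <- build_assembly(build_dimer_template(), "spiral", n_spirals = 1)
  cs <- coupling_set(sp)
  part <- partition_network(sp, "tubulin")
  jumps <- jump_operators(cs)
  times <- seq(0, 0.015, length.out = 121)
  sub <- c(part$groups[[1]], part$groups[[2]])
  out <- list()
  for (w in c("population", "phase")) {
    pair <- contrast_pair_states(part, 2, w, N = n_sites(sp))
    t1 <- lindblad_propagate(cs, pair[[1]], times, jumps = jumps,
                             rtol = 1e-10, atol = 1e-12)
    t2 <- lindblad_propagate(cs, pair[[2]], times, jumps = jumps,
                             rtol = 1e-10, atol = 1e-12)
    out[[w]] <- list(reduced = backflow_measure(t1, t2, subsystem = sub),
                     full = backflow_measure(t1, t2))
  }
  out
})

# plain n-row site table (unit dipoles along x, spaced along z)
synthetic_sites_for_test <- function(n) {
  data.frame(x = 0, y = 0, z = 15 * (seq_len(n) - 1),
             dx = 1, dy = 0, dz = 0)
}

expect_close <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected)), tol)
}
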