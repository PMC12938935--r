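# State-space convention: dimension N+1; index 1 is the global ground
# (sink) state |0>, index n+1 the single excitation on site n.  Pure states
# are complex vectors, mixed states complex density matrices.

#' Coerce a state to a density matrix
#' @param x complex vector (pure state) or square complex matrix.
#' @return complex density matrix.
#' @export
as_density <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as.complex(x)
  outer(x, Conj(x))
}

embed_excited <- function(amps, N) {
  psi <- complex(length.out = N + 1)
  psi[-1] <- amps
  psi
}

check_density <- function(rho, tol = 1e-10, where = "state") {
  if (abs(sum(diag(rho)) - 1) > tol) {
    stop(where, ": trace deviates from 1 by ",
         signif(abs(sum(diag(rho)) - 1), 3))
  }
  if (max(Mod(rho - Conj(t(rho)))) > tol) stop(where, ": not Hermitian")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop(where, ": negative eigenvalue ", signif(min(ev), 3))
  }
  invisible(TRUE)
}

#' The five initial preparations
#'
#' \describe{
#'   \item{superradiant}{unit-normalized right eigenvector of `H_eff` with
#'     the largest collective decay rate, embedded in the excitation block
#'     (pure).}
#'   \item{subradiant}{same for the smallest rate.}
#'   \item{uniform_coherent}{fully delocalized in-phase single excitation,
#'     amplitude `1/sqrt(N)` on every site (pure).}
#'   \item{uniform_mixed}{maximally mixed single excitation, population
#'     `1/N` on every site with no coherences (mixed).}
#'   \item{localized}{single excitation on site `site` (pure).}
#' }
#'
#' @param kind one of the five preparation names.
#' @param N number of chromophore sites.
#' @param modes a `mode_set` (required for the eigenmode preparations).
#' @param site site index 1..N (required for `localized`).
#' @return complex vector of length `N+1` (pure kinds) or `(N+1)^2` density
#'   matrix (`uniform_mixed`); index 1 is the ground sink.
#' @export
make_initial_state <- function(kind = c("superradiant", "subradiant",
                                        "uniform_coherent", "uniform_mixed",
                                        "localized"),
                               N, modes = NULL, site = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    superradiant = {
      stopifnot(inherits(modes, "mode_set"))
      embed_excited(modes$right[, 1], N)
    },
    subradiant = {
      stopifnot(inherits(modes, "mode_set"))
      embed_excited(modes$right[, ncol(modes$right)], N)
    },
    uniform_coherent = embed_excited(rep(1 / sqrt(N), N), N),
    uniform_mixed = {
      rho <- matrix(0 + 0i, N + 1, N + 1)
      diag(rho)[-1] <- 1 / N
      rho
    },
    localized = {
      if (is.null(site) || site < 1 || site > N) {
        stop("localized preparation needs a site index in 1..", N)
      }
      psi <- complex(length.out = N + 1)
      psi[site + 1] <- 1
      psi
    })
}

#' Contrast-pair preparations on two tubulin subsystems
#'
#' Builds the orthogonal state pairs used for trace-distance backflow
#' analysis between a focal tubulin `T1` and a neighbor `Tk`:
#' `|10> = |T1|^{-1/2} sum_{s in T1} |s>` and
#' `|01> = |Tk|^{-1/2} sum_{r in Tk} |r>` (uniform single excitations
#' delocalized over one full tubulin).  The population pair is
#' `(|10>, |01>)`; the phase pair is `((|10>+|01>)/sqrt(2),
#' (|10>-|01>)/sqrt(2))`.
#'
#' @param partition a `trp_partition` (typically by tubulin).
#' @param k index of the neighbor group `Tk` within the partition.
#' @param which `"population"` or `"phase"`.
#' @param N total number of sites (defaults to the partition's span).
#' @param focal index of the focal group `T1` (default 1).
#' @return list of two pure states (complex vectors of length `N+1`).
#' @export
contrast_pair_states <- function(partition, k,
                                 which = c("population", "phase"),
                                 N = NULL, focal = 1) {
  which <- match.arg(which)
  stopifnot(inherits(partition, "trp_partition"))
  T1 <- partition$groups[[focal]]
  Tk <- partition$groups[[k]]
  if (length(intersect(T1, Tk)) > 0) stop("groups overlap")
  if (is.null(N)) N <- max(unlist(partition$groups))
  s10 <- complex(length.out = N + 1)
  s10[T1 + 1] <- 1 / sqrt(length(T1))
  s01 <- complex(length.out = N + 1)
  s01[Tk + 1] <- 1 / sqrt(length(Tk))
  if (which == "population") list(s10, s01)
  else list((s10 + s01) / sqrt(2), (s10 - s01) / sqrt(2))
}

#' Collective jump operators from the decay matrix
#'
#' Diagonalizes `G = V diag(g_1..g_N) V^T` and assembles one collapse
#' operator per collective decay channel,
#' `L_j = sqrt(g_j) sum_n v_n^{(j)} |0><n|`, which transfers population
#' from the excitonic manifold into the explicit ground sink.  Eigenvalues
#' within `1e-10 * gamma` below zero are clamped to zero; larger negative
#' values raise an error.
#'
#' @param cs a `coupling_set`.
#' @return object of class `jump_operator_set`: list with `rates` (g_j),
#'   `vectors` (columns v^(j)), `operators` (list of (N+1)x(N+1) complex
#'   matrices) and `A` (`sum_j L_j^dag L_j`, the decay matrix embedded in
#'   the excited block).
#' @export
jump_operators <- function(cs) {
  stopifnot(inherits(cs, "coupling_set"))
  e <- eigen(cs$G, symmetric = TRUE)
  g <- e$values
  g[g < 0 & g > -1e-10 * cs$gamma] <- 0
  if (any(g < 0)) stop("decay matrix not positive semidefinite")
  N <- cs$n
  ops <- lapply(seq_len(N), function(j) {
    L <- matrix(0 + 0i, N + 1, N + 1)
    L[1, -1] <- sqrt(g[j]) * e$vectors[, j]
    L
  })
  A <- matrix(0 + 0i, N + 1, N + 1)
  for (L in ops) A <- A + Conj(t(L)) %*% L
  structure(list(rates = g, vectors = e$vectors, operators = ops, A = A),
            class = "jump_operator_set")
}

embed_hamiltonian <- function(cs) {
  N <- cs$n
  H <- matrix(0 + 0i, N + 1, N + 1)
  H[-1, -1] <- diag(cs$H0, N) + cs$Delta
  H
}

#' Propagate the Lindblad master equation
#'
#' Integrates `drho/dt = -i[H, rho] + sum_j (L_j rho L_j^dag -
#' (1/2){L_j^dag L_j, rho})` on the ground+single-excitation space with
#' `H = diag(H0) + Delta` (Hermitian part only) and the collective jump
#' operators of [jump_operators()].  Uses the adaptive complex ODE solver
#' `deSolve::zvode`; the right-hand side is evaluated in compiled code.
#' Time is measured in units of `1/gamma` for unit system `"gamma"`, or in
#' `1/(2 pi c gamma[cm-1])` seconds worth of phase for `"cm-1"`.
#'
#' The trace is verified to stay within `1e-8` of 1 at every output time
#' (an error with the worst-time diagnostic otherwise).  Positivity is
#' checked at every output time for small systems (dimension <= 41) and at
#' the final time otherwise; its tolerance is
#' `max(1e-8, 10 * rtol * spectral_radius * t_max)`, the scale at which
#' global integration error accumulates over fast near-field oscillations.
#'
#' @param cs a `coupling_set`.
#' @param rho0 initial state (pure vector of length N+1 or density matrix).
#' @param times numeric output time grid (monotone, starting at 0).
#' @param jumps optional precomputed `jump_operator_set`.
#' @param rtol,atol integrator tolerances (defaults 1e-12, 1e-14; tight
#'   because the near-field couplings put fast oscillations in the
#'   solution and global error grows with the integrated phase).
#' @param method `"adams"` (non-stiff, default) or `"bdf"`.
#' @param maxsteps maximum internal integrator steps.
#' @return object of class `exc_trajectory`: list with `times`, `rhos`
#'   (list of density matrices), `n` (number of sites) and provenance
#'   (integrator settings and diagnostics).
#' @export
lindblad_propagate <- function(cs, rho0, times, jumps = NULL,
                               rtol = 1e-12, atol = 1e-14,
                               method = c("adams", "bdf"),
                               maxsteps = 5e5) {
  method <- match.arg(method)
  stopifnot(inherits(cs, "coupling_set"))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  N <- cs$n
  d <- N + 1
  rho0 <- as_density(rho0)
  if (!all(dim(rho0) == d)) {
    stop("initial state has dimension ", nrow(rho0), ", expected ", d)
  }
  check_density(rho0, tol = 1e-8, where = "initial state")
  if (is.null(jumps)) jumps <- jump_operators(cs)
  H <- embed_hamiltonian(cs)
  A <- jumps$A
  B <- H - 0.5i * A

  rhs <- function(t, y, parms) {
    list(lindblad_rhs_cpp(y, parms$B, parms$A))
  }
  out <- deSolve::zvode(y = as.vector(rho0), times = times, func = rhs,
                        parms = list(B = B, A = A),
                        rtol = rtol, atol = atol,
                        mf = if (method == "adams") 10 else 22,
                        maxsteps = maxsteps)
  if (nrow(out) < length(times)) {
    stop("integrator stopped early at t = ", signif(Re(out[nrow(out), 1]), 4))
  }
  rhos <- lapply(seq_len(nrow(out)), function(i) {
    m <- matrix(out[i, -1], d, d)
    (m + Conj(t(m))) / 2   # symmetrize numerical Hermiticity noise
  })
  tr_dev <- vapply(rhos, function(r) abs(Re(sum(diag(r))) - 1), numeric(1))
  if (max(tr_dev) > 1e-8) {
    stop("trace preservation violated: deviation ", signif(max(tr_dev), 3),
         " at t = ", signif(times[which.max(tr_dev)], 4))
  }
  # global integration error grows like rtol * (spectral radius * window),
  # so the positivity surrogate is checked at that scale (floor 1e-8)
  omega <- max(abs(B))
  pos_tol <- max(1e-8, 10 * rtol * max(1, omega * max(times)))
  check_idx <- if (d <= 41) seq_along(rhos) else length(rhos)
  for (i in check_idx) {
    ev <- eigen(rhos[[i]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -pos_tol) {
      stop("positivity violated: min eigenvalue ", signif(min(ev), 3),
           " at t = ", signif(times[i], 4))
    }
  }
  structure(list(times = times, rhos = rhos, n = N,
                 provenance = list(generator = "lindblad",
                                   integrator = "zvode", method = method,
                                   rtol = rtol, atol = atol,
                                   max_trace_dev = max(tr_dev))),
            class = "exc_trajectory")
}

#' @export
print.exc_trajectory <- function(x, ...) {
  cat("exc_trajectory:", x$n, "sites,", length(x$times),
      "time points in [", min(x$times), ",", max(x$times), "]\n")
  invisible(x)
}

#' Propagate with the effective non-Hermitian Hamiltonian
#'
#' Evolves a pure excited state as `psi(t) = exp(-i H_eff t) psi(0)` in the
#' excitation block, via the complex eigendecomposition of `H_eff`.  The
#' squared norm is the survival probability; this evolution is explicitly
#' NOT trace preserving (the lost norm is the population emitted to the
#' radiation field).  For any pure excited initial state it coincides with
#' the excited-sector block of the Lindblad evolution, since all jump
#' operators feed the sink and never repopulate the excited manifold.
#'
#' @param cs a `coupling_set` (or a complex `H_eff` matrix).
#' @param psi0 complex amplitudes on the N sites (length N, or length N+1
#'   with zero ground amplitude).
#' @param times numeric output time grid.
#' @return object of class `nh_trajectory`: list with `times`, `psi`
#'   (length(times) x N complex matrix of site amplitudes), `survival`
#'   (squared norms) and provenance.
#' @export
nonhermitian_propagate <- function(cs, psi0, times) {
  Heff <- if (inherits(cs, "coupling_set")) effective_hamiltonian(cs) else cs
  N <- nrow(Heff)
  psi0 <- as.complex(psi0)
  if (length(psi0) == N + 1) {
    if (Mod(psi0[1]) > 1e-12) {
      stop("psi0 has ground-state amplitude; the non-Hermitian propagator ",
           "acts on the excitation block only")
    }
    psi0 <- psi0[-1]
  }
  if (length(psi0) != N) stop("psi0 has wrong length")
  e <- eigen(Heff)
  c0 <- solve(e$vectors, psi0)
  psi_t <- vapply(times, function(t) {
    e$vectors %*% (exp(-1i * e$values * t) * c0)
  }, complex(N))
  psi_t <- t(matrix(psi_t, nrow = N))
  structure(list(times = times, psi = psi_t,
                 survival = rowSums(Mod(psi_t)^2),
                 provenance = list(generator = "nonhermitian",
                                   trace_preserving = FALSE)),
            class = "nh_trajectory")
}

#' Site populations along a trajectory
#'
#' @param traj an `exc_trajectory` (Lindblad) or `nh_trajectory`
#'   (non-Hermitian; ground population is reported as the lost norm).
#' @return matrix `length(times) x (N+1)` with columns `ground`,
#'   `site_1..site_N`; rows of a Lindblad trajectory sum to 1.
#' @export
site_populations <- function(traj) {
  if (inherits(traj, "nh_trajectory")) {
    pops <- Mod(traj$psi)^2
    out <- cbind(1 - rowSums(pops), pops)
  } else {
    out <- t(vapply(traj$rhos, function(r) Re(diag(r)),
                    numeric(traj$n + 1)))
  }
  colnames(out) <- c("ground", paste0("site_", seq_len(ncol(out) - 1)))
  out
}

#' Total excited-state population along a trajectory
#' @param traj an `exc_trajectory` or `nh_trajectory`.
#' @return numeric vector over the time grid.
#' @export
excited_population <- function(traj) {
  p <- site_populations(traj)
  rowSums(p[, -1, drop = FALSE])
}

#' Project a trajectory onto the collective eigenmodes
#'
#' Mode weights `w_j(t)`.  With `method = "right"` (default)
#' `w_j = <r_j| rho |r_j>` using unit-normalized right eigenvectors of
#' `H_eff`; with `method = "biorthogonal"` the weights use the biorthogonal
#' left vectors, `w_j = <l_j| rho |l_j>`.  The bright (dark) weight is the
#' sum over modes with `Gamma_j/gamma > 1` (`< 1`); the crossover time is
#' the first output time at which the dark weight exceeds the bright
#' weight.
#'
#' @param traj an `exc_trajectory`.
#' @param modes a `mode_set` for the same network.
#' @param method `"right"` or `"biorthogonal"`.
#' @return list with `weights` (times x N matrix), `bright`, `dark`
#'   (numeric vectors), and `crossover_time` (NA if none).
#' @export
mode_projections <- function(traj, modes, method = c("right", "biorthogonal")) {
  method <- match.arg(method)
  stopifnot(inherits(modes, "mode_set"))
  V <- if (method == "right") modes$right else modes$left
  N <- traj$n
  W <- t(vapply(traj$rhos, function(r) {
    ree <- r[-1, -1, drop = FALSE]
    Re(diag(Conj(t(V)) %*% ree %*% V))
  }, numeric(N)))
  bright <- rowSums(W[, modes$bright, drop = FALSE])
  dark <- rowSums(W[, !modes$bright, drop = FALSE])
  cross <- which(dark > bright)
  list(weights = W, bright = bright, dark = dark,
       crossover_time = if (length(cross) > 0) traj$times[cross[1]] else NA_real_,
       method = method)
}
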