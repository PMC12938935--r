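# Pairwise geometry helpers -------------------------------------------------

pair_geometry <- function(net) {
  p <- as.matrix(net$sites[, c("x", "y", "z")])
  mu <- as.matrix(net$sites[, c("dx", "dy", "dz")])
  n <- nrow(p)
  dx <- outer(p[, 1], p[, 1], "-")
  dy <- outer(p[, 2], p[, 2], "-")
  dz <- outer(p[, 3], p[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  mm <- mu %*% t(mu)                       # mu_n . mu_m
  # mu_n . rhat_nm and mu_m . rhat_nm (rhat points n -> m, sign cancels in
  # the product, so orientation convention does not matter)
  rs <- r; rs[rs == 0] <- 1
  # r_nm vector from n to m has components -(dx,dy,dz) as built above
  an <- (-(dx) * mu[, 1][row(dx)] - (dy) * mu[, 2][row(dy)] - (dz) * mu[, 3][row(dz)]) / rs
  am <- (-(dx) * mu[, 1][col(dx)] - (dy) * mu[, 2][col(dy)] - (dz) * mu[, 3][col(dz)]) / rs
  list(r = r, mm = mm, proj = an * am, n = n)
}

# Oscillatory brackets of the dipole coupling and decay kernels.
# b1/b2 multiply (mu_n.mu_m) and (mu_n.rhat)(mu_m.rhat) in Delta;
# c1/c2 are the corresponding decay-kernel brackets.  c1 and c2 suffer
# catastrophic cancellation as alpha -> 0 and switch to a power series
# below ALPHA_SERIES_SWITCH (series truncation error < 1e-14 there).
ALPHA_SERIES_SWITCH <- 0.05

delta_brackets <- function(a) {
  list(b1 = -cos(a) / a + sin(a) / a^2 + cos(a) / a^3,
       b2 = -cos(a) / a + 3 * sin(a) / a^2 + 3 * cos(a) / a^3)
}

decay_brackets <- function(a) {
  c1 <- sin(a) / a + cos(a) / a^2 - sin(a) / a^3
  c2 <- sin(a) / a + 3 * cos(a) / a^2 - 3 * sin(a) / a^3
  small <- which(a < ALPHA_SERIES_SWITCH)
  if (length(small) > 0) {
    as <- a[small]
    s1 <- 0; s2 <- 0
    for (j in 0:10) {
      term <- (-1)^j * as^(2 * j)
      f1 <- 1 / factorial(2 * j + 1) - (2 * j + 2) / factorial(2 * j + 3)
      f2 <- 1 / factorial(2 * j + 1) - 3 * (2 * j + 2) / factorial(2 * j + 3)
      s1 <- s1 + term * f1
      s2 <- s2 + term * f2
    }
    c1[small] <- s1
    c2[small] <- s2
  }
  list(c1 = c1, c2 = c2)
}

#' Coherent dipole-dipole coupling matrix
#'
#' Off-diagonal interaction strengths between transition dipoles n and m,
#' in units of the single-site radiative rate gamma:
#' \deqn{\Delta_{nm} = \frac{3\gamma}{4}\Big[
#'   \big(-\tfrac{\cos\alpha}{\alpha} + \tfrac{\sin\alpha}{\alpha^2}
#'        + \tfrac{\cos\alpha}{\alpha^3}\big)\,\hat\mu_n\cdot\hat\mu_m
#'   - \big(-\tfrac{\cos\alpha}{\alpha} + \tfrac{3\sin\alpha}{\alpha^2}
#'        + \tfrac{3\cos\alpha}{\alpha^3}\big)\,
#'     (\hat\mu_n\cdot\hat r_{nm})(\hat\mu_m\cdot\hat r_{nm})\Big]}
#' with \eqn{\alpha_{nm} = k_0 r_{nm}}, \eqn{k_0 = 2\pi/\lambda_0}.  The
#' diagonal is zero (no self-coupling).
#'
#' @param net a `trp_network` with at least two sites.
#' @param mask_coincident if TRUE, coincident site pairs get
#'   `Delta = 0` instead of raising an error (Dicke-limit fixtures only).
#' @return symmetric N x N matrix in units of `net$gamma`.
#' @export
coupling_delta <- function(net, mask_coincident = FALSE) {
  if (n_sites(net) < 2) stop("coupling_delta needs at least two sites")
  g <- pair_geometry(net)
  k0 <- k0_per_angstrom(net$lambda0)
  a <- k0 * g$r
  coinc <- g$r < 1e-12; diag(coinc) <- FALSE
  if (any(coinc) && !mask_coincident) {
    ij <- which(coinc, arr.ind = TRUE)[1, ]
    stop("singular geometry: sites ", ij[1], " and ", ij[2],
         " are coincident; Delta diverges (mask_coincident = TRUE to zero it)")
  }
  a[a == 0] <- 1  # dummy, overwritten below
  br <- delta_brackets(a)
  D <- 0.75 * net$gamma * (br$b1 * g$mm - br$b2 * g$proj)
  D[coinc] <- 0
  diag(D) <- 0
  D <- (D + t(D)) / 2
  D
}

#' Collective radiative decay matrix
#'
#' \deqn{G_{nm} = \frac{3\gamma}{2}\Big[
#'   \big(\tfrac{\sin\alpha}{\alpha} + \tfrac{\cos\alpha}{\alpha^2}
#'        - \tfrac{\sin\alpha}{\alpha^3}\big)\,\hat\mu_n\cdot\hat\mu_m
#'   - \big(\tfrac{\sin\alpha}{\alpha} + \tfrac{3\cos\alpha}{\alpha^2}
#'        - \tfrac{3\sin\alpha}{\alpha^3}\big)\,
#'     (\hat\mu_n\cdot\hat r_{nm})(\hat\mu_m\cdot\hat r_{nm})\Big]}
#' with diagonal `G_nn = gamma` exactly.  For `alpha` below 0.05 the
#' brackets are evaluated by power series to avoid catastrophic
#' cancellation; coincident sites take the analytic `alpha -> 0` limit
#' `gamma * (mu_n . mu_m)`.
#'
#' @param net a `trp_network`.
#' @return symmetric positive-semidefinite N x N matrix, units of
#'   `net$gamma`.
#' @export
decay_matrix <- function(net) {
  n <- n_sites(net)
  if (n == 1) return(matrix(net$gamma, 1, 1))
  g <- pair_geometry(net)
  k0 <- k0_per_angstrom(net$lambda0)
  a <- k0 * g$r
  coinc <- g$r < 1e-12; diag(coinc) <- FALSE
  a[a == 0] <- 1
  br <- decay_brackets(a)
  G <- 1.5 * net$gamma * (br$c1 * g$mm - br$c2 * g$proj)
  # coincident pair: alpha -> 0 limit is gamma * (mu_n . mu_m)
  G[coinc] <- net$gamma * g$mm[coinc]
  diag(G) <- net$gamma
  (G + t(G)) / 2
}

#' Assemble a coupling set from a network
#'
#' Computes `Delta` and `G`, records the unit system, and carries the
#' diagonal site energies.  In the default rotating frame `H0` holds only
#' the static site-energy offsets (the common carrier energy hbar*omega0 is
#' a global phase on the single-excitation manifold and is dropped); set
#' `frame = "carrier"` to add omega0 (in cm^-1; only meaningful when
#' `gamma_unit == "cm-1"`).
#'
#' @param net a `trp_network`.
#' @param mask_coincident passed to [coupling_delta()].
#' @param frame `"rotating"` (default) or `"carrier"`.
#' @return an object of class `coupling_set`: list with `H0` (length-N
#'   diagonal, unit system of `gamma`), `Delta`, `G` (N x N, same units),
#'   `gamma`, `gamma_unit`, `lambda0`, `n`, `provenance`.
#' @export
coupling_set <- function(net, mask_coincident = FALSE,
                         frame = c("rotating", "carrier")) {
  frame <- match.arg(frame)
  n <- n_sites(net)
  G <- decay_matrix(net)
  Delta <- if (n >= 2) coupling_delta(net, mask_coincident) else
    matrix(0, 1, 1)
  # guard: G must be PSD up to numerical noise
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * net$gamma) {
    stop("decay matrix has a negative eigenvalue ", signif(min(ev), 4),
         "; geometry or unit error")
  }
  H0 <- net$sites$epsilon_cm1
  if (net$gamma_unit != "cm-1" && any(H0 != 0)) {
    warning("site-energy offsets are interpreted in units of gamma because ",
            "gamma_unit is not 'cm-1'")
  }
  if (frame == "carrier") {
    if (net$gamma_unit != "cm-1") {
      stop("carrier frame requires gamma_unit 'cm-1'")
    }
    H0 <- H0 + omega0_cm1(net$lambda0)
  }
  structure(list(H0 = H0, Delta = Delta, G = G, gamma = net$gamma,
                 gamma_unit = net$gamma_unit, lambda0 = net$lambda0,
                 n = n, frame = frame,
                 provenance = net$provenance),
            class = "coupling_set")
}

#' Effective non-Hermitian Hamiltonian
#'
#' `H_eff = diag(H0) + Delta - (i/2) G`, all blocks in the coupling set's
#' declared unit system.  Its complex eigenvalues `E_j - (i/2) Gamma_j`
#' carry the collective mode energies and radiative decay rates.
#'
#' @param cs a `coupling_set`.
#' @return complex N x N matrix.
#' @export
effective_hamiltonian <- function(cs) {
  stopifnot(inherits(cs, "coupling_set"))
  diag(cs$H0, cs$n) + cs$Delta - 0.5i * cs$G
}

#' Diagonalize the effective Hamiltonian into collective modes
#'
#' Eigenvalues are split into mode energies `E_j = Re` and radiative rates
#' `Gamma_j = -2 Im`, ordered by descending rate (ties broken by ascending
#' energy, then by index).  Rates within `1e-10 * gamma` below zero are
#' clamped to zero.  Modes are classified bright/superradiant
#' (`Gamma_j/gamma > 1`) or dark/subradiant (`Gamma_j/gamma < 1`); modes
#' within 1e-9 of the threshold are flagged ambiguous.  Left eigenvectors
#' are the rows of the inverse right-eigenvector matrix, so left/right
#' biorthonormality holds by construction.
#'
#' @param x a `coupling_set` or a complex matrix from
#'   [effective_hamiltonian()].
#' @param gamma single-site rate used for classification (taken from the
#'   coupling set when available).
#' @param vectors set FALSE to skip eigenvectors (faster for rate-only
#'   scans over large assemblies).
#' @return an object of class `mode_set`: list with `energies`, `rates`,
#'   `ratio` (`Gamma_j/gamma`), `right` and `left` (N x N complex matrices,
#'   mode j in column j), `bright`, `ambiguous`, `gamma`, `gamma_unit`.
#' @export
eigenmodes <- function(x, gamma = NULL, vectors = TRUE) {
  if (inherits(x, "coupling_set")) {
    H <- effective_hamiltonian(x)
    gamma <- x$gamma
    gamma_unit <- x$gamma_unit
  } else {
    H <- x
    if (is.null(gamma)) gamma <- 1
    gamma_unit <- "gamma"
  }
  e <- eigen(H, only.values = !vectors)
  energies <- Re(e$values)
  rates <- -2 * Im(e$values)
  rates[abs(rates) < 1e-10 * gamma] <- 0  # numerically dark modes
  ord <- order(-rates, energies, seq_along(rates))
  energies <- energies[ord]; rates <- rates[ord]
  if (vectors) {
    right <- e$vectors[, ord, drop = FALSE]
    # unit-normalize right eigenvectors (eigen() already does, but be exact)
    right <- sweep(right, 2, sqrt(colSums(Mod(right)^2)), "/")
    left <- Conj(t(solve(right)))   # <l_i | r_j> = delta_ij
  } else {
    right <- NULL; left <- NULL
  }
  ratio <- rates / gamma
  structure(list(energies = energies, rates = rates, ratio = ratio,
                 right = right, left = left,
                 bright = ratio > 1,
                 ambiguous = abs(ratio - 1) < 1e-9,
                 gamma = gamma, gamma_unit = gamma_unit),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  n <- length(x$rates)
  cat("mode_set:", n, "modes;", sum(x$bright), "bright,",
      sum(!x$bright), "dark (threshold Gamma/gamma = 1)\n")
  cat("  Gamma_max/gamma =", signif(max(x$ratio), 5),
      " Gamma_min/gamma =", signif(min(x$ratio), 5), "\n")
  invisible(x)
}

#' Radiative lifetimes of the collective modes
#'
#' Applies the spectroscopic relation `tau_j = 1/(2*pi*c*Gamma_j)` with c =
#' 2.99792458e10 cm/s.  Rates must be in cm^-1 (`gamma_unit == "cm-1"`);
#' zero rates yield `tau = +Inf`, flagged as perfectly dark.
#'
#' @param modes a `mode_set` with rates in cm^-1.
#' @return list with `tau_s` (per-mode lifetimes, seconds, in mode order),
#'   `tau_min` (most superradiant), `tau_max` (most subradiant), and
#'   `dark_flag` (TRUE where the rate was exactly zero).
#' @export
mode_lifetimes <- function(modes) {
  stopifnot(inherits(modes, "mode_set"))
  if (!identical(modes$gamma_unit, "cm-1")) {
    stop("lifetimes require rates in cm-1; this mode_set is in unit '",
         modes$gamma_unit, "'")
  }
  tau <- lifetime_s_from_rate_cm1(modes$rates)
  list(tau_s = tau, tau_min = min(tau), tau_max = max(tau),
       dark_flag = modes$rates == 0)
}

#' Add static diagonal (site-energy) disorder
#'
#' Adds i.i.d. site-energy shifts drawn uniformly from `[-W/2, W/2]` to the
#' diagonal of `H0`; `Delta` and `G` are untouched.  Deterministic per
#' seed.
#'
#' @param cs a `coupling_set`.
#' @param W disorder strength (full width), same unit system as the
#'   coupling set (cm^-1 in physical runs).
#' @param seed integer RNG seed.
#' @return a new `coupling_set` with perturbed `H0`.
#' @export
apply_static_disorder <- function(cs, W, seed = 1) {
  stopifnot(inherits(cs, "coupling_set"))
  if (W < 0) stop("disorder strength W must be nonnegative")
  eps <- with_seed(seed, runif(cs$n, -W / 2, W / 2))
  cs$H0 <- cs$H0 + eps
  cs$provenance <- c(cs$provenance,
                     list(static_disorder = list(W = W, seed = seed)))
  cs
}

#' Export a mode table
#'
#' @param modes a `mode_set`.
#' @param path optional CSV path; when given the table is also written.
#' @return data.frame with columns `j, E, Gamma, Gamma_over_gamma, bright`
#'   (+ `tau_s` when rates are in cm^-1).
#' @export
mode_table <- function(modes, path = NULL) {
  df <- data.frame(j = seq_along(modes$rates),
                   E = modes$energies,
                   Gamma = modes$rates,
                   Gamma_over_gamma = modes$ratio,
                   bright = modes$bright)
  if (identical(modes$gamma_unit, "cm-1")) {
    df$tau_s <- lifetime_s_from_rate_cm1(modes$rates)
  }
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
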