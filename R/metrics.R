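# Quantum-information measures over single-excitation states.
# Convention: density matrices are (N+1)-dimensional with index 1 = ground
# sink; "site index sets" use 1..N and are mapped internally to rows 2..N+1.

#' Reduce a state to a subset of sites
#'
#' Partial trace of a ground+single-excitation density matrix onto the
#' space spanned by the ground state and the excitations of `sites`.
#' Populations of traced-out sites accumulate in the ground entry;
#' coherences involving traced-out sites are discarded.
#'
#' @param rho density matrix (or pure vector) of dimension N+1.
#' @param sites integer site indices (1..N) to keep.
#' @return density matrix of dimension `length(sites) + 1`; entry 1 is the
#'   ground/vacuum of the subsystem.
#' @export
reduce_to_sites <- function(rho, sites) {
  rho <- as_density(rho)
  N <- nrow(rho) - 1
  stopifnot(all(sites >= 1), all(sites <= N), !anyDuplicated(sites))
  keep <- sites + 1
  drop <- setdiff(seq_len(N) + 1, keep)
  out <- matrix(0 + 0i, length(sites) + 1, length(sites) + 1)
  out[1, 1] <- rho[1, 1] + sum(diag(rho)[drop])
  out[1, -1] <- rho[1, keep]
  out[-1, 1] <- rho[keep, 1]
  out[-1, -1] <- rho[keep, keep]
  out
}

#' L1 norm of coherence
#'
#' Sum of absolute off-diagonal elements in the site basis,
#' `C = sum_{a != b} |rho_ab|`.  By default the sink row/column is
#' excluded: the ground state carries no optical coherence in this model.
#'
#' @param rho density matrix or pure vector (dimension N+1).
#' @param subset optional site indices (1..N) restricting the sum.
#' @param include_sink include coherences with the ground state.
#' @return nonnegative scalar.
#' @export
l1_coherence <- function(rho, subset = NULL, include_sink = FALSE) {
  rho <- as_density(rho)
  N <- nrow(rho) - 1
  idx <- if (is.null(subset)) seq_len(N) + 1 else subset + 1
  if (include_sink) idx <- c(1, idx)
  block <- Mod(rho[idx, idx, drop = FALSE])
  sum(block) - sum(diag(block))
}

#' Pairwise L1 coherence of two sites
#'
#' `2 |rho_ij|` in the site basis.
#'
#' @param rho density matrix or pure vector.
#' @param i,j site indices (1..N).
#' @return nonnegative scalar.
#' @export
pairwise_coherence <- function(rho, i, j) {
  rho <- as_density(rho)
  2 * Mod(rho[i + 1, j + 1])
}

#' Correlated coherence between two composite subsystems
#'
#' `C_cc = C_L1(rho_AB) - C_L1(rho_A) - C_L1(rho_B)`, with each reduction
#' obtained by partial trace onto {vacuum + single excitation} of the
#' subset ([reduce_to_sites()]).  Quantifies the coherence shared between
#' the subsystems rather than contained within either.  For a pure
#' single-excitation state with site amplitudes `psi` this equals
#' `2 (sum_{a in A} |psi_a|) (sum_{b in B} |psi_b|)`.
#'
#' All coherences are evaluated in the site basis (the local-eigenbasis
#' rotated variant is available via `rotate_local = TRUE`, which rotates
#' each reduction to its own eigenbasis before the joint L1 sum).
#'
#' @param state density matrix or pure vector.
#' @param A,B disjoint integer site-index sets.
#' @param rotate_local use local-eigenbasis rotation (default FALSE).
#' @return scalar (nonnegative for the site-basis variant on
#'   single-excitation states).
#' @export
correlated_coherence <- function(state, A, B, rotate_local = FALSE) {
  if (length(intersect(A, B)) > 0) stop("subsystems A and B overlap")
  rho <- as_density(state)
  AB <- c(A, B)
  rho_ab <- reduce_to_sites(rho, AB)
  rho_a <- reduce_to_sites(rho, A)
  rho_b <- reduce_to_sites(rho, B)
  if (rotate_local) {
    # rotate the joint state by the local eigenbases of the reductions
    Ua <- eigen(rho_a[-1, -1, drop = FALSE], symmetric = TRUE)$vectors
    Ub <- eigen(rho_b[-1, -1, drop = FALSE], symmetric = TRUE)$vectors
    U <- diag(1 + 0i, length(AB) + 1)
    U[1 + seq_along(A), 1 + seq_along(A)] <- Ua
    U[1 + length(A) + seq_along(B), 1 + length(A) + seq_along(B)] <- Ub
    rho_ab <- Conj(t(U)) %*% rho_ab %*% U
    rho_a <- Conj(t(Ua)) %*% rho_a[-1, -1] %*% Ua
    rho_b <- Conj(t(Ub)) %*% rho_b[-1, -1] %*% Ub
    c_ab <- sum(Mod(rho_ab[-1, -1])) - sum(diag(Mod(rho_ab[-1, -1])))
    c_a <- sum(Mod(rho_a)) - sum(diag(Mod(rho_a)))
    c_b <- sum(Mod(rho_b)) - sum(diag(Mod(rho_b)))
    return(c_ab - c_a - c_b)
  }
  l1_coherence(rho_ab, seq_along(AB)) -
    l1_coherence(rho_a, seq_along(A)) -
    l1_coherence(rho_b, seq_along(B))
}

#' Logarithmic negativity of a site pair
#'
#' Reduces the state to the two-qubit space of sites `i` and `j` (vacuum
#' and traced-out weight map to `|00>`; the double excitation `|11>` is
#' empty on the single-excitation manifold), applies the partial transpose
#' on the second qubit explicitly, and returns
#' `E_N = log2 || rho^{T_B} ||_1`.
#'
#' @param rho density matrix or pure vector.
#' @param i,j site indices (1..N).
#' @return `E_N >= 0`; at most 1 on the single-excitation manifold.
#' @export
log_negativity <- function(rho, i, j) {
  rho <- as_density(rho)
  ii <- i + 1; jj <- j + 1
  # two-qubit basis |ab>, a = excitation on i, b = excitation on j,
  # index = 2a + b + 1  ->  1:|00>, 2:|01>, 3:|10>, 4:|11>
  r2 <- matrix(0 + 0i, 4, 4)
  r2[1, 1] <- 1 - Re(rho[ii, ii]) - Re(rho[jj, jj])
  r2[3, 3] <- rho[ii, ii]
  r2[2, 2] <- rho[jj, jj]
  r2[3, 2] <- rho[ii, jj]; r2[2, 3] <- rho[jj, ii]
  r2[1, 3] <- rho[1, ii];  r2[3, 1] <- rho[ii, 1]
  r2[1, 2] <- rho[1, jj];  r2[2, 1] <- rho[jj, 1]
  # partial transpose on qubit B: (a,b);(a',b') -> (a,b');(a',b)
  pt <- matrix(0 + 0i, 4, 4)
  for (a in 0:1) for (b in 0:1) for (a2 in 0:1) for (b2 in 0:1) {
    pt[2 * a + b2 + 1, 2 * a2 + b + 1] <- r2[2 * a + b + 1, 2 * a2 + b2 + 1]
  }
  ev <- eigen((pt + Conj(t(pt))) / 2, symmetric = TRUE, only.values = TRUE)$values
  max(0, log2(sum(abs(ev))))
}

#' Von Neumann entropy (base 2)
#'
#' Eigenvalues below `1e-12` are dropped.
#'
#' @param rho density matrix.
#' @return entropy in bits.
#' @export
von_neumann_entropy <- function(rho) {
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12]
  -sum(ev * log2(ev))
}

#' Mutual information between two site subsets
#'
#' `I(A:B) = S(rho_A) + S(rho_B) - S(rho_AB)` with von Neumann entropies in
#' bits and reductions by [reduce_to_sites()].
#'
#' @param rho density matrix or pure vector.
#' @param A,B disjoint site-index sets.
#' @return nonnegative scalar (bits).
#' @export
mutual_information <- function(rho, A, B) {
  if (length(intersect(A, B)) > 0) stop("subsystems A and B overlap")
  rho <- as_density(rho)
  von_neumann_entropy(reduce_to_sites(rho, A)) +
    von_neumann_entropy(reduce_to_sites(rho, B)) -
    von_neumann_entropy(reduce_to_sites(rho, c(A, B)))
}

#' Trace distance between two states
#'
#' `D = (1/2) || rho1 - rho2 ||_1 = (1/2) sum |eigenvalues(rho1 - rho2)|`.
#'
#' @param rho1,rho2 density matrices or pure vectors of equal dimension.
#' @return scalar in [0, 1].
#' @export
trace_distance <- function(rho1, rho2) {
  d <- as_density(rho1) - as_density(rho2)
  ev <- eigen((d + Conj(t(d))) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(abs(ev)) / 2
}

#' Trace-distance backflow between two trajectories
#'
#' Reduces both trajectories to `subsystem` at every output time, computes
#' the trace distance series `D(t)`, and accumulates the discrete total
#' positive variation `N = sum_i max(0, D(t_{i+1}) - D(t_i))` --- the
#' grid-level analogue of integrating `dD/dt` over intervals where it is
#' positive.  For CP-divisible (Markovian) reduced dynamics `D` is
#' contractive and `N = 0`; transient increases witness information
#' backflow from the traced-out environment.  The output grid spacing is
#' part of the result's provenance: no smoothing or differentiation is
#' applied.
#'
#' @param traj1,traj2 `exc_trajectory` objects on a common time grid.
#' @param subsystem site indices retained (NULL = full system, nothing
#'   traced out).
#' @return object of class `backflow_result`: list with `times`, `D`,
#'   `N` (scalar), `increments`, and `backflow_intervals` (logical, TRUE
#'   where D increased).
#' @export
backflow_measure <- function(traj1, traj2, subsystem = NULL) {
  if (length(traj1$times) != length(traj2$times) ||
      max(abs(traj1$times - traj2$times)) > 1e-12) {
    stop("trajectories are on different time grids")
  }
  red <- function(r) if (is.null(subsystem)) r else reduce_to_sites(r, subsystem)
  D <- vapply(seq_along(traj1$times), function(i) {
    trace_distance(red(traj1$rhos[[i]]), red(traj2$rhos[[i]]))
  }, numeric(1))
  inc <- diff(D)
  structure(list(times = traj1$times, D = D,
                 N = sum(pmax(0, inc)), increments = inc,
                 backflow_intervals = inc > 0,
                 subsystem = subsystem),
            class = "backflow_result")
}

#' @export
print.backflow_result <- function(x, ...) {
  cat("backflow_result: N =", signif(x$N, 5), "over",
      length(x$times), "grid points; D(0) =", signif(x$D[1], 5), "\n")
  invisible(x)
}

#' Rank site pairs by peak pairwise coherence
#'
#' Scans a trajectory and ranks the pairs within `sites` (typically the
#' eight tryptophans of a focal tubulin) by the maximum over time of their
#' pairwise L1 coherence.  Ties are broken lexicographically by (i, j).
#'
#' @param traj an `exc_trajectory`.
#' @param sites site indices defining the focal group (default: all).
#' @param k number of pairs to return (default 4; capped at the number of
#'   available pairs).
#' @return data.frame with columns `i, j, peak, t_peak`, ranked by
#'   decreasing peak; the ranking criterion is recorded in
#'   `attr(,"criterion")`.
#' @export
top_pairs <- function(traj, sites = NULL, k = 4) {
  if (is.null(sites)) sites <- seq_len(traj$n)
  pairs <- utils::combn(sort(sites), 2)
  series <- apply(pairs, 2, function(p) {
    vapply(traj$rhos, pairwise_coherence, numeric(1), i = p[1], j = p[2])
  })
  peaks <- apply(series, 2, max)
  t_peak <- traj$times[apply(series, 2, which.max)]
  ord <- order(-peaks, pairs[1, ], pairs[2, ])
  k <- min(k, ncol(pairs))
  out <- data.frame(i = pairs[1, ord], j = pairs[2, ord],
                    peak = peaks[ord], t_peak = t_peak[ord])[seq_len(k), ]
  rownames(out) <- NULL
  attr(out, "criterion") <- "peak over time of pairwise L1 coherence"
  attr(out, "series") <- series[, ord[seq_len(k)], drop = FALSE]
  out
}

#' Tidy export of metric series
#'
#' Evaluates a set of metrics over a trajectory and returns (optionally
#' writes) a tidy table `time, metric, subsystem_A, subsystem_B, value`.
#'
#' @param traj an `exc_trajectory`.
#' @param metrics character vector among `"l1"`, `"pairwise"`,
#'   `"log_negativity"`, `"mutual_information"`.
#' @param pairs 2-row matrix of site pairs for the pairwise metrics.
#' @param path optional CSV output path.
#' @return data.frame in tidy form.
#' @export
metric_series <- function(traj, metrics = c("l1"), pairs = NULL, path = NULL) {
  rows <- list()
  if ("l1" %in% metrics) {
    rows[[length(rows) + 1]] <- data.frame(
      time = traj$times, metric = "l1_coherence",
      subsystem_A = "all", subsystem_B = "",
      value = vapply(traj$rhos, l1_coherence, numeric(1)))
  }
  if (!is.null(pairs)) {
    for (c_i in seq_len(ncol(pairs))) {
      i <- pairs[1, c_i]; j <- pairs[2, c_i]
      if ("pairwise" %in% metrics) {
        rows[[length(rows) + 1]] <- data.frame(
          time = traj$times, metric = "pairwise_coherence",
          subsystem_A = as.character(i), subsystem_B = as.character(j),
          value = vapply(traj$rhos, pairwise_coherence, numeric(1), i, j))
      }
      if ("log_negativity" %in% metrics) {
        rows[[length(rows) + 1]] <- data.frame(
          time = traj$times, metric = "log_negativity",
          subsystem_A = as.character(i), subsystem_B = as.character(j),
          value = vapply(traj$rhos, log_negativity, numeric(1), i, j))
      }
      if ("mutual_information" %in% metrics) {
        rows[[length(rows) + 1]] <- data.frame(
          time = traj$times, metric = "mutual_information",
          subsystem_A = as.character(i), subsystem_B = as.character(j),
          value = vapply(traj$rhos, mutual_information, numeric(1), i, j))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
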