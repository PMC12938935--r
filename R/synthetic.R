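# Synthetic network generators.  These are documented stand-ins with the
# geometric and statistical structure the analysis assumes (nm-scale
# spacings, mixed dipole orientations, hierarchical labels); they make no
# claim of structural fidelity to tubulin.

#' Generate a synthetic test network
#'
#' Deterministic per seed.  Kinds:
#' \describe{
#'   \item{pseudo_dimer}{the packaged synthetic 8-site dimer template
#'     ([build_dimer_template()]); nm-scale spacings, so every pairwise
#'     `k0 * r < 0.1` and couplings are deep in the collective regime, with
#'     both bright and dark modes present.}
#'   \item{dicke_pair}{two parallel dipoles separated by `spacing`
#'     Angstrom along z (default 0: exactly coincident, the Dicke limit,
#'     where collective rates are exactly 2 gamma and 0).}
#'   \item{chain}{`n_sites` sites along z at uniform `spacing`.}
#'   \item{ring}{`n_sites` sites on a circle with chord `spacing`.}
#'   \item{random_cloud}{`n_sites` sites uniform in a cube of side
#'     `spacing * n_sites^(1/3)`, random dipoles.}
#' }
#' Orientation rules for chain/ring: `"parallel"` (all along x),
#' `"radial"` (outward in the xy plane), `"random"` (seeded isotropic).
#'
#' @param kind fixture kind.
#' @param n_sites number of sites (chain/ring/random_cloud).
#' @param spacing characteristic spacing, Angstrom.
#' @param orientation dipole orientation rule.
#' @param seed RNG seed for the random rules.
#' @param lambda0,gamma,gamma_unit optical parameters.
#' @return a `trp_network`.
#' @export
make_fixture <- function(kind = c("pseudo_dimer", "dicke_pair", "chain",
                                  "ring", "random_cloud"),
                         n_sites = 8, spacing = 15,
                         orientation = c("parallel", "radial", "random"),
                         seed = 1, lambda0 = 280, gamma = 1,
                         gamma_unit = "gamma") {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  prov <- list(fixture = kind, n_sites = n_sites, spacing = spacing,
               orientation = orientation, seed = seed)
  if (kind == "pseudo_dimer") {
    net <- build_dimer_template("synthetic", lambda0 = lambda0,
                                gamma = gamma, gamma_unit = gamma_unit)
    net$provenance <- c(net$provenance, prov)
    return(net)
  }
  if (kind == "dicke_pair") {
    sep <- if (missing(spacing)) 0 else spacing
    sites <- data.frame(x = 0, y = 0, z = c(0, sep),
                        dx = 1, dy = 0, dz = 0)
    return(trp_network(sites, lambda0 = lambda0, gamma = gamma,
                       gamma_unit = gamma_unit, provenance = prov,
                       allow_coincident = sep == 0))
  }
  pos <- switch(kind,
    chain = cbind(0, 0, (seq_len(n_sites) - 1) * spacing),
    ring = {
      radius <- spacing / (2 * sin(pi / n_sites))
      th <- 2 * pi * (seq_len(n_sites) - 1) / n_sites
      cbind(radius * cos(th), radius * sin(th), 0)
    },
    random_cloud = with_seed(seed, {
      side <- spacing * n_sites^(1 / 3)
      matrix(runif(3 * n_sites, 0, side), ncol = 3)
    }))
  dip <- switch(orientation,
    parallel = matrix(rep(c(1, 0, 0), each = n_sites), ncol = 3),
    radial = {
      r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
      r[r == 0] <- 1
      cbind(pos[, 1] / r, pos[, 2] / r, 0)
    },
    random = with_seed(seed + 1, {
      m <- matrix(rnorm(3 * n_sites), ncol = 3)
      m / sqrt(rowSums(m^2))
    }))
  sites <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      dx = dip[, 1], dy = dip[, 2], dz = dip[, 3])
  trp_network(sites, lambda0 = lambda0, gamma = gamma,
              gamma_unit = gamma_unit, provenance = prov)
}

#' Ordered scaling series of assemblies
#'
#' Networks of growing size sharing the same dimer template, used for
#' size-scaling analyses of collective rates.  Default desk-scale sizes:
#' one dimer, a two-tubulin stack, and spiral stacks of 1, 2 and 4 turns.
#' The site list of a smaller spiral stack is a prefix of every larger one.
#'
#' @param template a dimer `trp_network` (default: the synthetic template).
#' @param sizes list of size specs, each `list(mode =, n =)` with mode
#'   `"dimer"`, `"two_tubulin"` or `"spiral"` (`n` = number of turns).
#' @param lattice a [lattice_params()] list.
#' @return named list of `trp_network` objects, in the given order.
#' @export
make_scaling_series <- function(template = build_dimer_template(),
                                sizes = list(
                                  list(mode = "dimer"),
                                  list(mode = "two_tubulin"),
                                  list(mode = "spiral", n = 1),
                                  list(mode = "spiral", n = 2),
                                  list(mode = "spiral", n = 4)),
                                lattice = lattice_params()) {
  out <- lapply(sizes, function(s) {
    switch(s$mode,
      dimer = template,
      two_tubulin = build_assembly(template, "two_tubulin", lattice = lattice),
      spiral = build_assembly(template, "spiral", n_spirals = s$n,
                              lattice = lattice),
      stop("unknown size mode '", s$mode, "'"))
  })
  names(out) <- vapply(sizes, function(s) {
    if (s$mode == "spiral") paste0("spiral_", s$n) else s$mode
  }, character(1))
  out
}

# minimal but well-formed PDB text for one TRP residue (indole ring + a few
# backbone atoms), translated by `shift`
trp_pdb_lines <- function(serial0, chain, resno, shift) {
  atoms <- list(
    c("N",   -2.40,  1.20, 0.50), c("CA", -1.50,  0.40, -0.30),
    c("CB",  -0.90, -0.80, 0.40),
    c("CG",   0.00,  0.00, 0.00), c("CD1",  1.09,  0.84, 0.00),
    c("NE1",  2.23,  0.10, 0.00), c("CE2",  1.91, -1.23, 0.00),
    c("CD2",  0.52, -1.34, 0.00), c("CE3", -0.27, -2.50, 0.00),
    c("CZ3",  0.34, -3.72, 0.00), c("CH2",  1.72, -3.80, 0.00),
    c("CZ2",  2.53, -2.68, 0.00))
  lines <- character(length(atoms))
  for (i in seq_along(atoms)) {
    a <- atoms[[i]]
    el <- substr(a[1], 1, 1)
    lines[i] <- sprintf(
      "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial0 + i - 1, a[1], "TRP", chain, resno,
      as.numeric(a[2]) + shift[1], as.numeric(a[3]) + shift[2],
      as.numeric(a[4]) + shift[3], 1.00, 0.00, el)
  }
  lines
}

#' Write a versioned bundle of plain-text fixtures
#'
#' Emits the synthetic dimer template as CSV and JSON site tables plus a
#' minimal two-TRP PDB file (synthetic coordinates) for exercising the
#' readers.  All files are deterministic, so checksums are stable for a
#' given bundle version.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture_bundle <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_fixture("pseudo_dimer")
  paths <- c(
    csv = file.path(dir, "pseudo_dimer_v1.csv"),
    json = file.path(dir, "pseudo_dimer_v1.json"),
    pdb = file.path(dir, "mini_two_trp_synthetic_v1.pdb"))
  write_site_table(net, paths["csv"])
  write_site_table(net, paths["json"])
  pdb <- c("HEADER    SYNTHETIC TEST FIXTURE",
           "REMARK    two tryptophan residues, synthetic coordinates",
           trp_pdb_lines(1, "A", 10, c(0, 0, 0)),
           trp_pdb_lines(13, "A", 25, c(12, 5, 8)),
           "END")
  writeLines(pdb, paths["pdb"])
  paths
}
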