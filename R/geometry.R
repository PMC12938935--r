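#' @useDynLib mtexciton, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd dist
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

SITE_COLUMNS <- c("x", "y", "z", "dx", "dy", "dz",
                  "epsilon_cm1", "trp", "tubulin", "spiral", "filament")

#' Chromophore network container
#'
#' A `trp_network` holds an ordered table of dipole sites together with the
#' global optical parameters.  Each site is a point dipole: a position (`x`,
#' `y`, `z`, Angstrom), a unit transition-dipole direction (`dx`, `dy`,
#' `dz`), a static site-energy offset (`epsilon_cm1`, cm^-1, default 0), and
#' hierarchical labels: `trp` (1-8 within a tubulin dimer), `tubulin`
#' (global dimer index, 0-based), `spiral` (circumferential turn index) and
#' `filament` (protofilament index, 0-based).
#'
#' @param sites data.frame with columns
#'   `x,y,z,dx,dy,dz,epsilon_cm1,trp,tubulin,spiral,filament` (missing label
#'   or epsilon columns are filled with defaults).
#' @param lambda0 transition wavelength in nm (default 280, the near-UV
#'   tryptophan band).
#' @param gamma single-site radiative decay rate; its meaning is fixed by
#'   `gamma_unit`.
#' @param gamma_unit `"gamma"` (rates expressed as multiples of the
#'   single-site rate; the default used in analyses that never need absolute
#'   time) or `"cm-1"` (wavenumbers, required to compute lifetimes in
#'   seconds).
#' @param provenance free-form list recording how the network was built.
#' @param allow_coincident permit duplicated positions (used by the
#'   Dicke-limit fixtures); otherwise coincident sites are an error.
#' @return an object of class `trp_network`.
#' @export
trp_network <- function(sites, lambda0 = 280, gamma = 1,
                        gamma_unit = c("gamma", "cm-1"),
                        provenance = list(), allow_coincident = FALSE) {
  gamma_unit <- match.arg(gamma_unit)
  sites <- as.data.frame(sites)
  if (nrow(sites) < 1L) stop("a network needs at least one site")
  for (col in c("x", "y", "z", "dx", "dy", "dz")) {
    if (!col %in% names(sites)) {
      stop("site table is missing required column '", col, "'")
    }
  }
  if (is.null(sites$epsilon_cm1)) sites$epsilon_cm1 <- 0
  if (is.null(sites$trp))      sites$trp      <- rep_len(1:8, nrow(sites))
  if (is.null(sites$tubulin))  sites$tubulin  <- 0L
  if (is.null(sites$spiral))   sites$spiral   <- 0L
  if (is.null(sites$filament)) sites$filament <- 0L
  sites <- sites[, SITE_COLUMNS]
  rownames(sites) <- NULL

  nrm <- sqrt(sites$dx^2 + sites$dy^2 + sites$dz^2)
  bad <- which(abs(nrm - 1) > 1e-9)
  if (length(bad) > 0) {
    stop("dipole is not a unit vector at row(s) ", paste(bad, collapse = ", "),
         " (|mu| = ", paste(signif(nrm[bad], 6), collapse = ", "), ")")
  }
  if (any(sites$tubulin < 0) || any(sites$spiral < 0) || any(sites$filament < 0)) {
    stop("hierarchical indices must be nonnegative")
  }
  if (!allow_coincident && nrow(sites) > 1) {
    key <- paste(round(sites$x, 9), round(sites$y, 9), round(sites$z, 9))
    if (anyDuplicated(key)) {
      j <- which(duplicated(key))[1]
      i <- match(key[j], key)
      stop("sites ", i, " and ", j, " are coincident; ",
           "use allow_coincident = TRUE only for Dicke-limit fixtures")
    }
  }
  structure(list(sites = sites, lambda0 = lambda0, gamma = gamma,
                 gamma_unit = gamma_unit, provenance = provenance,
                 allow_coincident = allow_coincident),
            class = "trp_network")
}

#' @export
print.trp_network <- function(x, ...) {
  cat("trp_network:", nrow(x$sites), "sites,",
      length(unique(x$sites$tubulin)), "tubulin dimer(s),",
      length(unique(x$sites$spiral)), "spiral(s)\n")
  cat("  lambda0 =", x$lambda0, "nm; gamma =", x$gamma,
      paste0("[", x$gamma_unit, "]\n"))
  invisible(x)
}

#' Number of sites in a network
#' @param net a `trp_network`.
#' @return integer site count.
#' @export
n_sites <- function(net) nrow(net$sites)

# Synthetic eight-site tubulin-dimer template: sites on a short helix
# (radius 7 A, rise 5.5 A per site, 100 deg step) with dipoles tilted 35 deg
# from the local tangent towards the helix axis.  Deliberately NOT a real
# tubulin geometry; spacings are nm-scale (all pairwise k0*r < 0.1 at
# lambda0 = 280 nm) so couplings are deep in the collective regime, and the
# mixed orientations guarantee both bright and dark collective modes.
synthetic_dimer_sites <- function() {
  k <- 0:7
  theta <- k * 100 * pi / 180
  phi <- 35 * pi / 180
  tang <- cbind(-sin(theta), cos(theta), 0)
  dip <- cos(phi) * tang
  dip[, 3] <- dip[, 3] + sin(phi)
  dip <- dip / sqrt(rowSums(dip^2))
  data.frame(
    x = 7 * cos(theta), y = 7 * sin(theta), z = 5.5 * k,
    dx = dip[, 1], dy = dip[, 2], dz = dip[, 3],
    epsilon_cm1 = 0, trp = k + 1L, tubulin = 0L, spiral = 0L, filament = 0L)
}

#' Build an eight-tryptophan tubulin-dimer template
#'
#' Either returns the packaged synthetic eight-site template (sites on a
#' short helix with mixed dipole orientations, spacings of order 1 nm so all
#' pairwise `k0*r < 0.1`) or validates a user-supplied site table with
#' exactly eight rows.
#'
#' @param template_spec `"synthetic"` (default) or a data.frame with exactly
#'   8 rows in the site-table format.
#' @param lambda0,gamma,gamma_unit passed to [trp_network()].
#' @return a `trp_network` of 8 sites labelled Trp1..Trp8, tubulin index 0.
#' @export
build_dimer_template <- function(template_spec = "synthetic",
                                 lambda0 = 280, gamma = 1,
                                 gamma_unit = "gamma") {
  if (is.character(template_spec)) {
    if (!identical(template_spec, "synthetic")) {
      stop("unknown template name '", template_spec, "'")
    }
    sites <- synthetic_dimer_sites()
    prov <- list(template = "synthetic",
                 description = "helical 8-site synthetic dimer template")
  } else {
    sites <- as.data.frame(template_spec)
    if (nrow(sites) != 8L) {
      stop("malformed template: a dimer template needs exactly 8 rows, got ",
           nrow(sites))
    }
    sites$trp <- 1:8
    sites$tubulin <- 0L
    sites$spiral <- 0L
    sites$filament <- 0L
    prov <- list(template = "user")
  }
  trp_network(sites, lambda0 = lambda0, gamma = gamma,
              gamma_unit = gamma_unit, provenance = prov)
}

#' Helical lattice parameters for microtubule assemblies
#'
#' Defaults approximate a 13-protofilament microtubule: cylinder radius
#' 112 Angstrom (11.2 nm), axial rise 80 Angstrom (8 nm) per dimer along a
#' protofilament, and a uniform angular step of 2*pi/13 between
#' protofilaments.  The seam offset and monomer rise of real lattices are
#' not modelled; one "spiral" is an ideal flat circumferential turn of 13
#' dimers.
#'
#' @param radius cylinder radius, Angstrom.
#' @param rise axial rise per dimer along a protofilament, Angstrom.
#' @param n_protofilaments number of protofilaments around the turn.
#' @param angular_step angle between adjacent protofilaments, radians.
#' @return a list of lattice parameters.
#' @export
lattice_params <- function(radius = 112, rise = 80, n_protofilaments = 13,
                           angular_step = 2 * pi / n_protofilaments) {
  list(radius = radius, rise = rise, n_protofilaments = n_protofilaments,
       angular_step = angular_step)
}

# rigid-body placement: rotate template about z by theta after shifting it
# onto the cylinder wall (template centroid axis -> radial direction x),
# then translate axially.
place_dimer <- function(tsites, theta, z_offset, radius) {
  ct <- cos(theta); st <- sin(theta)
  x0 <- tsites$x + radius
  x <- ct * x0 - st * tsites$y
  y <- st * x0 + ct * tsites$y
  dx <- ct * tsites$dx - st * tsites$dy
  dy <- st * tsites$dx + ct * tsites$dy
  out <- tsites
  out$x <- x; out$y <- y; out$z <- tsites$z + z_offset
  out$dx <- dx; out$dy <- dy
  out
}

#' Tile a dimer template into a microtubule assembly
#'
#' Three mutually exclusive modes:
#' \describe{
#'   \item{`"two_tubulin"`}{two dimers stacked longitudinally on one
#'     protofilament (axial translation by `lattice$rise`).}
#'   \item{`"spiral"`}{`n_spirals` circumferential turns, each holding
#'     `n_dimers_per_spiral` dimers equally spaced around the cylinder;
#'     successive turns are stacked axially.}
#'   \item{`"filament"`}{`n_filament_dimers` dimers stacked along a single
#'     protofilament.}
#' }
#' Each dimer is a rigid-body copy of the template (rotation about the
#' cylinder axis z plus axial translation), so all intra-dimer distances are
#' preserved exactly.  Site labels are populated: `tubulin` is a global
#' dimer counter, `spiral` the turn index, `filament` the protofilament
#' index.
#'
#' @param template a `trp_network` with one dimer (8 sites).
#' @param mode one of `"spiral"`, `"two_tubulin"`, `"filament"`.
#' @param n_spirals number of circumferential turns (spiral mode).
#' @param n_dimers_per_spiral dimers per turn (default from the lattice).
#' @param n_filament_dimers dimers in a single-protofilament stack.
#' @param lattice a [lattice_params()] list.
#' @return a `trp_network` with `8 * n_dimers` sites.
#' @export
build_assembly <- function(template,
                           mode = c("spiral", "two_tubulin", "filament"),
                           n_spirals = 1,
                           n_dimers_per_spiral = NULL,
                           n_filament_dimers = NULL,
                           lattice = lattice_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(template, "trp_network"))
  tsites <- template$sites
  # express template relative to its centroid so placement is symmetric
  tsites$x <- tsites$x - mean(tsites$x)
  tsites$y <- tsites$y - mean(tsites$y)
  tsites$z <- tsites$z - mean(tsites$z)

  placements <- switch(mode,
    two_tubulin = data.frame(theta = 0, z = c(0, lattice$rise),
                             spiral = 0L, filament = 0L),
    spiral = {
      if (n_spirals < 1) stop("n_spirals must be a positive integer")
      npf <- n_dimers_per_spiral %||% lattice$n_protofilaments
      if (npf < 1) stop("n_dimers_per_spiral must be a positive integer")
      g <- expand.grid(filament = seq_len(npf) - 1L,
                       spiral = seq_len(n_spirals) - 1L)
      data.frame(theta = g$filament * lattice$angular_step,
                 z = g$spiral * lattice$rise,
                 spiral = g$spiral, filament = g$filament)
    },
    filament = {
      if (is.null(n_filament_dimers) || n_filament_dimers < 1) {
        stop("n_filament_dimers must be a positive integer")
      }
      data.frame(theta = 0, z = (seq_len(n_filament_dimers) - 1L) * lattice$rise,
                 spiral = seq_len(n_filament_dimers) - 1L, filament = 0L)
    })

  pieces <- vector("list", nrow(placements))
  for (i in seq_len(nrow(placements))) {
    s <- place_dimer(tsites, placements$theta[i], placements$z[i],
                     if (mode == "spiral") lattice$radius else 0)
    s$tubulin <- i - 1L
    s$spiral <- placements$spiral[i]
    s$filament <- placements$filament[i]
    pieces[[i]] <- s
  }
  sites <- do.call(rbind, pieces)

  prov <- c(template$provenance,
            list(assembly = mode, lattice = lattice,
                 n_dimers = nrow(placements)))
  # warn (in provenance) about implausibly close dimer placements
  cent <- cbind(tapply(sites$x, sites$tubulin, mean),
                tapply(sites$y, sites$tubulin, mean),
                tapply(sites$z, sites$tubulin, mean))
  if (nrow(cent) > 1) {
    dmin <- min(stats::dist(cent))
    if (dmin < 20) {
      prov$warning <- paste0("min inter-dimer centroid distance ",
                             signif(dmin, 4), " A is below 20 A")
      warning(prov$warning)
    }
  }
  trp_network(sites, lambda0 = template$lambda0, gamma = template$gamma,
              gamma_unit = template$gamma_unit, provenance = prov)
}

# scoped RNG: run expr with a fixed seed without disturbing the global stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Apply structural (geometric) disorder to a network
#'
#' Emulates conformational variability by jittering the geometry: positions
#' receive zero-mean isotropic Gaussian displacements (sd `sigma_pos` per
#' Cartesian axis) and each dipole is rotated about a uniformly random axis
#' by an angle drawn from N(0, `sigma_angle`), then renormalized.  The
#' perturbation is deterministic for a fixed seed.
#'
#' @param net a `trp_network`.
#' @param sigma_pos positional jitter sd per axis, Angstrom.
#' @param sigma_angle dipole rotation angle sd, degrees.
#' @param seed integer RNG seed.
#' @return a new `trp_network` with perturbed geometry.
#' @export
apply_structural_disorder <- function(net, sigma_pos = 0, sigma_angle = 0,
                                      seed = 1) {
  stopifnot(inherits(net, "trp_network"), sigma_pos >= 0, sigma_angle >= 0)
  s <- net$sites
  n <- nrow(s)
  with_seed(seed, {
    if (sigma_pos > 0) {
      s$x <- s$x + rnorm(n, 0, sigma_pos)
      s$y <- s$y + rnorm(n, 0, sigma_pos)
      s$z <- s$z + rnorm(n, 0, sigma_pos)
    }
    if (sigma_angle > 0) {
      sd_rad <- sigma_angle * pi / 180
      # uniform random rotation axis, Gaussian angle (Rodrigues formula)
      u <- matrix(rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      ang <- rnorm(n, 0, sd_rad)
      d <- as.matrix(s[, c("dx", "dy", "dz")])
      ca <- cos(ang); sa <- sin(ang)
      udotd <- rowSums(u * d)
      cross <- cbind(u[, 2] * d[, 3] - u[, 3] * d[, 2],
                     u[, 3] * d[, 1] - u[, 1] * d[, 3],
                     u[, 1] * d[, 2] - u[, 2] * d[, 1])
      dnew <- ca * d + sa * cross + (1 - ca) * udotd * u
      dnew <- dnew / sqrt(rowSums(dnew^2))
      s$dx <- dnew[, 1]; s$dy <- dnew[, 2]; s$dz <- dnew[, 3]
    }
  })
  prov <- c(net$provenance,
            list(structural_disorder = list(sigma_pos = sigma_pos,
                                            sigma_angle = sigma_angle,
                                            seed = seed)))
  trp_network(s, lambda0 = net$lambda0, gamma = net$gamma,
              gamma_unit = net$gamma_unit, provenance = prov,
              allow_coincident = net$allow_coincident)
}

#' Partition the sites of a network by hierarchical label
#'
#' Produces an exact set partition of the site indices, grouped by tubulin
#' dimer, spiral (circumferential turn), or filament (protofilament track).
#'
#' @param net a `trp_network` with populated labels.
#' @param mode `"tubulin"`, `"spiral"`, or `"filament"`.
#' @return an object of class `trp_partition`: a list with `name` and
#'   `groups` (list of integer site-index vectors, ordered by label).
#' @export
partition_network <- function(net, mode = c("tubulin", "spiral", "filament")) {
  mode <- match.arg(mode)
  lab <- net$sites[[mode]]
  if (is.null(lab) || anyNA(lab)) stop("missing '", mode, "' labels")
  idx <- sort(unique(lab))
  groups <- lapply(idx, function(v) which(lab == v))
  names(groups) <- paste0(mode, "_", idx)
  structure(list(name = mode, groups = groups), class = "trp_partition")
}

#' Write a network to a site table (CSV or JSON)
#'
#' CSV holds the site columns only
#' (`x,y,z,dx,dy,dz,epsilon_cm1,trp,tubulin,spiral,filament`, Angstrom);
#' JSON additionally round-trips `lambda0`, `gamma`, `gamma_unit` and
#' provenance.
#'
#' @param net a `trp_network`.
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_site_table <- function(net, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(format = "trp_network", version = 1L,
           lambda0 = net$lambda0, gamma = net$gamma,
           gamma_unit = net$gamma_unit,
           sites = net$sites, provenance = net$provenance),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(net$sites, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network from a site table (CSV or JSON)
#'
#' @param path a CSV or JSON site table written by [write_site_table()] (or
#'   hand-authored in the same dialect).  Unknown JSON keys are preserved in
#'   the provenance record.
#' @param lambda0,gamma,gamma_unit defaults used for CSV input (JSON input
#'   carries its own).
#' @return a `trp_network`.
#' @export
read_site_table <- function(path, lambda0 = 280, gamma = 1,
                            gamma_unit = "gamma") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    known <- c("format", "version", "lambda0", "gamma", "gamma_unit",
               "sites", "provenance")
    extra <- obj[setdiff(names(obj), known)]
    prov <- as.list(obj$provenance %||% list())
    if (length(extra) > 0) prov$extra_keys <- extra
    sites <- as.data.frame(obj$sites)
    missing <- setdiff(c("x", "y", "z", "dx", "dy", "dz"), names(sites))
    if (length(missing) > 0) {
      stop("site table ", path, " is missing column(s): ",
           paste(missing, collapse = ", "))
    }
    trp_network(sites, lambda0 = obj$lambda0 %||% lambda0,
                gamma = obj$gamma %||% gamma,
                gamma_unit = obj$gamma_unit %||% gamma_unit,
                provenance = prov)
  } else {
    sites <- read.csv(path)
    missing <- setdiff(c("x", "y", "z", "dx", "dy", "dz"), names(sites))
    if (length(missing) > 0) {
      stop("site table ", path, " is missing column(s): ",
           paste(missing, collapse = ", "))
    }
    trp_network(sites, lambda0 = lambda0, gamma = gamma,
                gamma_unit = gamma_unit,
                provenance = list(source = path))
  }
}

# nine atoms of the indole ring used for the site centroid
INDOLE_RING_ATOMS <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                       "CZ2", "CZ3", "CH2")

#' Extract tryptophan dipole sites from a PDB file
#'
#' Convenience reader: each selected TRP residue becomes one site whose
#' position is the centroid of the nine indole ring atoms and whose dipole
#' is the unit vector between two configurable indole atoms (default CD1 to
#' CZ2, an approximation to the indole long axis; the in-plane orientation
#' of the 1La transition moment is not standardized, so override
#' `axis_atoms` to match your convention).  Requires the `bio3d` package.
#'
#' @param path a PDB file containing TRP residues.
#' @param chains optional character vector restricting chains.
#' @param axis_atoms length-2 character vector of atom names defining the
#'   dipole direction (from the first to the second).
#' @param lambda0,gamma,gamma_unit passed to [trp_network()].
#' @return a `trp_network`, one site per TRP residue; residue and chain are
#'   recorded in the provenance.
#' @export
read_pdb_trp_sites <- function(path, chains = NULL,
                               axis_atoms = c("CD1", "CZ2"),
                               lambda0 = 280, gamma = 1,
                               gamma_unit = "gamma") {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_pdb_trp_sites requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  a <- a[a$resid == "TRP", , drop = FALSE]
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0) stop("no TRP residues found in ", path)
  key <- paste(a$chain, a$resno)
  rows <- list(); meta <- list()
  for (k in unique(key)) {
    res <- a[key == k, , drop = FALSE]
    ring <- res[res$elety %in% INDOLE_RING_ATOMS, , drop = FALSE]
    if (nrow(ring) < length(INDOLE_RING_ATOMS)) {
      stop("TRP ", k, " is missing indole ring atoms")
    }
    p1 <- res[res$elety == axis_atoms[1], c("x", "y", "z")]
    p2 <- res[res$elety == axis_atoms[2], c("x", "y", "z")]
    if (nrow(p1) != 1 || nrow(p2) != 1) {
      stop("TRP ", k, " is missing dipole axis atom(s) ",
           paste(axis_atoms, collapse = "/"))
    }
    d <- as.numeric(p2) - as.numeric(p1)
    d <- d / sqrt(sum(d^2))
    rows[[k]] <- data.frame(
      x = mean(ring$x), y = mean(ring$y), z = mean(ring$z),
      dx = d[1], dy = d[2], dz = d[3],
      epsilon_cm1 = 0, trp = length(rows) %% 8L + 1L,
      tubulin = 0L, spiral = 0L, filament = 0L)
    meta[[k]] <- k
  }
  trp_network(do.call(rbind, rows), lambda0 = lambda0, gamma = gamma,
              gamma_unit = gamma_unit,
              provenance = list(pdb = path, residues = unlist(meta),
                                axis_atoms = axis_atoms))
}
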