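# Desk-scale experiment pipeline.  Each command takes a config (an R list,
# or a path to a JSON file with the same structure), writes tidy CSV
# outputs plus a run manifest into `out_dir`, and returns its results
# invisibly.  Existing output files are never silently overwritten: set
# `overwrite = TRUE` explicitly to replace them.

DESK_SCALE_MAX_LINDBLAD_SITES <- 208   # <= 2 spirals for full Lindblad runs
DESK_SCALE_MAX_EIGEN_SITES <- 832      # <= 8 spirals for eigenmode analysis

load_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON path")
  config
}

config_network <- function(config) {
  net <- if (!is.null(config$site_table)) {
    read_site_table(config$site_table,
                    lambda0 = config$lambda0 %||% 280,
                    gamma = config$gamma %||% 1,
                    gamma_unit = config$gamma_unit %||% "gamma")
  } else {
    fix <- config$fixture %||% "pseudo_dimer"
    make_fixture(fix,
                 n_sites = config$n_sites %||% 8,
                 spacing = config$spacing %||% 15,
                 seed = config$seed %||% 1,
                 lambda0 = config$lambda0 %||% 280,
                 gamma = config$gamma %||% 1,
                 gamma_unit = config$gamma_unit %||% "gamma")
  }
  asm <- config$assembly
  if (!is.null(asm)) {
    net <- build_assembly(net, mode = asm$mode %||% "spiral",
                          n_spirals = asm$n_spirals %||% 1,
                          n_dimers_per_spiral = asm$n_dimers_per_spiral,
                          n_filament_dimers = asm$n_filament_dimers)
  }
  net
}

out_file <- function(out_dir, name, overwrite) {
  path <- file.path(out_dir, name)
  if (file.exists(path) && !overwrite) {
    stop("output file ", path, " exists; pass overwrite = TRUE to replace it")
  }
  path
}

write_manifest <- function(out_dir, config, command, extra = list(),
                           overwrite = FALSE) {
  cfg_path <- out_file(out_dir, paste0(command, "_config.json"), overwrite)
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- c(list(command = command,
                     package = "mtexciton",
                     version = as.character(utils::packageVersion("mtexciton")),
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     gamma_unit = config$gamma_unit %||% "gamma",
                     seed = config$seed %||% 1),
                extra)
  jsonlite::write_json(manifest,
                       out_file(out_dir, paste0(command, "_manifest.json"),
                                overwrite),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Build a network from a config and write its site table
#'
#' @param config list or JSON path; fields: `fixture` (or `site_table`),
#'   `assembly` (`mode`, `n_spirals`, ...), `lambda0`, `gamma`,
#'   `gamma_unit`, `seed`, optional `structural_disorder`
#'   (`sigma_pos`, `sigma_angle`, `seed`).
#' @param out_dir output directory.
#' @param overwrite replace existing outputs.
#' @return the built `trp_network`, invisibly.
#' @export
cmd_build <- function(config, out_dir, overwrite = FALSE) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- config_network(config)
  sd <- config$structural_disorder
  if (!is.null(sd)) {
    net <- apply_structural_disorder(net, sd$sigma_pos %||% 0,
                                     sd$sigma_angle %||% 0,
                                     sd$seed %||% (config$seed %||% 1))
  }
  write_site_table(net, out_file(out_dir, "sites.csv", overwrite))
  write_site_table(net, out_file(out_dir, "sites.json", overwrite))
  write_manifest(out_dir, config, "build",
                 list(n_sites = n_sites(net)), overwrite)
  invisible(net)
}

#' Compute and export the collective mode table
#'
#' Builds the couplings, diagonalizes the effective non-Hermitian
#' Hamiltonian and writes `modes.csv`
#' (`j, E, Gamma, Gamma_over_gamma, bright[, tau_s]`).
#'
#' @inheritParams cmd_build
#' @return the `mode_set`, invisibly.
#' @export
cmd_modes <- function(config, out_dir, overwrite = FALSE) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- config_network(config)
  if (n_sites(net) > DESK_SCALE_MAX_EIGEN_SITES && !isTRUE(config$force)) {
    stop("eigenmode analysis beyond ", DESK_SCALE_MAX_EIGEN_SITES,
         " sites needs config$force = TRUE")
  }
  cs <- coupling_set(net, mask_coincident = isTRUE(net$allow_coincident))
  if (!is.null(config$static_disorder_W)) {
    cs <- apply_static_disorder(cs, config$static_disorder_W,
                                config$seed %||% 1)
  }
  modes <- eigenmodes(cs)
  mode_table(modes, out_file(out_dir, "modes.csv", overwrite))
  write_manifest(out_dir, config, "modes",
                 list(n_sites = n_sites(net),
                      gamma_max_ratio = max(modes$ratio),
                      gamma_min_ratio = min(modes$ratio)), overwrite)
  invisible(modes)
}

config_times <- function(config, cs) {
  tw <- config$time %||% list()
  t_max <- tw$t_max %||% 5
  n_out <- tw$n_out %||% 201
  seq(0, t_max, length.out = n_out)
}

#' Run a preparation -> trajectory -> metrics pipeline
#'
#' Propagates the configured initial preparation under the Lindblad master
#' equation and writes `populations.csv` (time, site, population),
#' `metrics.csv` (tidy metric series: total L1 coherence, the top-`k`
#' pairwise coherences and their logarithmic negativities) and
#' `projections.csv` (bright/dark eigenmode weights).
#'
#' @inheritParams cmd_build
#' @return list with the trajectory, mode set, and top-pair table,
#'   invisibly.
#' @export
cmd_evolve <- function(config, out_dir, overwrite = FALSE) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- config_network(config)
  if (n_sites(net) > DESK_SCALE_MAX_LINDBLAD_SITES && !isTRUE(config$force)) {
    stop("full Lindblad runs beyond ", DESK_SCALE_MAX_LINDBLAD_SITES,
         " sites need config$force = TRUE")
  }
  cs <- coupling_set(net, mask_coincident = isTRUE(net$allow_coincident))
  modes <- eigenmodes(cs)
  N <- n_sites(net)
  prep <- config$preparation %||% "uniform_coherent"
  rho0 <- make_initial_state(prep, N = N, modes = modes,
                             site = config$site)
  times <- config_times(config, cs)
  traj <- lindblad_propagate(cs, rho0, times,
                             rtol = config$rtol %||% 1e-12,
                             atol = config$atol %||% 1e-14)

  pops <- site_populations(traj)
  pop_tidy <- data.frame(
    time = rep(times, ncol(pops)),
    site = rep(colnames(pops), each = length(times)),
    population = as.vector(pops))
  write.csv(pop_tidy, out_file(out_dir, "populations.csv", overwrite),
            row.names = FALSE)

  focal <- config$focal_sites %||% seq_len(min(N, 8))
  tp <- top_pairs(traj, sites = focal, k = config$k_pairs %||% 4)
  metric_series(traj, metrics = c("l1", "pairwise", "log_negativity"),
                pairs = rbind(tp$i, tp$j),
                path = out_file(out_dir, "metrics.csv", overwrite))

  proj <- mode_projections(traj, modes)
  write.csv(data.frame(time = times, bright = proj$bright,
                       dark = proj$dark),
            out_file(out_dir, "projections.csv", overwrite),
            row.names = FALSE)
  write_manifest(out_dir, config, "evolve",
                 list(n_sites = N, preparation = prep,
                      rtol = config$rtol %||% 1e-12,
                      atol = config$atol %||% 1e-14,
                      crossover_time = proj$crossover_time), overwrite)
  invisible(list(trajectory = traj, modes = modes, top_pairs = tp))
}

#' Trace-distance backflow protocol on a spiral
#'
#' For each requested neighbor `k`, prepares the population and phase
#' contrast pairs on tubulins `T1`/`Tk`, propagates them under the same
#' Liouvillian, reduces to the two-tubulin subsystem `Xk = T1 U Tk`, and
#' writes the scalar backflow table `backflow.csv` (k, preparation, N) and
#' the distance series `backflow_series.csv`.
#'
#' @inheritParams cmd_build
#' @return data.frame of scalar backflow values, invisibly.
#' @export
cmd_backflow <- function(config, out_dir, overwrite = FALSE) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- config_network(config)
  if (n_sites(net) > DESK_SCALE_MAX_LINDBLAD_SITES && !isTRUE(config$force)) {
    stop("full Lindblad runs beyond ", DESK_SCALE_MAX_LINDBLAD_SITES,
         " sites need config$force = TRUE")
  }
  cs <- coupling_set(net)
  part <- partition_network(net, "tubulin")
  ks <- config$neighbors %||% seq(2, length(part$groups))
  times <- config_times(config, cs)
  jumps <- jump_operators(cs)
  trace_out <- !isTRUE(config$full_system)

  rows <- list(); series <- list()
  for (k in ks) {
    sub <- if (trace_out) c(part$groups[[1]], part$groups[[k]]) else NULL
    for (which in c("population", "phase")) {
      pair <- contrast_pair_states(part, k, which, N = n_sites(net))
      t1 <- lindblad_propagate(cs, pair[[1]], times, jumps = jumps,
                               rtol = config$rtol %||% 1e-12,
                               atol = config$atol %||% 1e-14)
      t2 <- lindblad_propagate(cs, pair[[2]], times, jumps = jumps,
                               rtol = config$rtol %||% 1e-12,
                               atol = config$atol %||% 1e-14)
      bf <- backflow_measure(t1, t2, subsystem = sub)
      rows[[length(rows) + 1]] <- data.frame(k = k, preparation = which,
                                             N = bf$N, D0 = bf$D[1])
      series[[length(series) + 1]] <- data.frame(
        k = k, preparation = which, time = bf$times, D = bf$D)
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, out_file(out_dir, "backflow.csv", overwrite),
            row.names = FALSE)
  write.csv(do.call(rbind, series),
            out_file(out_dir, "backflow_series.csv", overwrite),
            row.names = FALSE)
  write_manifest(out_dir, config, "backflow",
                 list(n_sites = n_sites(net), neighbors = ks,
                      traced_out = trace_out), overwrite)
  invisible(out)
}

#' Size x disorder scan of collective rates and lifetimes
#'
#' Sweeps the ordered scaling series and, when `static_disorder_W > 0`, a
#' seeded disorder ensemble at each size; writes `scan.csv` with the
#' extreme rates (and lifetimes when the unit system is cm-1), reporting
#' ensemble mean and sd over seeds for disordered entries.
#'
#' @inheritParams cmd_build
#' @return the scan data.frame, invisibly.
#' @export
cmd_scan <- function(config, out_dir, overwrite = FALSE) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gamma <- config$gamma %||% 1
  gamma_unit <- config$gamma_unit %||% "gamma"
  template <- build_dimer_template("synthetic", gamma = gamma,
                                   gamma_unit = gamma_unit)
  series <- make_scaling_series(template)
  W <- config$static_disorder_W %||% 0
  n_seeds <- config$n_seeds %||% 20
  base_seed <- config$seed %||% 1

  rows <- list()
  for (nm in names(series)) {
    net <- series[[nm]]
    if (n_sites(net) > DESK_SCALE_MAX_EIGEN_SITES && !isTRUE(config$force)) {
      stop("eigenmode analysis beyond ", DESK_SCALE_MAX_EIGEN_SITES,
           " sites needs config$force = TRUE")
    }
    cs <- coupling_set(net)
    seeds <- if (W > 0) base_seed + seq_len(n_seeds) - 1 else base_seed
    gmax <- gmin <- numeric(length(seeds))
    for (i in seq_along(seeds)) {
      csi <- if (W > 0) apply_static_disorder(cs, W, seeds[i]) else cs
      m <- eigenmodes(csi, vectors = FALSE)
      gmax[i] <- max(m$rates); gmin[i] <- min(m$rates)
    }
    row <- data.frame(size = nm, n_sites = n_sites(net), W = W,
                      n_seeds = length(seeds),
                      gamma_max_mean = mean(gmax), gamma_max_sd = sd(gmax),
                      gamma_min_mean = mean(gmin), gamma_min_sd = sd(gmin))
    if (gamma_unit == "cm-1") {
      row$tau_min_s <- lifetime_s_from_rate_cm1(mean(gmax))
      row$tau_max_s <- lifetime_s_from_rate_cm1(mean(gmin))
    }
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.csv(out, out_file(out_dir, "scan.csv", overwrite), row.names = FALSE)
  write_manifest(out_dir, config, "scan",
                 list(W = W, n_seeds = n_seeds, sizes = names(series)),
                 overwrite)
  invisible(out)
}
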