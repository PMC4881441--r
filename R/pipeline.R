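# End-to-end orchestration: monomer (ensemble -> order parameters ->
# landscape -> basins/barriers -> per-basin contact maps) and dimer
# (campaign -> binding/flat-stage -> interface maps -> common segments ->
# snapshots -> landscape projection), driven by one config, with a
# manifest recording the config hash and seed.

monomer_defaults <- function() {
  list(temperature = 319.3, n_points = 60000, seed = 1,
       bin_width = 0.25, sigma_bins = 0.6, f_max = 1.1, basin_frames = 100,
       min_spacing_ps = 100, decorate = TRUE, out_dir = NULL)
}

dimer_defaults <- function() {
  list(seed = 1, n_sims = 8, out_dir = NULL,
       contact_cutoff = 4.5, persist_ns = 5,
       flat_window_ns = 50, slope_tol = 0.05, stats_window_ns = 400,
       seg_threshold = 0.3)
}

#' Read a run configuration file
#'
#' YAML with two optional blocks, `monomer` and `dimer`, whose entries
#' override the documented defaults of [run_monomer_pipeline()] and
#' [run_dimer_pipeline()].
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  yaml::read_yaml(path)
}

merge_config <- function(defaults, cfg) {
  for (nm in names(cfg)) defaults[[nm]] <- cfg[[nm]]
  defaults
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_manifest <- function(out_dir, cfg, extra = list()) {
  manifest <- c(list(package = "foldscape",
                     version = as.character(utils::packageVersion("foldscape")),
                     config_hash = rlang::hash(cfg), seed = cfg$seed),
                extra)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

#' Run the monomer analysis pipeline
#'
#' Samples the planted monomer ensemble at the analysis temperature,
#' builds the (beta-RMSD, alpha-RMSD) free-energy landscape, detects
#' basins and the barriers between them, decorates representative frames
#' of each basin into 3D conformations, and writes per-basin contact
#' maps plus an order-parameter table.
#'
#' @param cfg A named list (or path to a YAML config, block `monomer`):
#'   `temperature` (K), `n_points`, `seed`, `bin_width` (A), `f_max`
#'   (kcal/mol above the global minimum), `basin_frames`,
#'   `min_spacing_ps`, `decorate` (logical), `out_dir` (optional: write
#'   TSV outputs there).
#' @param spec Planted landscape spec (default [ds119_landscape_spec()]).
#' @return A list: `grid`, `basins`, `basin_table`, `barrier_table`,
#'   `params` (order parameters of decorated basin frames),
#'   `contact_maps` (per basin label), `points`.
#' @export
run_monomer_pipeline <- function(cfg = list(), spec = ds119_landscape_spec()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)$monomer
  cfg <- merge_config(monomer_defaults(), cfg)
  message("stage 1/4: sampling planted ensemble")
  samp <- sample_planted_points(spec, cfg$temperature, cfg$n_points,
                                seed = cfg$seed)
  xe <- seq(spec$xlim[1], spec$xlim[2], by = cfg$bin_width)
  ye <- seq(spec$ylim[1], spec$ylim[2], by = cfg$bin_width)
  message("stage 2/4: building landscape and basins")
  grid <- build_landscape(samp$points, xe, ye, cfg$temperature)
  # basins are detected on a lightly smoothed grid: raw sampling noise
  # can dig spurious bridges between neighbouring basins
  sm <- smooth_landscape(grid, cfg$sigma_bins)
  basins <- find_basins(sm, f_max = cfg$f_max)
  # name detected basins after the nearest planted state centre
  if (length(basins)) {
    for (k in seq_along(basins)) {
      d2 <- (spec$basins$x - basins[[k]]$min_x)^2 +
        (spec$basins$y - basins[[k]]$min_y)^2
      basins[[k]]$label <- spec$basins$label[which.min(d2)]
    }
  }
  basin_table <- tidy(basins)
  pairs <- if (length(basins) >= 2L) utils::combn(basin_table$label, 2) else
    matrix(character(), 2, 0)
  barrier_table <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    b <- minimax_barrier(sm, basins, pairs[1, j], pairs[2, j])
    tibble::tibble(from = b$from, to = b$to, saddle_F = b$saddle_F,
                   barrier = b$barrier)
  })
  message("stage 3/4: decorating basin frames")
  params <- NULL; contact_maps <- list()
  if (isTRUE(cfg$decorate) && length(basins)) {
    ref <- build_mock_reference()
    unf <- build_extended_chain(jitter_deg = 8, seed = cfg$seed + 1)
    pts <- samp$points
    pts$time_ps <- (seq_len(nrow(pts)) - 1) * cfg$min_spacing_ps
    for (k in seq_along(basins)) {
      sel <- sample_basin_frames(pts, grid, basins[[k]],
                                 min_count = cfg$basin_frames,
                                 min_spacing_ps = cfg$min_spacing_ps)
      sel <- head(sel, cfg$basin_frames)
      if (!length(sel)) next
      dec <- decorate_conformations(pts[sel, ], ref, unf,
                                    seed = cfg$seed + 10 + k)
      contact_maps[[basins[[k]]$label]] <- intra_contact_map(dec$traj)
      p <- compute_order_params(dec$traj, ref, sasa = TRUE, ss = TRUE)
      p$basin <- basins[[k]]$label
      params <- dplyr::bind_rows(params, p)
    }
  }
  message("stage 4/4: writing outputs")
  out <- list(grid = grid, smoothed = sm, basins = basins,
              basin_table = basin_table, barrier_table = barrier_table,
              params = params, contact_maps = contact_maps,
              points = samp$points)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tidy(grid), file.path(cfg$out_dir, "landscape.tsv"))
    write_tsv(basin_table, file.path(cfg$out_dir, "basins.tsv"))
    write_tsv(barrier_table, file.path(cfg$out_dir, "barriers.tsv"))
    if (!is.null(params)) {
      write_tsv(params, file.path(cfg$out_dir, "params.tsv"))
    }
    for (lab in names(contact_maps)) {
      write_tsv(tidy(contact_maps[[lab]]),
                file.path(cfg$out_dir, sprintf("contacts_%s.tsv",
                                               gsub("'", "p", lab))))
    }
    write_manifest(cfg$out_dir, cfg)
  }
  out
}

#' The default synthetic dimer campaign
#'
#' Eight scripted two-chain runs emulating independent association
#' simulations: seven bind (times spread over 30-750 ns), six of the
#' seven share the 5-10 N-terminal interface on both chains, one binds
#' through a helix-face interface (16-21), and one never binds. Bound
#' monomer conformations are drawn from the planted intermediate states.
#'
#' @param spec Planted landscape spec providing the state centres.
#' @return A list of 8 [dimer_script()]s.
#' @export
default_dimer_campaign <- function(spec = ds119_landscape_spec()) {
  states <- list(c("I2", "I3"), c("I1", "I2"), c("I3", "I1"),
                 c("I2", "I1"), c("F'", "I2"), c("I3", "I2"),
                 c("I1", "I3"), c("I2", "I2"))
  t_bind <- c(30, 120, 250, 400, 520, 700, 750, NA)
  iface_a <- list(c(5, 10), c(5, 10), c(5, 10), c(5, 10), c(5, 10),
                  c(5, 10), c(16, 21), c(5, 10))
  iface_b <- list(c(5, 10), c(5, 10), c(10, 15), c(5, 10), c(10, 15),
                  c(5, 10), c(16, 21), c(5, 10))
  lapply(1:8, function(i) {
    dimer_script(t_end_ns = 1200, dt_ns = 2,
                 t_approach_ns = if (is.na(t_bind[i])) 60 else
                   max(10, t_bind[i] - 30),
                 t_bind_ns = t_bind[i],
                 interface_a = iface_a[[i]], interface_b = iface_b[[i]],
                 state_a = states[[i]][1], state_b = states[[i]][2],
                 spec = spec)
  })
}

#' Run the dimer aggregation pipeline
#'
#' Generates (or accepts) a campaign of two-chain trajectories and, per
#' simulation: detects binding, the flat stage of the inter-chain
#' contact-pair count, and the interface map over the first 400 ns of
#' the stage; then aggregates the common binding-segment report, builds
#' average/representative structures, and projects each bound monomer
#' onto the monomer folding landscape.
#'
#' @param cfg A named list (or path to YAML config, block `dimer`):
#'   `seed`, `n_sims`, `out_dir`, `contact_cutoff`, `persist_ns`,
#'   `flat_window_ns`, `slope_tol`, `stats_window_ns`, `seg_threshold`.
#' @param campaign Optional list of [dimer_script()]s (default
#'   [default_dimer_campaign()], truncated to `n_sims`).
#' @param trajectories Optional pre-generated list of two-chain
#'   trajectories (bypasses generation).
#' @param monomer Optional result of [run_monomer_pipeline()] providing
#'   `grid` and `basins` for the projection; when `NULL` a landscape is
#'   built from the planted spec.
#' @return A list: `binding_table`, `flat_stages`, `interfaces`,
#'   `common`, `snapshots`, `projection`, `truths`.
#' @export
run_dimer_pipeline <- function(cfg = list(), campaign = NULL,
                               trajectories = NULL, monomer = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)$dimer
  cfg <- merge_config(dimer_defaults(), cfg)
  spec <- ds119_landscape_spec()
  if (is.null(campaign)) campaign <- default_dimer_campaign(spec)
  campaign <- head(campaign, cfg$n_sims)
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = cfg$seed + 99)

  truths <- list()
  if (is.null(trajectories)) {
    message(sprintf("generating %d scripted simulations", length(campaign)))
    trajectories <- vector("list", length(campaign))
    for (i in seq_along(campaign)) {
      g <- generate_dimer_trajectory(campaign[[i]], ref, unf,
                                     seed = (cfg$seed %% 100000) * 1000 + i)
      trajectories[[i]] <- g$traj
      truths[[i]] <- g$truth
    }
  }

  if (is.null(monomer)) {
    monomer <- run_monomer_pipeline(
      list(seed = cfg$seed, decorate = FALSE), spec = spec)
  }

  binding <- list(); stages <- list(); interfaces <- list()
  snapshots <- list(); projection <- NULL
  for (i in seq_along(trajectories)) {
    message(sprintf("analysing simulation %d/%d", i, length(trajectories)))
    traj <- trajectories[[i]]
    bind <- detect_binding(traj, cfg$contact_cutoff, cfg$persist_ns)
    binding[[i]] <- tibble::tibble(
      sim = i, bound = !is.null(bind),
      t_bind_ns = if (is.null(bind)) NA_real_ else bind$t_bind_ns)
    if (is.null(bind)) next
    series <- contact_pair_timeseries(traj, cfg$contact_cutoff)
    stage <- detect_flat_stage(series$counts, cfg$flat_window_ns,
                               cfg$slope_tol, t_from_ns = bind$t_bind_ns)
    stages[[i]] <- stage
    if (is.null(stage)) next
    interfaces[[i]] <- interface_map(traj, stage, cfg$stats_window_ns,
                                     cfg$contact_cutoff, cfg$seg_threshold)
    avg <- average_structure(traj, stage, cfg$stats_window_ns)
    snap <- representative_snapshot(traj, stage, avg, cfg$stats_window_ns)
    snapshots[[i]] <- snap
    pr <- project_monomers(traj_frame(traj, snap$frame), ref,
                           monomer$smoothed, monomer$basins)
    pr$sim <- i
    projection <- dplyr::bind_rows(projection, pr)
  }
  binding_table <- dplyr::bind_rows(binding)
  common <- common_segment_report(purrr::compact(interfaces))
  out <- list(binding_table = binding_table, flat_stages = stages,
              interfaces = interfaces, common = common,
              snapshots = snapshots, projection = projection,
              truths = truths, monomer = monomer)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(binding_table, file.path(cfg$out_dir, "binding.tsv"))
    write_tsv(common$support, file.path(cfg$out_dir, "segment_support.tsv"))
    write_tsv(common$common, file.path(cfg$out_dir, "common_segments.tsv"))
    if (!is.null(projection)) {
      write_tsv(projection, file.path(cfg$out_dir, "projection.tsv"))
    }
    for (i in seq_along(interfaces)) {
      if (is.null(interfaces[[i]])) next
      write_tsv(tidy(interfaces[[i]]$map),
                file.path(cfg$out_dir, sprintf("interface_sim%d.tsv", i)))
    }
    for (i in seq_along(snapshots)) {
      if (is.null(snapshots[[i]])) next
      write_pdb(traj_frame(trajectories[[i]], snapshots[[i]]$frame),
                file.path(cfg$out_dir, sprintf("snapshot_sim%d.pdb", i)))
    }
    write_manifest(cfg$out_dir, cfg)
  }
  out
}
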