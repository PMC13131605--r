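#' Simulate the stratifying epidermis
#'
#' The main orchestration loop.  Vertices advance by Langevin steps in
#' segments of `t_retess`; at that cadence the topology is refreshed by full
#' re-tessellation from cell centroids (so neighbor exchanges can occur
#' between divisions) followed by a brief relaxation, and the stratification
#' checks run.  Divisions fire at multiples of `spec$t_div` on the designated
#' growing cell; the homeostatic density check runs at multiples of `t_pop`.
#'
#' @param tissue a layered `vm_tissue` (see [build_initial_tissue()]).
#' @param params a `vm_params` (stage applied via [stage_to_params()]).
#' @param t_end run length (tau).
#' @param spec a [division_spec()], or `NULL` for a division-free run.
#' @param protocol `"homeostatic"` (fate conversions keep the basal count
#'   near its initial value) or `"densifying"` (no fate conversion).
#' @param t_pop homeostasis check interval; default `t_div/2` (or 100 without
#'   divisions).
#' @param t_retess re-tessellation cadence (tau).
#' @param alpha growth rate of the designated growing cell.
#' @param record_every trajectory sampling interval (tau).
#' @param log optionally a pre-built [new_event_log()] to append to.
#' @param division_mode `"timer"` (default: divisions fire at multiples of
#'   `t_div` regardless of the growing cell's volume) or `"volume"` (the
#'   growing cell divides once its target volume reaches
#'   `division_volume_threshold`).
#' @param division_volume_threshold target-volume trigger for
#'   `division_mode = "volume"`.
#' @param measure_long_axis record the growing cell's long-axis orientation
#'   just before each division.
#' @param divide_along_long_axis orient each division along the measured
#'   long axis instead of `spec`'s fixed angles.
#' @param relax_maxit iteration cap of the post-retessellation relaxation.
#' @param div_relax_maxit iteration cap of the post-division relaxation.
#' @param verbose print progress.
#' @return list with the final `tissue`, the event `log`, `trajectories`
#'   (data frame `time, cell, type, x, y, z`), `long_axis` (data frame of
#'   pre-division orientation samples) and `params`.
#' @export
simulate_epidermis <- function(tissue, params, t_end, spec = NULL,
                               protocol = c("homeostatic", "densifying"),
                               t_pop = NULL, t_retess = 1, alpha = 1 / 200,
                               record_every = 1, log = NULL,
                               division_mode = c("timer", "volume"),
                               division_volume_threshold = 2,
                               measure_long_axis = FALSE,
                               divide_along_long_axis = FALSE,
                               relax_maxit = 30, div_relax_maxit = 150,
                               verbose = FALSE) {
  protocol <- match.arg(protocol)
  division_mode <- match.arg(division_mode)
  if (is.null(t_pop))
    t_pop <- if (!is.null(spec)) max(t_retess, spec$t_div / 2) else 100
  if (!is.null(spec) && abs(spec$t_div / t_retess - round(spec$t_div / t_retess)) > 1e-9)
    stop("t_div must be a multiple of t_retess")
  tissue <- set_cell_targets(tissue, params)
  if (is.null(log))
    log <- new_event_log(protocol, t_pop,
                         n_basal0 = sum(tissue$cells$type == "basal"))
  if (is.na(log$n_basal0)) log$n_basal0 <- sum(tissue$cells$type == "basal")
  if (!is.null(spec)) tissue <- ensure_growing_cell(tissue, alpha)

  steps_per_seg <- max(1L, round(t_retess / params$dt))
  n_seg <- round(t_end / t_retess)
  traj <- list()
  long_axis <- list()
  t_start <- tissue$time

  record <- function(tissue) {
    geo <- tissue_metrics(tissue)
    traj[[length(traj) + 1L]] <<- data.frame(
      time = tissue$time, cell = tissue$cells$id, type = tissue$cells$type,
      x = geo$centroid[, 1], y = geo$centroid[, 2], z = geo$centroid[, 3],
      stringsAsFactors = FALSE)
  }
  record(tissue)

  # trigger context: was the stratifying cell born within one t_div?
  recent_daughter <- function(id, t_now) {
    if (is.null(spec) || length(log$divisions) == 0) return("neighbor")
    for (e in log$divisions)
      if (id %in% c(e$d1, e$d2) && t_now - e$time <= spec$t_div)
        return("daughter")
    "neighbor"
  }

  run_strat_checks <- function(tissue) {
    iface <- tryCatch(compute_bs_interface(tissue), error = function(e) NA_real_)
    if (is.finite(iface)) {
      for (id in detect_homotypic(tissue, iface)) {
        tissue <- switch_to_suprabasal(tissue, id, params)
        .log_event(log, tissue$time, id, "homotypic",
                   sum(tissue$cells$type == "basal"),
                   context = recent_daughter(id, tissue$time))
        tissue <- ghost_convert_top(tissue)
      }
    }
    tissue
  }

  for (seg in seq_len(n_seg)) {
    tissue <- langevin_step(tissue, params, steps_per_seg)
    t_now <- t_start + seg * t_retess
    tissue$time <- t_now  # avoid fp drift in the scheduler

    due_division <- !is.null(spec) &&
      if (division_mode == "timer") {
        abs(t_now / spec$t_div - round(t_now / spec$t_div)) < 1e-9
      } else {
        any(tissue$cells$alpha > 0 &
              tissue$cells$V0 >= division_volume_threshold)
      }
    if (due_division) {
      gid <- tissue$cells$id[tissue$cells$alpha > 0][1]
      if (is.na(gid)) {
        tissue <- ensure_growing_cell(tissue, alpha)
        gid <- attr(tissue, "growing_cell")
      }
      th <- spec$theta; ph <- spec$phi
      if (measure_long_axis || divide_along_long_axis) {
        ax <- fit_ellipsoid(tissue, gid)
        if (measure_long_axis && !ax$degenerate)
          long_axis[[length(long_axis) + 1L]] <-
            data.frame(time = t_now, cell = gid, theta = ax$theta_long,
                       phi = ax$phi_long)
        if (divide_along_long_axis && !ax$degenerate) {
          th <- ax$theta_long; ph <- ax$phi_long
        }
      }
      dv <- divide_cell(tissue, gid, division_spec(th, ph, spec$t_div,
                                                   spec$ell_sep),
                        params, relax_maxit = div_relax_maxit)
      tissue <- dv$tissue
      log$N_div <- log$N_div + 1L
      log$divisions[[length(log$divisions) + 1L]] <- dv$event
      tissue <- ensure_growing_cell(tissue, alpha)
      if (verbose) message("t=", t_now, " division #", log$N_div)
    } else {
      tissue <- retessellate(tissue)
      tissue <- minimize_tissue(tissue, params, maxit = relax_maxit)
    }

    tissue <- run_strat_checks(tissue)
    if (!is.null(spec)) tissue <- ensure_growing_cell(tissue, alpha)

    if (protocol == "homeostatic" &&
        abs(t_now / t_pop - round(t_now / t_pop)) < 1e-9) {
      hc <- homeostatic_check(tissue, log, params, t_now)
      tissue <- hc$tissue
    }

    if (abs(t_now / record_every - round(t_now / record_every)) < 1e-9)
      record(tissue)
  }
  list(tissue = tissue, log = log, trajectories = do.call(rbind, traj),
       long_axis = if (length(long_axis)) do.call(rbind, long_axis) else
         data.frame(time = numeric(0), cell = integer(0), theta = numeric(0),
                    phi = numeric(0)),
       params = params)
}

#' Run a configured experiment
#'
#' Thin dispatcher over the simulation and analysis layers.  Experiments:
#' \describe{
#'   \item{`growth_orientation`}{grow randomly designated basal cells and
#'     record the long-axis orientation prior to each division (divisions
#'     oriented along the measured long axis).}
#'   \item{`division_sweep`}{a division run at fixed angle/stage/protocol,
#'     returning event logs and stratification yields.}
#'   \item{`droplet`}{the droplet rheometer plus a two-timescale fit.}
#' }
#'
#' @param config a list with entries `experiment`, `stage`, `theta`, `t_div`,
#'   `protocol`, `t_end`, `n_basal`, `seed`, `alpha`, `out_dir`, plus
#'   overrides passed to [default_params()].
#' @return experiment-specific result list; if `config$out_dir` is set the
#'   tables are also written there as delimited text.
#' @export
run_experiment <- function(config) {
  experiment <- match.arg(config$experiment,
                          c("growth_orientation", "division_sweep", "droplet"))
  seed <- config$seed %||% 1L
  set.seed(seed)
  stage <- config$stage %||% "E14"
  params <- default_params(stage = stage,
                           D_t = config$D_t %||% 0.02,
                           dt = config$dt %||% 0.01)
  out <- switch(experiment,
    growth_orientation = {
      tissue <- build_initial_tissue(config$n_basal %||% 36,
                                     config$n_suprabasal_layers %||% 2,
                                     jitter = config$jitter %||% 0.25)
      tissue <- set_cell_targets(tissue, params)
      tissue <- minimize_tissue(tissue, params, maxit = 300)
      res <- simulate_epidermis(tissue, params,
                                t_end = config$t_end %||% 200,
                                spec = division_spec(0, t_div = config$t_div %||% 20),
                                protocol = "homeostatic",
                                alpha = config$alpha %||% 0.05,
                                measure_long_axis = TRUE,
                                divide_along_long_axis = TRUE)
      dist <- long_axis_distribution(res$long_axis$theta)
      c(res, list(distribution = dist))
    },
    division_sweep = {
      tissue <- build_initial_tissue(config$n_basal %||% 36,
                                     config$n_suprabasal_layers %||% 2,
                                     jitter = config$jitter %||% 0.25)
      tissue <- set_cell_targets(tissue, params)
      tissue <- minimize_tissue(tissue, params, maxit = 300)
      spec <- division_spec(config$theta %||% 0, t_div = config$t_div %||% 25)
      res <- simulate_epidermis(tissue, params,
                                t_end = config$t_end %||% (10 * spec$t_div),
                                spec = spec,
                                protocol = config$protocol %||% "homeostatic",
                                alpha = config$alpha %||% 0.05)
      c(res, list(yield = stratification_yield(res$log)))
    },
    droplet = {
      cfg <- droplet_config(
        n_droplet_cells = config$n_droplet_cells %||% 7,
        sigma_drop = config$sigma_drop %||% 0.8,
        f = config$f %||% 0.5,
        t_on = config$t_on %||% 30, t_off = config$t_off %||% 120,
        n_cycles = config$n_cycles %||% 1)
      params$s0["suprabasal"] <- config$s0 %||% 5.8
      trace <- run_droplet_experiment(cfg, params,
                                      tissue = build_bulk_tissue(
                                        config$nx %||% 6, config$ny %||% 6,
                                        config$nz %||% 5,
                                        jitter = config$jitter %||% 0.3))
      fit <- fit_relaxation(trace)
      list(trace = trace, fit = fit, config = cfg)
    })
  if (!is.null(config$out_dir)) .write_experiment(out, experiment, config)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_experiment <- function(out, experiment, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wp <- function(df, name)
    write.csv(df, file.path(config$out_dir, paste0(name, ".csv")),
              row.names = FALSE)
  if (!is.null(out$trajectories)) wp(out$trajectories, "trajectories")
  if (!is.null(out$log)) {
    wp(event_table(out$log), "events")
    wp(division_table(out$log), "divisions")
  }
  if (!is.null(out$long_axis) && nrow(out$long_axis)) wp(out$long_axis, "long_axis")
  if (!is.null(out$trace)) wp(out$trace, "strain_trace")
  cfgdf <- data.frame(key = names(config),
                      value = vapply(config, function(x)
                        paste(format(x), collapse = " "), character(1)))
  wp(cfgdf, "config")
  invisible(NULL)
}

#' Generate deterministic test fixtures
#'
#' Small inputs for unit tests: `tiny_tissue` (3x3 basal lattice),
#' `bilayer` (4x4 basal, one suprabasal layer), `synthetic_separation_trace`
#' (independent Brownian daughter pairs with known diffusivity) and
#' `synthetic_strain_trace` (two-exponential recovery with noise).
#'
#' @param kind fixture kind.
#' @param params named list of fixture parameters (see details in code).
#' @param seed RNG seed.
#' @return fixture object (tissue or data structure).
#' @export
generate_fixture <- function(kind = c("tiny_tissue", "bilayer",
                                      "synthetic_separation_trace",
                                      "synthetic_strain_trace"),
                             params = list(), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    tiny_tissue = build_initial_tissue(9, 1, jitter = params$jitter %||% 0.25),
    bilayer = build_initial_tissue(16, 1, jitter = params$jitter %||% 0.25),
    synthetic_separation_trace = {
      n_pairs <- params$n_pairs %||% 40
      D0 <- params$D0 %||% 0.01
      t_max <- params$t_max %||% 50
      dt <- params$dt %||% 1
      times <- seq(0, t_max, by = dt)
      box <- c(1e6, 1e6, 0, 1e6, 0)
      events <- data.frame(time = 0, d1 = seq_len(n_pairs) * 2 - 1,
                           d2 = seq_len(n_pairs) * 2)
      traj <- list()
      for (p in seq_len(n_pairs)) {
        for (d in c(events$d1[p], events$d2[p])) {
          steps <- matrix(stats::rnorm(3 * (length(times) - 1),
                                       sd = sqrt(2 * D0 * dt)), ncol = 3)
          pos <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
          traj[[length(traj) + 1L]] <- data.frame(
            time = times, cell = d, type = "basal",
            x = pos[, 1], y = pos[, 2], z = pos[, 3])
        }
      }
      list(events = events, trajectories = do.call(rbind, traj), box = box,
           D0 = D0)
    },
    synthetic_strain_trace = {
      A1 <- params$A1 %||% 0.05
      A2 <- params$A2 %||% 0.05
      tau1 <- params$tau1 %||% 10
      tau2 <- params$tau2 %||% 68
      noise <- params$noise %||% 0.01
      t <- seq(0, params$t_max %||% 400, by = params$dt %||% 0.5)
      eps <- A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
      eps <- eps * (1 + stats::rnorm(length(t), sd = noise))
      data.frame(time = t, strain = eps, phase = "off")
    })
}

#' Write a tissue snapshot to a portable mesh + metadata
#'
#' Writes `<path>.off` (every cell's closed boundary as an OFF polygon mesh,
#' vertices duplicated per cell so volumes can be recomputed offline),
#' `<path>_cells.csv` (cell id, type, targets) and `<path>_faces.csv`
#' (face-to-cell mapping in mesh order).
#'
#' @param tissue a `vm_tissue`.
#' @param path output path prefix.
#' @return the paths written, invisibly.
#' @export
snapshot_writer <- function(tissue, path) {
  nc <- nrow(tissue$cells)
  verts <- list()
  faces <- list()
  face_cell <- integer(0)
  nv <- 0L
  b <- tissue$box
  L <- c(b[1], b[2], b[4] - b[3])
  for (r in seq_len(nc)) {
    for (f in tissue$cell_faces[[r]]) {
      ids <- tissue$face_vertices[[f]]
      sh <- tissue$face_shifts[[f]]
      P <- tissue$vertices[ids, , drop = FALSE] + sh %*% diag(L)
      ctr <- colMeans(P)
      off <- -L * round((ctr - tissue$cell_ref[r, ]) / L)
      if (b[5] == 0) off[3] <- 0
      P <- sweep(P, 2, -off)
      if (tissue$face_cells[f, 1] != r) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
      verts[[length(verts) + 1L]] <- P
      faces[[length(faces) + 1L]] <- nv + seq_len(nrow(P)) - 1L
      face_cell <- c(face_cell, r)
      nv <- nv + nrow(P)
    }
  }
  V <- do.call(rbind, verts)
  off_path <- paste0(path, ".off")
  con <- file(off_path, "w")
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(V), length(faces)), con)
  writeLines(apply(V, 1, function(p) sprintf("%.10g %.10g %.10g",
                                             p[1], p[2], p[3])), con)
  writeLines(vapply(faces, function(f)
    paste(c(length(f), f), collapse = " "), character(1)), con)
  close(con)
  cells_path <- paste0(path, "_cells.csv")
  write.csv(cbind(tissue$cells,
                  ghost = tissue$cells$type == "ghost"),
            cells_path, row.names = FALSE)
  faces_path <- paste0(path, "_faces.csv")
  write.csv(data.frame(mesh_face = seq_along(face_cell), cell = face_cell),
            faces_path, row.names = FALSE)
  invisible(c(off_path, cells_path, faces_path))
}

#' Read a snapshot written by [snapshot_writer()]
#' @param path the path prefix used when writing.
#' @return list with `vertices`, `faces` (1-based index lists), `face_cell`,
#'   `cells`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(paste0(path, ".off"))
  stopifnot(lines[1] == "OFF")
  hdr <- as.integer(strsplit(lines[2], " ")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  V <- matrix(as.numeric(unlist(strsplit(lines[3:(2 + nv)], " "))),
              ncol = 3, byrow = TRUE)
  faces <- lapply(strsplit(lines[(3 + nv):(2 + nv + nf)], " "), function(x) {
    x <- as.integer(x)
    x[-1] + 1L
  })
  list(vertices = V, faces = faces,
       face_cell = read.csv(paste0(path, "_faces.csv"))$cell,
       cells = read.csv(paste0(path, "_cells.csv")))
}

#' Per-cell volumes of a snapshot mesh
#' @param snap output of [read_snapshot()].
#' @return numeric vector of cell volumes (mesh order).
#' @export
mesh_cell_volumes <- function(snap) {
  vols <- numeric(max(snap$face_cell))
  for (k in seq_along(snap$faces)) {
    P <- snap$vertices[snap$faces[[k]], , drop = FALSE]
    ctr <- colMeans(P)
    m <- nrow(P)
    v <- 0
    for (e in seq_len(m)) {
      a <- P[e, ]; b2 <- P[if (e == m) 1 else e + 1, ]
      v <- v + sum(ctr * c(a[2] * b2[3] - a[3] * b2[2],
                           a[3] * b2[1] - a[1] * b2[3],
                           a[1] * b2[2] - a[2] * b2[1])) / 6
    }
    vols[snap$face_cell[k]] <- vols[snap$face_cell[k]] + v
  }
  vols
}
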