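#' Droplet rheometer configuration
#'
#' An in-silico ferrofluid droplet: a contiguous blob of vertex cells kept in
#' the fluid regime (`s_droplet = 5.8`, where the cells do not contribute to
#' the shear modulus), distinguished from the tissue by a heterotypic
#' interfacial tension, and actuated by a zero-net-force dipole along x.
#'
#' @param n_droplet_cells number of droplet cells (17 at full scale).
#' @param s_droplet droplet-cell target shape index.
#' @param sigma_drop droplet-tissue heterotypic tension.
#' @param f dipole strength.
#' @param t_on,t_off actuation phase durations (tau).
#' @param n_cycles number of on/off cycles.
#' @return a `droplet_config` list.
#' @export
droplet_config <- function(n_droplet_cells = 17, s_droplet = 5.8,
                           sigma_drop = 0.8, f = 0.5, t_on = 50, t_off = 200,
                           n_cycles = 3) {
  structure(list(n_droplet_cells = n_droplet_cells, s_droplet = s_droplet,
                 sigma_drop = sigma_drop, f = f, t_on = t_on, t_off = t_off,
                 n_cycles = n_cycles), class = "droplet_config")
}

#' Embed a droplet into a bulk tissue
#'
#' Re-types a contiguous blob of cells (grown by face adjacency from the cell
#' nearest the box centre) as droplet cells and applies the droplet targets
#' and droplet-tissue tension to the parameter set.
#'
#' @param tissue a bulk `vm_tissue`.
#' @param cfg a [droplet_config()].
#' @param params a `vm_params`; updated with `s0_droplet` and `sigma_drop`.
#' @return list of the updated `tissue` and `params`.
#' @export
embed_droplet <- function(tissue, cfg, params = default_params()) {
  n <- nrow(tissue$cells)
  if (cfg$n_droplet_cells >= n / 4)
    stop("tissue too small to bulk-embed the requested droplet")
  geo <- tissue_metrics(tissue)
  b <- tissue$box
  ctr <- c(b[1] / 2, b[2] / 2, (b[3] + b[4]) / 2)
  d2 <- rowSums(sweep(geo$centroid, 2, ctr)^2)
  seed_cell <- which.min(d2)
  adj <- cell_adjacency(tissue)
  nbrs <- function(r) unique(c(adj[adj[, 1] == r, 2], adj[adj[, 2] == r, 1]))
  blob <- seed_cell
  frontier <- seed_cell
  while (length(blob) < cfg$n_droplet_cells) {
    cand <- setdiff(unique(unlist(lapply(frontier, nbrs))), blob)
    if (length(cand) == 0) break
    cand <- cand[order(d2[cand])]
    take <- head(cand, cfg$n_droplet_cells - length(blob))
    blob <- c(blob, take)
    frontier <- take
  }
  tissue$cells$type[blob] <- "droplet"
  params$s0["droplet"] <- cfg$s_droplet
  for (ty in c("basement", "basal", "suprabasal"))
    params$sigma["droplet", ty] <- params$sigma[ty, "droplet"] <- cfg$sigma_drop
  tissue <- set_cell_targets(tissue, params)
  list(tissue = tissue, params = params)
}

#' External dipole forces on the droplet vertices
#'
#' Each droplet-cell vertex receives `F = f (x_i - x_cm) xhat` with `x_cm`
#' the droplet-vertex centre of mass; all other vertices receive zero.  The
#' net external force vanishes exactly.
#'
#' @param tissue a `vm_tissue` with an embedded droplet.
#' @param cfg a [droplet_config()] (only `f` is used).
#' @return n_vertices x 3 force matrix.
#' @export
apply_dipole <- function(tissue, cfg) {
  mask <- .droplet_vertex_mask(tissue)
  F <- matrix(0, nrow(tissue$vertices), 3)
  if (!any(mask) || cfg$f == 0) return(F)
  x <- tissue$vertices[mask, 1]
  F[mask, 1] <- cfg$f * (x - mean(x))
  F
}

#' Droplet strain
#'
#' Gyration-tensor fit of the droplet vertex cloud; the strain is the
#' elongation along the force axis relative to the mean transverse extent,
#' `eps = l_par / l_perp - 1`, positive under stretch and zero for a sphere.
#'
#' @param tissue a `vm_tissue` with an embedded droplet.
#' @return scalar strain (NA when the fit is degenerate).
#' @export
measure_strain <- function(tissue) {
  rows <- which(tissue$cells$type == "droplet")
  if (length(rows) == 0) stop("no droplet embedded")
  pts <- NULL
  for (r in rows) pts <- rbind(pts, .vm_cell_vertices(tissue$vertices,
                                                      .tess_arg(tissue), r))
  # unwrap around the first point (minimal image)
  b <- tissue$box
  L <- c(b[1], b[2], b[4] - b[3])
  ref <- pts[1, ]
  for (d in 1:3)
    pts[, d] <- pts[, d] - L[d] * round((pts[, d] - ref[d]) / L[d])
  .strain_of_points(pts)
}

# elongation along x relative to the mean transverse extent
.strain_of_points <- function(pts) {
  ctr <- colMeans(pts)
  dd <- sweep(pts, 2, ctr)
  G <- crossprod(dd) / nrow(dd)
  l_par <- sqrt(G[1, 1])
  l_perp <- sqrt((G[2, 2] + G[3, 3]) / 2)
  if (!is.finite(l_perp) || l_perp <= 0) return(NA_real_)
  l_par / l_perp - 1
}

#' Run the droplet rheometer experiment
#'
#' Builds (or accepts) a bulk tissue, embeds the droplet, relaxes, then runs
#' `n_cycles` of dipole actuation (`t_on`) and recovery (`t_off`), recording
#' the strain trace.  Topology is refreshed by re-tessellation at cadence
#' `t_retess`.
#'
#' @param cfg a [droplet_config()].
#' @param params a `vm_params`.
#' @param tissue optional pre-built bulk tissue (default 8x8x5 cells).
#' @param t_retess re-tessellation cadence (tau).
#' @param record_every strain sampling interval (tau).
#' @param seed RNG seed.
#' @param relax_maxit iterations for the initial relaxation.
#' @param retess_maxit iterations for the relaxation after each cadence
#'   rebuild (the dipole is held on during actuated phases).
#' @return a data frame `strain_trace` with columns `time`, `strain`, `phase`.
#' @export
run_droplet_experiment <- function(cfg = droplet_config(), params = default_params(),
                                   tissue = NULL, t_retess = 1,
                                   record_every = 1, seed = NULL,
                                   relax_maxit = 400, retess_maxit = 120) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tissue)) tissue <- build_bulk_tissue(8, 8, 5, jitter = 0.3)
  emb <- embed_droplet(tissue, cfg, params)
  tissue <- emb$tissue
  params <- emb$params
  tissue <- minimize_tissue(tissue, params, maxit = relax_maxit)
  tissue <- retessellate(tissue)
  tissue <- set_cell_targets(tissue, params)
  tissue <- minimize_tissue(tissue, params, maxit = relax_maxit)

  steps_per <- max(1L, round(record_every / params$dt))
  trace <- list()
  t0 <- tissue$time
  push <- function(tissue, phase) {
    trace[[length(trace) + 1L]] <<- data.frame(
      time = tissue$time - t0, strain = measure_strain(tissue), phase = phase)
  }
  push(tissue, "off")
  last_retess <- tissue$time
  advance <- function(tissue, duration, f, phase) {
    n_rec <- round(duration / record_every)
    for (k in seq_len(n_rec)) {
      tissue <- langevin_step(tissue, params, steps_per, dipole_f = f)
      if (tissue$time - last_retess >= t_retess - 1e-9) {
        tissue <- retessellate(tissue)
        tissue <- minimize_tissue(tissue, params, maxit = retess_maxit,
                                  dipole_f = f)
        last_retess <<- tissue$time
      }
      push(tissue, phase)
    }
    tissue
  }
  for (cyc in seq_len(cfg$n_cycles)) {
    tissue <- advance(tissue, cfg$t_on, cfg$f, "on")
    tissue <- advance(tissue, cfg$t_off, 0, "off")
  }
  out <- do.call(rbind, trace)
  class(out) <- c("strain_trace", class(out))
  out
}

#' Fit a generalized-Maxwell two-timescale relaxation
#'
#' Nonlinear least squares of `eps(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2)` on
#' a recovery (force-off) branch of a strain trace, with multi-start
#' restarts; `tau1 < tau2` by convention.
#'
#' @param trace a data frame with columns `time` and `strain` (and optionally
#'   `phase`, in which case the last complete off-phase is used).
#' @param n_starts number of random restarts.
#' @return list with `tau1`, `tau2`, `A1`, `A2`, `residual`, `converged`.
#' @export
fit_relaxation <- function(trace, n_starts = 12) {
  df <- as.data.frame(trace)
  if (!is.null(df$phase)) {
    off <- df$phase == "off"
    # last maximal run of off-phase samples
    r <- rle(off)
    ends <- cumsum(r$lengths)
    runs <- which(r$values & r$lengths >= 5)
    if (length(runs) == 0) stop("trace contains no usable off-phase")
    i <- runs[length(runs)]
    idx <- (ends[i] - r$lengths[i] + 1):ends[i]
    df <- df[idx, ]
  }
  df <- df[complete.cases(df[, c("time", "strain")]), ]
  t <- df$time - df$time[1]
  y <- df$strain
  if (length(t) < 6) stop("too few points on the recovery branch")
  span <- max(t)
  amp0 <- max(abs(y))
  best <- NULL
  set_starts <- expand.grid(tau1 = span * c(0.01, 0.03, 0.1),
                            tau2 = span * c(0.25, 0.5, 1))
  set_starts <- set_starts[seq_len(min(nrow(set_starts), n_starts)), ]
  # amplitudes bounded by the observed range and tau2 by a multiple of the
  # span: keeps the two-exponential model identifiable on noisy traces
  for (k in seq_len(nrow(set_starts))) {
    fit <- tryCatch(
      suppressWarnings(
        nls(y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
            start = list(A1 = y[1] / 2, A2 = y[1] / 2,
                         tau1 = set_starts$tau1[k], tau2 = set_starts$tau2[k]),
            control = nls.control(maxiter = 200, warnOnly = TRUE),
            lower = c(-2 * amp0, -2 * amp0, 1e-6, 1e-6),
            upper = c(2 * amp0, 2 * amp0, span, 3 * span),
            algorithm = "port")),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(list(tau1 = NA_real_, tau2 = NA_real_,
                                 A1 = NA_real_, A2 = NA_real_,
                                 residual = NA_real_, converged = FALSE))
  cf <- coef(best$fit)
  taus <- sort(c(cf[["tau1"]], cf[["tau2"]]))
  amps <- c(cf[["A1"]], cf[["A2"]])[order(c(cf[["tau1"]], cf[["tau2"]]))]
  list(tau1 = taus[1], tau2 = taus[2], A1 = amps[1], A2 = amps[2],
       residual = sqrt(best$rss / length(t)), converged = TRUE)
}
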