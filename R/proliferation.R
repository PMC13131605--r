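#' Division specification
#'
#' The mitotic axis is `n = (cos(theta) cos(phi), cos(theta) sin(phi),
#' sin(theta))`: `theta = 0` is an in-plane (symmetric) division, `theta =
#' pi/2` a perpendicular (asymmetric) one; the azimuth `phi` defaults to 0
#' without loss of generality.
#'
#' @param theta division-plane angle in \[0, pi/2\] relative to the basal plane.
#' @param phi azimuth in \[0, 2*pi).
#' @param t_div division interval (tau).
#' @param ell_sep daughter-seed separation distance (defaults to
#'   `0.3 * V0^(1/3)` at division time).
#' @return a `division_spec` list.
#' @export
division_spec <- function(theta, phi = 0, t_div = 200, ell_sep = NULL) {
  if (theta < 0 || theta > pi / 2 + 1e-12) stop("theta must lie in [0, pi/2]")
  structure(list(theta = theta, phi = phi %% (2 * pi), t_div = t_div,
                 ell_sep = ell_sep), class = "division_spec")
}

#' Designate the growing basal cell
#'
#' Ensures exactly one basal cell has a nonzero growth rate.  If the current
#' growing cell is still basal, the designation is unchanged; otherwise a
#' basal cell is chosen uniformly at random.
#'
#' @param tissue a `vm_tissue`.
#' @param alpha growth rate assigned to the designated cell (volume per tau).
#' @return the updated tissue; the chosen cell id is in attribute
#'   `growing_cell`.
#' @export
ensure_growing_cell <- function(tissue, alpha = 1 / 200) {
  basal <- which(tissue$cells$type == "basal")
  if (length(basal) == 0) stop("tissue collapsed: no basal cells remain")
  grow <- which(tissue$cells$alpha > 0)
  keep <- grow[tissue$cells$type[grow] == "basal"]
  tissue$cells$alpha <- 0
  if (length(keep) >= 1) {
    pick <- keep[1]
  } else {
    pick <- basal[sample.int(length(basal), 1)]
  }
  tissue$cells$alpha[pick] <- alpha
  attr(tissue, "growing_cell") <- tissue$cells$id[pick]
  tissue
}

#' Grow the designated cell's target volume
#'
#' `V0 <- V0 + alpha * dt` for every cell with nonzero growth rate, with the
#' target surface area updated to keep the target shape index fixed
#' (`S0 = s0 * V0^(2/3)`).
#'
#' @param tissue a `vm_tissue`.
#' @param dt time increment (tau).
#' @return the updated tissue.
#' @export
grow_step <- function(tissue, dt) {
  g <- tissue$cells$alpha != 0
  if (any(g)) {
    tissue$cells$V0[g] <- tissue$cells$V0[g] + tissue$cells$alpha[g] * dt
    tissue$cells$S0[g] <- tissue$cells$s0[g] * tissue$cells$V0[g]^(2 / 3)
  }
  tissue
}

#' Divide a basal cell along a prescribed mitotic axis
#'
#' The parent cell is replaced by two daughter Voronoi seeds displaced by
#' `+/- ell_sep/2` along the mitotic axis from the parent centroid; the full
#' tessellation is recomputed, the daughters share the parent's target volume
#' equally, both inherit the basal identity, and the energy is re-minimized
#' before dynamics resume.
#'
#' @param tissue a `vm_tissue` with initialised targets.
#' @param cell_id id of the (basal) parent.
#' @param spec a [division_spec()].
#' @param params a `vm_params` (for the post-division relaxation).
#' @param relax_maxit iteration cap for the relaxation.
#' @return list with the new `tissue` and the `event` record.
#' @export
divide_cell <- function(tissue, cell_id, spec, params, relax_maxit = 200) {
  row <- match(cell_id, tissue$cells$id)
  if (is.na(row)) stop("no cell with id ", cell_id)
  if (tissue$cells$type[row] != "basal") stop("only basal cells divide")
  geo <- tissue_metrics(tissue)
  seeds <- geo$centroid
  parent_c <- seeds[row, ]
  V0p <- tissue$cells$V0[row]
  ell <- if (is.null(spec$ell_sep)) 0.3 * V0p^(1 / 3) else spec$ell_sep
  nhat <- c(cos(spec$theta) * cos(spec$phi), cos(spec$theta) * sin(spec$phi),
            sin(spec$theta))
  s1 <- parent_c - (ell / 2) * nhat
  s2 <- parent_c + (ell / 2) * nhat
  # keep daughter seeds inside the basal slab
  if (tissue$box[5] == 0) {
    zlo <- tissue$box[3] + 1.05
    zhi <- tissue$box[4] - 0.55
    if (s1[3] < zlo || s1[3] > zhi || s2[3] < zlo || s2[3] > zhi)
      warning("daughter seed clamped into the basal slab")
    s1[3] <- min(max(s1[3], zlo), zhi)
    s2[3] <- min(max(s2[3], zlo), zhi)
  }

  cells <- tissue$cells
  d1 <- max(cells$id) + 1L
  d2 <- max(cells$id) + 2L
  s0b <- cells$s0[row]
  cells$id[row] <- d1
  cells$V0[row] <- V0p / 2
  cells$S0[row] <- s0b * (V0p / 2)^(2 / 3)
  cells$alpha[row] <- 0
  newrow <- cells[row, , drop = FALSE]
  newrow$id <- d2
  cells <- rbind(cells, newrow)
  rownames(cells) <- NULL
  seeds[row, ] <- s1
  seeds <- rbind(seeds, s2)

  out <- .tessellate(seeds, tissue$box, cells)
  out$time <- tissue$time
  out <- minimize_tissue(out, params, maxit = relax_maxit)
  event <- list(time = tissue$time, parent = cell_id, d1 = d1, d2 = d2,
                theta = spec$theta, phi = spec$phi,
                pos1 = s1, pos2 = s2)
  list(tissue = out, event = event)
}

#' Division schedule over a run
#'
#' Divisions fire exactly once per `t_div` window, at multiples of `t_div`;
#' at most one cell divides per time step.
#'
#' @param t_end run length (tau).
#' @param t_div division interval (tau).
#' @return vector of division times.
#' @export
division_times <- function(t_end, t_div) {
  if (t_div <= 0) stop("t_div must be positive")
  out <- seq(t_div, t_end, by = t_div)
  out[out <= t_end]
}

#' Division-rate unit conversions
#'
#' In simulation units the basal division rate is `lambda = 1 / (N_basal *
#' t_div)` per tau per cell.  With the natural time unit `tau = 0.1` min one
#' estimated day is `14400` tau, so the physical rate is `lambda = 14400 /
#' (N_basal * t_div)` divisions per basal cell per estimated day.
#'
#' @param n_basal number of basal cells.
#' @param t_div division interval (tau).
#' @param tau_minutes physical duration of one tau (minutes).
#' @return list with `lambda_sim` (per tau per cell), `lambda_per_day`, and
#'   `tau_per_day`.
#' @export
rate_conversions <- function(n_basal, t_div, tau_minutes = 0.1) {
  if (n_basal <= 0 || t_div <= 0 || tau_minutes <= 0)
    stop("all inputs must be positive")
  tau_per_day <- 24 * 60 / tau_minutes
  list(lambda_sim = 1 / (n_basal * t_div),
       lambda_per_day = tau_per_day / (n_basal * t_div),
       tau_per_day = tau_per_day)
}

#' Dimensionless speed conversions for timescale calibration
#'
#' Converts a measured physical speed (e.g. the ~0.55 um/min migration speed
#' of Kupffer's vesicle) into units of cell lengths per minute and cell
#' lengths per simulation time unit tau, used to cross-check the natural
#' time unit tau = 0.1 min of the vertex model.
#'
#' @param speed_um_min physical speed in micrometres per minute.
#' @param cell_size_um characteristic cell size l in micrometres.
#' @param tau_minutes physical duration of one tau (minutes).
#' @return list with `l_per_min` and `l_per_tau`.
#' @export
speed_conversions <- function(speed_um_min, cell_size_um = 10,
                              tau_minutes = 0.1) {
  if (speed_um_min < 0 || cell_size_um <= 0 || tau_minutes <= 0)
    stop("inputs must be positive")
  l_per_min <- speed_um_min / cell_size_um
  list(l_per_min = l_per_min, l_per_tau = l_per_min * tau_minutes)
}

#' Division interval for a target physical division rate
#' @param n_basal number of basal cells.
#' @param lambda_per_day divisions per basal cell per estimated day.
#' @param tau_minutes physical duration of one tau (minutes).
#' @return t_div in tau.
#' @export
tdiv_for_rate <- function(n_basal, lambda_per_day, tau_minutes = 0.1) {
  (24 * 60 / tau_minutes) / (n_basal * lambda_per_day)
}
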