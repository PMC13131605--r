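#' Default mechanical parameters
#'
#' Nondimensional convention of the 3D vertex-model family: elastic moduli
#' `K_V = K_S = 1`, target volume `V0 = 1`, mobility `mu = 1`.  Per-type
#' target shape indices `s0` control rigidity (the basal reference
#' `s0_ref = 5.40` sits near the 3D rigidity transition); `D_t` is the
#' white-noise strength of the Langevin dynamics and `dt = 0.01` tau the
#' simulation time step.  The tension matrix `sigma` over unordered type
#' pairs carries the heterotypic interfacial tensions; it is filled in by
#' [stage_to_params()].
#'
#' @param stage optional stage preset name (`"E14"` or `"E16"`) or a
#'   [stage_params()] object; applied via [stage_to_params()].
#' @param K_V,K_S volume and surface moduli.
#' @param mu vertex mobility (inverse drag).
#' @param D_t translational noise strength.
#' @param dt time step (tau).
#' @param s0_ref basal reference target shape index.
#' @param s0_basement,s0_suprabasal,s0_droplet per-type target shape indices.
#' @param tol force tolerance of the minimizer.
#' @return a `vm_params` list.
#' @export
default_params <- function(stage = NULL, K_V = 1, K_S = 1, mu = 1, D_t = 0.02,
                           dt = 0.01, s0_ref = 5.40, s0_basement = 5.30,
                           s0_suprabasal = 5.50, s0_droplet = 5.80,
                           tol = 1e-3) {
  p <- list(K_V = K_V, K_S = K_S, mu = mu, D_t = D_t, dt = dt,
            s0_ref = s0_ref,
            s0 = c(basement = s0_basement, basal = s0_ref,
                   suprabasal = s0_suprabasal, ghost = 0,
                   droplet = s0_droplet),
            sigma = matrix(0, 5, 5, dimnames = list(names(.TYPES),
                                                    names(.TYPES))),
            tol = tol)
  class(p) <- "vm_params"
  if (!is.null(stage)) p <- stage_to_params(stage, p)
  p
}

#' Stage parameter triplets
#'
#' Experimentally inferred (sigma_a, sigma_b, delta_s) presets for the mouse
#' epidermis: the basal-suprabasal heterotypic tension, the basal-basement
#' wetting tension, and the basal stiffness shift.  Shipped presets are
#' E14 = (0.044, 0.062, 0) and E16 = (0.116, 0.067, 0.14).
#'
#' @param stage `"E14"`, `"E16"`, or leave `NULL` and give the triplet.
#' @param sigma_a,sigma_b,delta_s explicit values (override the preset).
#' @return a `stage_params` list.
#' @export
stage_params <- function(stage = NULL, sigma_a = NULL, sigma_b = NULL,
                         delta_s = NULL) {
  presets <- list(E14 = c(0.044, 0.062, 0), E16 = c(0.116, 0.067, 0.14))
  if (!is.null(stage)) {
    stage <- match.arg(stage, names(presets))
    v <- presets[[stage]]
  } else {
    v <- c(NA_real_, NA_real_, NA_real_)
  }
  out <- list(stage = if (is.null(stage)) "custom" else stage,
              sigma_a = if (is.null(sigma_a)) v[1] else sigma_a,
              sigma_b = if (is.null(sigma_b)) v[2] else sigma_b,
              delta_s = if (is.null(delta_s)) v[3] else delta_s)
  if (anyNA(unlist(out[2:4]))) stop("incomplete stage triplet")
  class(out) <- "stage_params"
  out
}

#' Apply a developmental-stage triplet to mechanical parameters
#'
#' Sets `sigma(basal, suprabasal) = sigma_a`, `sigma(basal, basement) =
#' sigma_b`, and lowers the basal target shape index to `s0_ref - delta_s`
#' (the stiffness shift acts through the rigidity-controlling shape index).
#'
#' @param stage a [stage_params()] object or preset name.
#' @param base a `vm_params` object to modify.
#' @return the updated `vm_params`.
#' @export
stage_to_params <- function(stage, base = default_params()) {
  if (is.character(stage)) stage <- stage_params(stage)
  s0_basal <- base$s0_ref - stage$delta_s
  if (s0_basal <= 0) stop("delta_s yields a negative basal shape index")
  p <- base
  p$stage <- stage
  p$s0["basal"] <- s0_basal
  p$sigma["basal", "suprabasal"] <- p$sigma["suprabasal", "basal"] <- stage$sigma_a
  p$sigma["basal", "basement"] <- p$sigma["basement", "basal"] <- stage$sigma_b
  p
}

#' @export
print.vm_params <- function(x, ...) {
  cat("<vm_params> K_V=", x$K_V, " K_S=", x$K_S, " mu=", x$mu,
      " D_t=", x$D_t, " dt=", x$dt, "\n", sep = "")
  cat("  s0:", paste(names(x$s0), signif(x$s0, 4), sep = "=", collapse = " "),
      "\n")
  nz <- which(x$sigma != 0 & upper.tri(x$sigma, diag = TRUE), arr.ind = TRUE)
  if (nrow(nz))
    cat("  sigma:", paste(rownames(x$sigma)[nz[, 1]], colnames(x$sigma)[nz[, 2]],
                          signif(x$sigma[nz], 4), sep = ":", collapse = " "), "\n")
  invisible(x)
}

# initialise / refresh per-cell targets from the parameter set
.apply_targets <- function(tissue, params) {
  s0 <- params$s0[tissue$cells$type]
  tissue$cells$s0 <- unname(s0)
  tissue$cells$S0 <- unname(s0) * tissue$cells$V0^(2 / 3)
  tissue
}

.check_targets <- function(tissue) {
  if (anyNA(tissue$cells$S0[tissue$cells$type != "ghost"]))
    stop("cell targets not initialised; call set_cell_targets() first")
}

#' Initialise per-cell mechanical targets from a parameter set
#'
#' Sets each cell's target shape index from its type and derives the target
#' surface area `S0 = s0 * V0^(2/3)`.
#' @param tissue a `vm_tissue`.
#' @param params a `vm_params`.
#' @return the updated tissue.
#' @export
set_cell_targets <- function(tissue, params) .apply_targets(tissue, params)

#' Total mechanical energy
#'
#' `E = sum_c K_V (V_c - V0_c)^2 + sum_c K_S (S_c - S0_c)^2 +
#' sum_f sigma_ij A_f` with ghost cells excluded from all sums and the
#' heterotypic term counted once per shared interface.
#'
#' @param tissue a `vm_tissue` with initialised targets.
#' @param params a `vm_params`.
#' @return scalar energy.
#' @export
tissue_energy <- function(tissue, params) {
  .check_targets(tissue)
  cl <- tissue$cells
  out <- .vm_eval(tissue$vertices, .tess_arg(tissue),
                  ifelse(is.na(cl$V0), 0, cl$V0),
                  ifelse(is.na(cl$S0), 0, cl$S0),
                  params$K_V, params$K_S, params$sigma, FALSE)
  out$energy
}

#' Per-vertex forces `-grad E`
#'
#' Analytic gradients of the volume, surface and interfacial terms.  Pinned
#' vertices (basement floor, ghost ceiling) receive zero force.
#'
#' @inheritParams tissue_energy
#' @return n_vertices x 3 matrix.
#' @export
tissue_forces <- function(tissue, params) {
  .check_targets(tissue)
  cl <- tissue$cells
  out <- .vm_eval(tissue$vertices, .tess_arg(tissue),
                  ifelse(is.na(cl$V0), 0, cl$V0),
                  ifelse(is.na(cl$S0), 0, cl$S0),
                  params$K_V, params$K_S, params$sigma, TRUE)
  F <- out$forces
  if (!all(is.finite(F))) {
    bad <- which(!is.finite(rowSums(F)))[1]
    stop("non-finite force at vertex ", bad)
  }
  F[tissue$pinned, ] <- 0
  F
}

#' Advance the vertices by Euler-Maruyama Langevin steps
#'
#' `r <- r + mu F dt + sqrt(2 D_t dt) xi` with standard-normal `xi` per
#' component; pinned vertices unmoved.  The designated growing cell's target
#' volume increases by `alpha dt` per step with `S0` following its target
#' shape index.  Uses R's RNG stream (seed with [set.seed()]).
#'
#' @param tissue a `vm_tissue` with initialised targets.
#' @param params a `vm_params`.
#' @param n_steps number of time steps.
#' @param dipole_f droplet dipole strength (0 = off).
#' @return the advanced tissue.
#' @export
langevin_step <- function(tissue, params, n_steps = 1, dipole_f = 0) {
  .check_targets(tissue)
  cl <- tissue$cells
  dmask <- .droplet_vertex_mask(tissue)
  out <- .vm_steps(tissue$vertices, .tess_arg(tissue),
                   ifelse(is.na(cl$V0), 0, cl$V0),
                   ifelse(is.na(cl$S0), 0, cl$S0),
                   ifelse(is.na(cl$s0), 0, cl$s0),
                   cl$alpha, params$K_V, params$K_S, params$sigma,
                   tissue$pinned, as.integer(n_steps), params$dt, params$mu,
                   params$D_t, dmask, dipole_f)
  tissue$vertices <- out$vertices
  tissue$cells$V0 <- out$V0
  tissue$cells$S0 <- out$S0
  tissue$time <- tissue$time + n_steps * params$dt
  tissue
}

.droplet_vertex_mask <- function(tissue) {
  mask <- rep(FALSE, nrow(tissue$vertices))
  rows <- which(tissue$cells$type == "droplet")
  for (r in rows)
    for (f in tissue$cell_faces[[r]])
      mask[tissue$face_vertices[[f]]] <- TRUE
  mask
}

#' Relax the tissue to a force balance (noise-free)
#'
#' Damped gradient descent with an adaptive step, run until
#' `max |F_i| < tol` or the iteration cap.
#'
#' @param tissue a `vm_tissue` with initialised targets.
#' @param params a `vm_params`.
#' @param tol force-residual tolerance (defaults to `params$tol`).
#' @param maxit iteration cap.
#' @param dipole_f droplet dipole strength held on during the relaxation
#'   (0 = unloaded).
#' @return the relaxed tissue, with attributes `energy`, `residual`,
#'   `iterations`, `converged`.
#' @export
minimize_tissue <- function(tissue, params, tol = params$tol, maxit = 2000,
                            dipole_f = 0) {
  .check_targets(tissue)
  cl <- tissue$cells
  dmask <- if (dipole_f != 0) .droplet_vertex_mask(tissue) else
    rep(FALSE, nrow(tissue$vertices))
  out <- .vm_minimize(tissue$vertices, .tess_arg(tissue),
                      ifelse(is.na(cl$V0), 0, cl$V0),
                      ifelse(is.na(cl$S0), 0, cl$S0),
                      params$K_V, params$K_S, params$sigma, tissue$pinned,
                      tol, as.integer(maxit), params$dt, dmask, dipole_f)
  if (!out$converged && maxit > 200)
    warning("minimize: iteration cap reached (residual ",
            signif(out$residual, 3), ")")
  tissue$vertices <- out$vertices
  attr(tissue, "energy") <- out$energy
  attr(tissue, "residual") <- out$residual
  attr(tissue, "iterations") <- out$iterations
  attr(tissue, "converged") <- out$converged
  tissue
}
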