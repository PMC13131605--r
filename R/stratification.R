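#' Create a stratification event log
#'
#' Book-keeps the stratification counters: `N_homo` (spontaneous/homotypic
#' events), `N_fate` (fate-conversion events under the homeostatic protocol)
#' and `N_div` (divisions), plus one record per event.
#'
#' @param protocol `"homeostatic"` or `"densifying"`.
#' @param t_pop homeostasis check interval (tau).
#' @param n_basal0 reference basal count `N_basal(0)`.
#' @return an `event_log` environment.
#' @export
new_event_log <- function(protocol = c("homeostatic", "densifying"),
                          t_pop = 100, n_basal0 = NA_integer_) {
  protocol <- match.arg(protocol)
  log <- new.env(parent = emptyenv())
  log$protocol <- protocol
  log$t_pop <- t_pop
  log$n_basal0 <- n_basal0
  log$N_homo <- 0L
  log$N_fate <- 0L
  log$N_div <- 0L
  log$events <- list()
  log$divisions <- list()
  class(log) <- "event_log"
  log
}

.log_event <- function(log, time, cell, kind, n_basal, context = NA_character_) {
  log$events[[length(log$events) + 1L]] <-
    data.frame(time = time, cell = cell, kind = kind, n_basal = n_basal,
               context = context, stringsAsFactors = FALSE)
  if (kind == "homotypic") log$N_homo <- log$N_homo + 1L
  if (kind == "fate") log$N_fate <- log$N_fate + 1L
  invisible(log)
}

#' Event table of a log
#' @param log an `event_log`.
#' @return data frame with one row per stratification event.
#' @export
event_table <- function(log) {
  if (length(log$events) == 0)
    return(data.frame(time = numeric(0), cell = integer(0),
                      kind = character(0), n_basal = integer(0),
                      context = character(0), stringsAsFactors = FALSE))
  do.call(rbind, log$events)
}

#' Division-event table of a log
#' @param log an `event_log`.
#' @return data frame with one row per division.
#' @export
division_table <- function(log) {
  if (length(log$divisions) == 0)
    return(data.frame(time = numeric(0), parent = integer(0), d1 = integer(0),
                      d2 = integer(0), theta = numeric(0), phi = numeric(0)))
  do.call(rbind, lapply(log$divisions, function(e)
    data.frame(time = e$time, parent = e$parent, d1 = e$d1, d2 = e$d2,
               theta = e$theta, phi = e$phi)))
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> protocol=", x$protocol, " t_pop=", x$t_pop, "\n", sep = "")
  cat("  N_homo=", x$N_homo, " N_fate=", x$N_fate, " N_div=", x$N_div, "\n",
      sep = "")
  invisible(x)
}

#' Basal-suprabasal interface height
#'
#' Mean z position of the centroids of all faces shared between basal and
#' suprabasal cells.
#'
#' @param tissue a `vm_tissue`.
#' @return interface height (scalar).
#' @export
compute_bs_interface <- function(tissue) {
  code <- .type_code(tissue$cells$type)
  fc <- tissue$face_cells
  internal <- fc[, 1] > 0 & fc[, 2] > 0
  t1 <- ifelse(internal, code[pmax(fc[, 1], 1)], 0L)
  t2 <- ifelse(internal, code[pmax(fc[, 2], 1)], 0L)
  bs <- which(internal & ((t1 == 2 & t2 == 3) | (t1 == 3 & t2 == 2)))
  if (length(bs) == 0) stop("no basal-suprabasal shared faces")
  mean(face_centroids(tissue, bs)[, 3])
}

#' Detect spontaneously stratifying basal cells
#'
#' A basal cell stratifies homotypically when its centroid lies above the
#' basal-suprabasal interface AND it no longer shares a face with any
#' basement cell.
#'
#' @param tissue a `vm_tissue`.
#' @param interface interface height from [compute_bs_interface()].
#' @return integer vector of stratifying cell ids (may be empty).
#' @export
detect_homotypic <- function(tissue, interface = compute_bs_interface(tissue)) {
  geo <- tissue_metrics(tissue)
  code <- .type_code(tissue$cells$type)
  basal <- which(code == 2L)
  if (length(basal) == 0) return(integer(0))
  adj <- cell_adjacency(tissue)
  touches_bm <- rep(FALSE, nrow(tissue$cells))
  bm_edges <- code[adj[, 1]] == 1L | code[adj[, 2]] == 1L
  touches_bm[adj[bm_edges, 1]] <- TRUE
  touches_bm[adj[bm_edges, 2]] <- TRUE
  hit <- basal[geo$centroid[basal, 3] > interface & !touches_bm[basal]]
  tissue$cells$id[hit]
}

#' Switch a cell's mechanical identity to suprabasal
#'
#' @param tissue a `vm_tissue`.
#' @param cell_id cell to convert.
#' @param params a `vm_params` (source of the suprabasal targets).
#' @return the updated tissue.
#' @export
switch_to_suprabasal <- function(tissue, cell_id, params) {
  row <- match(cell_id, tissue$cells$id)
  if (is.na(row)) stop("no cell with id ", cell_id)
  if (tissue$cells$type[row] != "basal") stop("only basal cells stratify")
  tissue$cells$type[row] <- "suprabasal"
  tissue$cells$s0[row] <- unname(params$s0["suprabasal"])
  tissue$cells$S0[row] <- tissue$cells$s0[row] * tissue$cells$V0[row]^(2 / 3)
  tissue$cells$alpha[row] <- 0
  tissue
}

#' Convert the top-most suprabasal cell into a ghost cell
#'
#' Pairs each stratification event with the removal (ghost conversion) of a
#' suprabasal cell at the apical surface, preserving a quasi-steady tissue
#' height.  Ghost cells keep their topology but drop out of all energy and
#' force sums.  Ties in centroid height break by cell id.
#'
#' @param tissue a `vm_tissue`.
#' @return the updated tissue.
#' @export
ghost_convert_top <- function(tissue) {
  sup <- which(tissue$cells$type == "suprabasal")
  if (length(sup) == 0) stop("no suprabasal cell available for ghost conversion")
  geo <- tissue_metrics(tissue)
  z <- geo$centroid[sup, 3]
  ord <- order(-z, tissue$cells$id[sup])
  row <- sup[ord[1]]
  tissue$cells$type[row] <- "ghost"
  tissue$cells$s0[row] <- 0
  tissue$cells$alpha[row] <- 0
  tissue
}

#' Homeostatic density check
#'
#' At multiples of `t_pop` the basal count is compared with its initial
#' reference; whenever it has expanded by more than two cells, one uniformly
#' random basal cell is converted to suprabasal identity (fate event).
#'
#' @param tissue a `vm_tissue`.
#' @param log an `event_log` (protocol must be `"homeostatic"`).
#' @param params a `vm_params`.
#' @param time current time (for logging).
#' @return list of updated `tissue` and `converted` (id or `NULL`).
#' @export
homeostatic_check <- function(tissue, log, params, time = tissue$time) {
  if (log$protocol != "homeostatic") return(list(tissue = tissue, converted = NULL))
  basal <- which(tissue$cells$type == "basal")
  if (length(basal) - log$n_basal0 <= 2) return(list(tissue = tissue, converted = NULL))
  pick <- basal[sample.int(length(basal), 1)]
  id <- tissue$cells$id[pick]
  tissue <- switch_to_suprabasal(tissue, id, params)
  .log_event(log, time, id, "fate", sum(tissue$cells$type == "basal"))
  tissue <- ghost_convert_top(tissue)
  list(tissue = tissue, converted = id)
}

#' Stratification yield fractions
#'
#' Event counts normalized by the number of divisions, for comparison across
#' division rates.  Under homeostasis the two fractions sum to about 1 at
#' steady state.
#'
#' @param log an `event_log` with `N_div > 0`.
#' @return named vector `c(homo = N_homo/N_div, fate = N_fate/N_div)`.
#' @export
stratification_yield <- function(log) {
  if (log$N_div == 0) return(c(homo = NA_real_, fate = NA_real_))
  c(homo = log$N_homo / log$N_div, fate = log$N_fate / log$N_div)
}
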