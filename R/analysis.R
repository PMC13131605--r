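#' Long-axis orientation distribution
#'
#' Histograms orientation angles measured on \[0, pi/2\], mirrors the
#' distribution about pi/2 to extend over \[0, pi\], normalizes it to unit
#' integral, and divides by the 3D isotropic reference `P_iso(theta) =
#' sin(theta)/2`.  Summary metrics are taken on the `P/P_iso` curve: the peak
#' normalized probability, the anisotropy ratio (max/min) and the full width
#' at half maximum around the global peak (linear interpolation between
#' bins).
#'
#' @param theta_samples angles in \[0, pi/2\] (radians).
#' @param n_bins number of bins on \[0, pi/2\] (the mirrored curve has twice
#'   as many).
#' @return an `angle_distribution` list with the binned curves and `metrics`.
#' @export
long_axis_distribution <- function(theta_samples, n_bins = 9) {
  theta_samples <- theta_samples[is.finite(theta_samples)]
  if (length(theta_samples) == 0) stop("no orientation samples")
  if (any(theta_samples < -1e-9 | theta_samples > pi / 2 + 1e-9))
    stop("samples must lie in [0, pi/2]")
  mirrored <- c(theta_samples, pi - theta_samples)
  edges <- seq(0, pi, length.out = 2 * n_bins + 1)
  counts <- tabulate(pmin(findInterval(mirrored, edges,
                                       rightmost.closed = TRUE), 2 * n_bins),
                     nbins = 2 * n_bins)
  width <- edges[2] - edges[1]
  P <- counts / (sum(counts) * width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  P_iso <- sin(mids) / 2
  ratio <- P / P_iso
  metrics <- c(peak = max(ratio), anisotropy_ratio = max(ratio) / min(ratio),
               fwhm = .fwhm(mids, ratio))
  structure(list(edges = edges, mids = mids, P = P, P_iso = P_iso,
                 ratio = ratio, metrics = metrics),
            class = "angle_distribution")
}

# full width at half maximum of a binned curve around its global peak,
# with linear interpolation between bin midpoints
.fwhm <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  left <- x[1]
  if (i > 1) {
    for (k in seq(i, 2)) {
      if (y[k - 1] <= half) {
        left <- x[k - 1] + (x[k] - x[k - 1]) * (half - y[k - 1]) /
          (y[k] - y[k - 1])
        break
      }
    }
  }
  right <- x[length(x)]
  if (i < length(y)) {
    for (k in seq(i, length(y) - 1)) {
      if (y[k + 1] <= half) {
        right <- x[k] + (x[k + 1] - x[k]) * (y[k] - half) / (y[k] - y[k + 1])
        break
      }
    }
  }
  right - left
}

#' Division-angle bin classification
#'
#' Bins exactly as printed: planar `[0, pi/6]`, oblique `(pi/6, pi/3]`,
#' perpendicular `(pi/3, pi/2]` (only the planar bin is left-closed).
#'
#' @param theta angle(s) in \[0, pi/2\].
#' @return character vector of bin labels.
#' @export
classify_division_angle <- function(theta) {
  if (any(theta < 0 | theta > pi / 2 + 1e-12))
    stop("theta out of [0, pi/2]")
  ifelse(theta <= pi / 6, "planar",
         ifelse(theta <= pi / 3, "oblique", "perpendicular"))
}

#' Observed division-angle fractions by developmental stage
#'
#' Estimated fractions of planar/oblique/perpendicular divisions: E14 about
#' (0.20, 0.25, 0.55) and E16 (with stages >= E15) about (0.60, 0.25, 0.15).
#'
#' @param stage `"E14"` or `"E16"`.
#' @return named numeric vector of fractions.
#' @export
stage_division_fractions <- function(stage = c("E14", "E16")) {
  stage <- match.arg(stage)
  if (stage == "E14") c(planar = 0.20, oblique = 0.25, perpendicular = 0.55)
  else c(planar = 0.60, oblique = 0.25, perpendicular = 0.15)
}

#' Normalized division-angle weights
#'
#' `W_i = f_i / sum(f_i)`; the weights sum to 1 exactly.
#'
#' @param fractions nonnegative fractions per angular bin (named or not).
#' @return a `division_angle_weights` vector.
#' @export
division_angle_weights <- function(fractions) {
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  s <- sum(fractions)
  if (s == 0) stop("all-zero fractions")
  structure(fractions / s, class = "division_angle_weights")
}

#' Daughter-separation squared after division
#'
#' For each division event the instantaneous separation vector is
#' `s(t) = r_d1(t) - r_d2(t)` (minimal image, unwrapped in time); the change
#' `ds(t) = s(t) - s(t0)` filters out global tissue motion, and
#' `dd2(t) = |ds(t)|^2` is reported per event as a function of time since
#' division.  Pairs are censored once either daughter leaves the basal
#' layer; there is no averaging over time windows.
#'
#' @param events division table (columns `time`, `d1`, `d2`; see
#'   [division_table()]).
#' @param trajectories data frame of centroid trajectories with columns
#'   `time`, `cell`, `type`, `x`, `y`, `z`.
#' @param box the tissue `box` vector (for minimal-image unwrapping).
#' @return data frame with columns `event`, `t` (time since division), `dd2`.
#' @export
daughter_separation <- function(events, trajectories, box) {
  L <- c(box[1], box[2], if (box[5] != 0) box[4] - box[3] else Inf)
  out <- list()
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    tr1 <- trajectories[trajectories$cell == e$d1 & trajectories$time >= e$time, ]
    tr2 <- trajectories[trajectories$cell == e$d2 & trajectories$time >= e$time, ]
    tt <- intersect(tr1$time, tr2$time)
    if (length(tt) == 0) next
    tt <- sort(tt)
    tr1 <- tr1[match(tt, tr1$time), ]
    tr2 <- tr2[match(tt, tr2$time), ]
    keep_basal <- tr1$type == "basal" & tr2$type == "basal"
    cut <- which(!keep_basal)
    if (length(cut)) {
      if (cut[1] == 1) next
      idx <- seq_len(cut[1] - 1)
      tt <- tt[idx]; tr1 <- tr1[idx, ]; tr2 <- tr2[idx, ]
    }
    s <- cbind(tr1$x - tr2$x, tr1$y - tr2$y, tr1$z - tr2$z)
    # minimal image of the first sample, then unwrap in time
    for (d in 1:2) s[1, d] <- s[1, d] - L[d] * round(s[1, d] / L[d])
    if (nrow(s) > 1) {
      for (k in 2:nrow(s)) {
        for (d in 1:3) {
          if (is.finite(L[d]))
            s[k, d] <- s[k, d] - L[d] * round((s[k, d] - s[k - 1, d]) / L[d])
        }
      }
    }
    ds <- sweep(s, 2, s[1, ])
    out[[length(out) + 1L]] <- data.frame(event = i, t = tt - e$time,
                                          dd2 = rowSums(ds^2))
  }
  if (length(out) == 0)
    return(data.frame(event = integer(0), t = numeric(0), dd2 = numeric(0)))
  do.call(rbind, out)
}

#' Bin a per-event trace with subgroup bootstrap errors
#'
#' Bins the samples into time intervals of width `bin_width`; the per-bin
#' mean is taken over all samples while the uncertainty comes from splitting
#' the events into `n_subgroups` independent subgroups: the error is the
#' standard deviation of the subgroup means divided by the square root of
#' the number of subgroups.
#'
#' @param trace data frame with columns `event`, `t`, and a value column.
#' @param bin_width time-bin width (tau).
#' @param n_subgroups number of subgroups the events are split into.
#' @param value name of the value column (default `"dd2"`).
#' @return data frame with `t` (bin centre), `mean`, `error`, `n`.
#' @export
bin_with_bootstrap <- function(trace, bin_width = 5, n_subgroups = 5,
                               value = "dd2") {
  ev <- sort(unique(trace$event))
  if (length(ev) %% n_subgroups != 0)
    stop("number of events (", length(ev), ") not divisible by n_subgroups (",
         n_subgroups, ")")
  grp <- setNames(rep(seq_len(n_subgroups), each = length(ev) / n_subgroups),
                  ev)
  bin <- floor(trace$t / bin_width)
  v <- trace[[value]]
  agg <- aggregate(v, list(bin = bin), mean)
  sub <- aggregate(v, list(bin = bin, grp = grp[as.character(trace$event)]),
                   mean)
  err <- vapply(agg$bin, function(b) {
    m <- sub$x[sub$bin == b]
    if (length(m) < 2) return(NA_real_)
    sd(m) / sqrt(n_subgroups)
  }, numeric(1))
  nb <- vapply(agg$bin, function(b) sum(bin == b), numeric(1))
  data.frame(t = (agg$bin + 0.5) * bin_width, mean = agg$x, error = err,
             n = nb)
}

#' Effective diffusion coefficient from a linear fit
#'
#' `dd2(t) ~ D t`: `D` is the raw slope of an unweighted linear fit on the
#' window (no dimensional prefactor).  When the unbinned trace is supplied,
#' the uncertainty is the standard deviation of per-subgroup slopes.
#'
#' @param binned output of [bin_with_bootstrap()] (columns `t`, `mean`).
#' @param window `c(tmin, tmax)` fit window; default the late 40% of the
#'   trace.
#' @param trace optional raw trace for subgroup errors.
#' @param n_subgroups subgroups for the uncertainty.
#' @return list with `D`, `D_error` (NA without `trace`), `window`.
#' @export
fit_diffusion <- function(binned, window = NULL, trace = NULL,
                          n_subgroups = 5) {
  if (is.null(window)) {
    tmax <- max(binned$t)
    window <- c(0.6 * tmax, tmax)
  }
  sel <- binned$t >= window[1] & binned$t <= window[2] & is.finite(binned$mean)
  if (sum(sel) < 3) stop("fewer than 3 bins in the fit window")
  D <- unname(coef(lm(mean ~ t, data = binned[sel, ]))[2])
  D_err <- NA_real_
  if (!is.null(trace)) {
    ev <- sort(unique(trace$event))
    if (length(ev) %% n_subgroups == 0) {
      grp <- setNames(rep(seq_len(n_subgroups), each = length(ev) / n_subgroups),
                      ev)
      slopes <- vapply(seq_len(n_subgroups), function(g) {
        sub <- trace[grp[as.character(trace$event)] == g, ]
        bw <- if (nrow(binned) > 1) binned$t[2] - binned$t[1] else 5
        b <- aggregate(sub$dd2, list(bin = floor(sub$t / bw)), mean)
        b$t <- (b$bin + 0.5) * bw
        s <- b$t >= window[1] & b$t <= window[2]
        if (sum(s) < 3) return(NA_real_)
        unname(coef(lm(x ~ t, data = b[s, ]))[2])
      }, numeric(1))
      D_err <- sd(slopes[is.finite(slopes)])
    }
  }
  list(D = D, D_error = D_err, window = window)
}

#' Orientation-weighted average
#'
#' `<X> = sum_theta W(theta) X(theta)` using the stage's division-angle
#' weights; the spread is the (unweighted) standard deviation of the mean
#' over the orientation angles.
#'
#' @param values_by_angle named numeric vector (one value per weighted bin).
#' @param weights a [division_angle_weights()] vector.
#' @return list with `mean` and `spread`.
#' @export
orientation_weighted_average <- function(values_by_angle, weights) {
  w <- unclass(weights)
  if (!is.null(names(w)) && !is.null(names(values_by_angle)))
    values_by_angle <- values_by_angle[names(w)]
  if (length(values_by_angle) != length(w) || anyNA(values_by_angle))
    stop("a value is required for every weighted bin")
  list(mean = sum(w * values_by_angle),
       spread = sd(values_by_angle) / sqrt(length(values_by_angle)))
}

#' Scaling exponent of a separation trace
#'
#' Slope of `log dd2` vs `log t` on the window; classifies the dynamics as
#' subdiffusive, diffusive or superdiffusive by configurable thresholds.
#'
#' @param binned output of [bin_with_bootstrap()].
#' @param window `c(tmin, tmax)`; default the late 40%.
#' @param thresholds `c(sub, super)` classification cutoffs.
#' @return list with `exponent` and `regime`.
#' @export
msd_exponent <- function(binned, window = NULL, thresholds = c(0.8, 1.2)) {
  if (is.null(window)) {
    tmax <- max(binned$t)
    window <- c(0.6 * tmax, tmax)
  }
  sel <- binned$t >= window[1] & binned$t <= window[2] &
    is.finite(binned$mean) & binned$mean > 0 & binned$t > 0
  if (sum(sel) < 3) stop("fewer than 3 positive bins in the window")
  fit <- lm(log(mean) ~ log(t), data = binned[sel, ])
  ex <- unname(coef(fit)[2])
  regime <- if (ex < thresholds[1]) "subdiffusive"
            else if (ex > thresholds[2]) "superdiffusive" else "diffusive"
  list(exponent = ex, regime = regime)
}
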