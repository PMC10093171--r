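# Compactness profile machinery: concentric-ring binning in
# direction-normalised radius, 4-parameter logistic profile fits, and the
# 60-sector radial summary (RP, RS, RPSD, RSSD).

# Polar description of the filled section around a centre: for every interior
# pixel, its radius, angle and the boundary radius along its direction
# (max pixel radius within a fine angular bin). Normalised radius is
# r / R(theta), so it lives in [0, 1] regardless of section eccentricity.
polar_pixels <- function(s, centre, n_dir = 720L) {
  interior <- section_interior(s)
  idx <- which(interior$filled, arr.ind = TRUE)
  dy <- idx[, 1] - centre[["row"]]
  dx <- idx[, 2] - centre[["col"]]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)                      # [-pi, pi]
  dir_bin <- pmin(floor((theta + pi) / (2 * pi) * n_dir) + 1L, n_dir)
  r_max <- rep(NA_real_, n_dir)
  agg <- tapply(r, dir_bin, max)
  r_max[as.integer(names(agg))] <- agg
  # circular fill of empty direction bins (tiny medulla-adjacent gaps)
  if (anyNA(r_max)) {
    ok <- which(!is.na(r_max))
    for (b in which(is.na(r_max))) {
      d <- pmin(abs(ok - b), n_dir - abs(ok - b))
      r_max[b] <- r_max[ok[which.min(d)]]
    }
  }
  rnorm <- pmin(r / pmax(r_max[dir_bin], .Machine$double.eps), 1 - 1e-9)
  list(bone = s$mask[interior$filled], r = r, theta = theta,
       rnorm = rnorm, n_interior = nrow(idx))
}

#' Concentric-ring compactness profile
#'
#' Assigns every pixel enclosed by the outer boundary a normalised radius
#' (distance from the medullary centre divided by the distance from the
#' centre to the outer boundary along the pixel's direction) and bins it into
#' `n_rings` equal-width rings. Per-ring compactness is the fraction of bone
#' pixels in the ring. Rings with no pixels (possible very close to the
#' centre) are reported with count 0 and `NA` compactness and are excluded
#' from profile fitting.
#'
#' @param s a `section_image`.
#' @param centre medullary centre as returned by [medullary_centre()]
#'   (the `centre` element); defaults to computing it.
#' @param n_rings number of concentric rings (default 100).
#' @return list of class `ring_profile` with `mids` (ring mid radii),
#'   `compactness`, `counts`.
#' @export
ring_profile <- function(s, centre = NULL, n_rings = 100L) {
  stopifnot(inherits(s, "section_image"))
  if (is.null(centre)) centre <- medullary_centre(s)$centre
  pp <- polar_pixels(s, centre)
  ring_profile_from_polar(pp, n_rings)
}

ring_profile_from_polar <- function(pp, n_rings = 100L, subset = NULL) {
  rnorm <- pp$rnorm
  bone <- pp$bone
  if (!is.null(subset)) {
    rnorm <- rnorm[subset]
    bone <- bone[subset]
  }
  ring <- pmin(floor(rnorm * n_rings) + 1L, n_rings)
  counts <- tabulate(ring, nbins = n_rings)
  bone_in <- rep(0, n_rings)
  agg <- tapply(bone, ring, sum)
  bone_in[as.integer(names(agg))] <- agg
  comp <- ifelse(counts > 0, bone_in / counts, NA_real_)
  structure(list(mids = (seq_len(n_rings) - 0.5) / n_rings,
                 compactness = comp, counts = counts),
            class = "ring_profile")
}

# The compactness profile model: a 4-parameter logistic in normalised radius.
# Min and Max are the asymptotic compactness levels, P the inflection radius
# and S the transition scale (reciprocal-slope parameterisation: the tangent
# slope at P is (Max - Min) / (4 S)).
sigmoid_model <- function(r, min_, max_, p, s) {
  min_ + (max_ - min_) / (1 + exp((p - r) / s))
}

S_FLOOR <- 1e-4

#' Fit the sigmoid compactness-profile model
#'
#' Bounded weighted least squares fit of
#' `C(r) = Min + (Max - Min) / (1 + exp((P - r)/S))` to a ring profile,
#' with weights proportional to ring pixel counts. Five deterministic
#' multi-starts (P in 0.1..0.9) guard against local minima on abrupt
#' transitions; bounds are `0 <= Min <= Max <= 1`, `0 <= P <= 1`,
#' `S >= 1e-4`. A profile whose non-missing values are all (numerically)
#' equal is degenerate: the fit returns `Min = Max = level`, `P = 0`,
#' `S` at its floor and `converged = FALSE`, and downstream consumers treat
#' its `P` as missing.
#'
#' @param profile a `ring_profile`.
#' @return list of class `sigmoid_fit` with elements `Min`, `Max`, `P`, `S`,
#'   `converged`, `sse`.
#' @export
fit_sigmoid <- function(profile) {
  ok <- !is.na(profile$compactness)
  if (sum(ok) < 4L) {
    return(structure(list(Min = NA_real_, Max = NA_real_, P = NA_real_,
                          S = NA_real_, converged = FALSE, sse = NA_real_),
                     class = "sigmoid_fit"))
  }
  r <- profile$mids[ok]
  y <- profile$compactness[ok]
  w <- profile$counts[ok]
  w <- w / mean(w)
  if (diff(range(y)) < 1e-9) {
    return(structure(list(Min = y[1], Max = y[1], P = 0, S = S_FLOOR,
                          converged = FALSE, sse = 0),
                     class = "sigmoid_fit"))
  }
  obj <- function(par) {
    sum(w * (y - sigmoid_model(r, par[1], par[2], par[3], par[4]))^2)
  }
  lower <- c(0, 0, 0, S_FLOOR)
  upper <- c(1, 1, 1, 5)
  best <- NULL
  for (p0 in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    start <- c(max(min(y), 0), min(max(y), 1), p0, 0.05)
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(Min = NA_real_, Max = NA_real_, P = NA_real_,
                          S = NA_real_, converged = FALSE, sse = NA_real_),
                     class = "sigmoid_fit"))
  }
  par <- best$par
  # enforce Min <= Max (the logistic is symmetric under (Min,Max,S) sign flips)
  if (par[1] > par[2]) {
    par <- c(par[2], par[1], par[3], par[4])
  }
  # code 52 (abnormal line-search termination) occurs when a parameter sits
  # on its bound (e.g. S at its floor for a step profile) and no further
  # improvement is possible: the minimiser has effectively converged.
  conv <- best$convergence %in% c(0L, 52L) && is.finite(best$value)
  structure(list(Min = par[1], Max = par[2], P = par[3], S = par[4],
                 converged = conv, sse = best$value),
            class = "sigmoid_fit")
}

#' Measure all compactness parameters of a section
#'
#' Computes the observed global compactness `C_obs` (bone pixels over all
#' pixels enclosed by the outer boundary), the global sigmoid profile fit
#' (parameters `P` and `S`), and the radial summary obtained by fitting the
#' profile independently in each of 60 sectors of 6 degrees around the
#' medullary centre: `RP`/`RS` are the means and `RPSD`/`RSSD` the sample
#' standard deviations of the per-sector `P` and `S` over sectors whose fits
#' converged (degenerate or non-converged sector fits are excluded, not
#' imputed). Fewer than 30 valid sectors triggers a low-confidence warning.
#'
#' @param s a `section_image`.
#' @param n_rings rings per profile (default 100).
#' @param n_sectors number of angular sectors (default 60).
#' @param radial if `FALSE`, skip the 60 per-sector fits (RP/RS/RPSD/RSSD
#'   come back `NA`); the global profile fit alone is much cheaper.
#' @param centre optional centre override (row/col); by default the
#'   medullary centroid from [medullary_centre()]. A strongly asymmetric
#'   medulla pulls its centroid off the section centre, which is the
#'   behaviour wanted on real bone; generator-truth comparisons can pin the
#'   centre instead.
#' @return list of class `compactness_set`: `C_obs`, `fit` (global
#'   `sigmoid_fit`), `P`, `S`, `RP`, `RS`, `RPSD`, `RSSD`,
#'   `n_valid_sectors`, `centre`, `degenerate_centre`.
#' @export
measure_compactness <- function(s, n_rings = 100L, n_sectors = 60L,
                                radial = TRUE, centre = NULL) {
  stopifnot(inherits(s, "section_image"))
  mc <- medullary_centre(s)
  if (!is.null(centre)) {
    mc$centre <- c(row = centre[[1]], col = centre[[2]])
  }
  pp <- polar_pixels(s, mc$centre)
  c_obs <- sum(pp$bone) / pp$n_interior
  global <- fit_sigmoid(ring_profile_from_polar(pp, n_rings))
  ps <- matrix(NA_real_, n_sectors, 2L)
  if (radial) {
    sector <- pmin(floor((pp$theta + pi) / (2 * pi) * n_sectors) + 1L,
                   n_sectors)
    for (k in seq_len(n_sectors)) {
      sel <- sector == k
      if (sum(sel) < 4L) next
      f <- fit_sigmoid(ring_profile_from_polar(pp, n_rings, subset = sel))
      if (isTRUE(f$converged)) ps[k, ] <- c(f$P, f$S)
    }
  }
  valid <- !is.na(ps[, 1])
  if (radial && sum(valid) < 30L) {
    warning("fewer than 30 valid sectors (", sum(valid),
            "): radial summary is low-confidence")
  }
  structure(list(
    C_obs = c_obs,
    fit = global,
    P = if (isTRUE(global$converged)) global$P else NA_real_,
    S = if (isTRUE(global$converged)) global$S else NA_real_,
    RP = if (any(valid)) mean(ps[valid, 1]) else NA_real_,
    RS = if (any(valid)) mean(ps[valid, 2]) else NA_real_,
    RPSD = if (sum(valid) > 1) stats::sd(ps[valid, 1]) else NA_real_,
    RSSD = if (sum(valid) > 1) stats::sd(ps[valid, 2]) else NA_real_,
    n_valid_sectors = sum(valid),
    centre = mc$centre,
    degenerate_centre = mc$degenerate
  ), class = "compactness_set")
}

#' Tabulate a section's compactness profile with its fitted curve
#'
#' Convenience dump of the global ring profile and the fitted sigmoid,
#' one row per ring: ring index, mid radius, pixel count, observed and
#' fitted compactness. Suitable for writing to CSV or plotting a
#' compactness-profile figure.
#'
#' @param s a `section_image`.
#' @param n_rings rings (default 100).
#' @return a `data.frame` with columns `ring`, `mid_radius`, `count`,
#'   `compactness`, `fitted`.
#' @export
profile_table <- function(s, n_rings = 100L) {
  pr <- ring_profile(s, n_rings = n_rings)
  fit <- fit_sigmoid(pr)
  fitted <- if (is.na(fit$P)) rep(NA_real_, n_rings) else
    sigmoid_model(pr$mids, fit$Min, fit$Max, fit$P, fit$S)
  data.frame(ring = seq_len(n_rings), mid_radius = pr$mids,
             count = pr$counts, compactness = pr$compactness,
             fitted = fitted)
}
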