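curve_xy <- function(x, y = NULL, condition = "drug") {
  if (is.null(y)) {
    stopifnot(is.data.frame(x),
              all(c("sweep_value", "relative_current") %in% names(x)))
    if ("condition" %in% names(x) && length(unique(x$condition)) > 1) {
      x <- x[x$condition == condition, ]
    }
    list(x = x$sweep_value, y = x$relative_current)
  } else {
    list(x = x, y = y)
  }
}

#' Boltzmann fit of an availability curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + exp((V - Vhalf)
#' / slope))` to an availability-versus-voltage curve (decreasing with
#' depolarization for `slope > 0`). If the curve has no transition in range
#' (dynamic range below `min_range`), the midpoint is undefined and the fit
#' is reported as such rather than failing.
#'
#' @param x A `sweep_result` (the `"drug"` condition is used when both are
#'   present; subset first for the control fit) or a numeric vector of
#'   voltages (mV).
#' @param y Availability values when `x` is a vector.
#' @param condition Which condition to fit when `x` holds both.
#' @param min_range Minimum dynamic range for a defined fit.
#' @return An object of class `boltzmann_fit` with elements `Vhalf`,
#'   `slope`, `top`, `bottom`, `residual` (residual norm) and `undefined`.
#' @export
fit_boltzmann <- function(x, y = NULL, condition = "drug", min_range = 0.2) {
  d <- curve_xy(x, y, condition)
  if (length(d$x) < 6) stop("need at least 6 points", call. = FALSE)
  rng <- max(d$y) - min(d$y)
  if (rng < min_range) {
    return(structure(list(Vhalf = NA_real_, slope = NA_real_,
                          top = max(d$y), bottom = min(d$y),
                          residual = NA_real_, undefined = TRUE,
                          data = d),
                     class = "boltzmann_fit"))
  }
  df <- data.frame(v = d$x, y = d$y)
  mid <- (max(d$y) + min(d$y)) / 2
  v0 <- d$x[which.min(abs(d$y - mid))]
  best <- NULL
  for (k0 in c(3, 6, 10, 15, 20)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp((v - Vhalf) / slope)),
        data = df,
        start = list(bottom = min(d$y), top = max(d$y), Vhalf = v0,
                     slope = k0),
        lower = c(bottom = -0.5, top = 0, Vhalf = min(d$x) - 50,
                  slope = 0.1),
        upper = c(bottom = 1, top = 1.5, Vhalf = max(d$x) + 50,
                  slope = 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Boltzmann fit failed to converge", call. = FALSE)
  cf <- stats::coef(best$fit)
  structure(list(Vhalf = unname(cf["Vhalf"]), slope = unname(cf["slope"]),
                 top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 residual = sqrt(best$rss), undefined = FALSE, data = d),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$undefined) {
    cat("<boltzmann_fit> undefined (no transition in range)\n")
  } else {
    cat(sprintf("<boltzmann_fit> Vhalf = %.2f mV, slope = %.2f mV, top = %.3f, bottom = %.3f\n",
                x$Vhalf, x$slope, x$top, x$bottom))
  }
  invisible(x)
}

#' Biexponential fit of a recovery curve
#'
#' Fits `y = 1 - A_fast * exp(-t / tau_fast) - A_slow * exp(-t / tau_slow)`
#' (shared asymptote 1) to availability versus recovery-gap duration.
#' Time constants are optimized on the log scale from five deterministic
#' starting points to avoid local minima. Essentially single-exponential
#' data are flagged via a vanishing slow amplitude.
#'
#' @param x A `sweep_result` over time (gap duration) or a numeric time
#'   vector, s.
#' @param y Availability values when `x` is a vector.
#' @param condition Condition to fit when both are present.
#' @return An object of class `biexp_fit`: `tau_fast`, `tau_slow` (s),
#'   `amp_fast`, `amp_slow`, `residual`, `single_exponential`.
#' @export
fit_biexponential <- function(x, y = NULL, condition = "drug") {
  d <- curve_xy(x, y, condition)
  stopifnot(length(d$x) >= 6, all(d$x > 0))
  df <- data.frame(t = d$x, y = d$y)
  span <- range(d$x)
  # deterministic multi-start: tau pairs spread over the observed time span
  starts <- list(
    c(lf = log(span[1] * 3), ls = log(span[2] / 3)),
    c(lf = log(sqrt(prod(span)) / 10), ls = log(sqrt(prod(span)) * 10)),
    c(lf = log(span[1] * 10), ls = log(span[2] / 30)),
    c(lf = log(span[1] * 30), ls = log(span[2] / 10)),
    c(lf = log(sqrt(prod(span)) / 3), ls = log(sqrt(prod(span)) * 3)))
  a0 <- max(0.05, min(0.95, 1 - min(d$y)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ 1 - af * exp(-t / exp(lf)) - as * exp(-t / exp(ls)),
        data = df,
        start = list(af = a0 / 2, as = a0 / 2, lf = s[["lf"]],
                     ls = s[["ls"]]),
        lower = c(af = 0, as = 0, lf = log(span[1] / 100),
                  ls = log(span[1] / 100)),
        upper = c(af = 1.5, as = 1.5, lf = log(span[2] * 100),
                  ls = log(span[2] * 100)),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("biexponential fit failed to converge",
                          call. = FALSE)
  cf <- stats::coef(best$fit)
  tau <- exp(c(cf[["lf"]], cf[["ls"]]))
  amp <- c(cf[["af"]], cf[["as"]])
  ord <- order(tau)
  structure(list(tau_fast = tau[ord[1]], tau_slow = tau[ord[2]],
                 amp_fast = amp[ord[1]], amp_slow = amp[ord[2]],
                 residual = sqrt(best$rss),
                 single_exponential = min(amp) < 1e-3, data = d),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> tau_fast = %.4g ms (amp %.3f), tau_slow = %.4g ms (amp %.3f)%s\n",
              1e3 * x$tau_fast, x$amp_fast, 1e3 * x$tau_slow, x$amp_slow,
              if (x$single_exponential) " [single-exponential]" else ""))
  invisible(x)
}

#' Normalized sum of differences between control and drug curves
#'
#' `nSOD = sum(control - drug) / sum(control)`, clipped to `[0, 1]`.
#' On a log-evenly spaced sweep grid the raw sum of differences (SOD) is
#' proportional to the area between the two curves on a semilogarithmic
#' plot. The statistic is 0 for a drug with no effect and 1 when the
#' current is completely abolished.
#'
#' @param control A `sweep_result` containing both conditions, or the
#'   control curve values.
#' @param drug Drug curve values when `control` is a vector (grids must
#'   match).
#' @return A single number in `[0, 1]`.
#' @export
nsod <- function(control, drug = NULL) {
  if (is.data.frame(control) && is.null(drug)) {
    res <- control
    c_rows <- res[res$condition == "control", ]
    d_rows <- res[res$condition == "drug", ]
    if (!nrow(d_rows)) stop("sweep result has no drug condition",
                            call. = FALSE)
    if (!isTRUE(all.equal(c_rows$sweep_value, d_rows$sweep_value))) {
      stop("control and drug sweep grids differ", call. = FALSE)
    }
    control <- c_rows$relative_current
    drug <- d_rows$relative_current
  }
  if (length(control) != length(drug)) {
    stop("control and drug curves have different lengths", call. = FALSE)
  }
  min(1, max(0, sum(control - drug) / sum(control)))
}

#' Half-maximal inhibitory concentration by bisection
#'
#' Finds the concentration at which a single depolarization from the given
#' holding potential is inhibited by 50%, by bisection on the log
#' concentration axis to a relative tolerance. Inhibition is monotone in
#' concentration for the models built here, so bisection is exact up to the
#' tolerance.
#'
#' @param model Drug-free `channel_model`.
#' @param drug [drug_spec()] template.
#' @param holding Holding potential, mV (-90 mV is the reference condition
#'   used to scale the 100-drug grid).
#' @param interval Bracketing concentration interval, uM.
#' @param tol Relative tolerance on the concentration.
#' @return Concentration, uM.
#' @export
ic50 <- function(model, drug, holding = -90, interval = c(1e-3, 1e5),
                 tol = 0.01) {
  f <- function(conc) {
    concentration_response(model, drug, holding, conc)$inhibition - 0.5
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    stop("50% inhibition not bracketed within the concentration interval",
         call. = FALSE)
  }
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Drug effect on slow-inactivation onset as a function of gap duration
#'
#' Re-runs the slow-inactivation-onset protocol (`SInact_t`) with a range of
#' hyperpolarizing-gap durations and quantifies the drug effect at each gap
#' as the sum of differences (area between control and drug curves on the
#' semilogarithmic plot) and its normalized version.
#'
#' @param model Drug-free `channel_model`.
#' @param drug [drug_spec()].
#' @param gaps Gap durations, s.
#' @param ... Passed to [standard_protocol()].
#' @return Tibble with columns `gap`, `sod`, `nsod`.
#' @export
gap_duration_curve <- function(model, drug,
                               gaps = log_grid(1e-3, 10, 4), ...) {
  purrr::map_dfr(gaps, function(g) {
    res <- run_sweep(model, standard_protocol("SInact_t", gap_duration = g,
                                              ...), drug = drug)
    ctrl <- res$relative_current[res$condition == "control"]
    drg <- res$relative_current[res$condition == "drug"]
    tibble(gap = g, sod = sum(ctrl - drg), nsod = nsod(ctrl, drg))
  })
}

#' Effectiveness plane: nSOD(recovery) versus nSOD(onset)
#'
#' Runs every drug of a grid in both the slow-inactivation-onset
#' (`SInact_t`) and recovery (`Rec_t`) protocols - each drug at its own
#' IC50 at -90 mV holding - and places it on the nSOD(Rec_t) vs
#' nSOD(SInact_t) plane. To delimit the regions occupied by fast- (FI) and
#' slow- (SI) inactivated-state-preferring mechanisms, additional point
#' families are simulated the same way the study's plane is populated:
#' every grid drug at a fixed family concentration
#' (`fixed_concentrations`), and the factor-10 drugs with their
#' concentration decreased and increased tenfold (`concentration_series`).
#' Region polygons are convex hulls over all points of each family; low
#' concentrations pull the hulls toward the origin so that weakly acting
#' drugs are still classified.
#'
#' @param model Drug-free `channel_model`.
#' @param drugs A tibble as from [drug_grid()] (columns `name`, `family`,
#'   `factor` and list-column `drug`), or a list of [drug_spec()]s (each
#'   run at its own concentration; no regions are computed then).
#' @param fixed_concentrations Named vector of per-family fixed
#'   concentrations, uM, for the region point cloud (`NULL` to skip).
#' @param concentration_series Multipliers applied to the fixed
#'   concentration of the factor-10 drugs (`NULL` to skip).
#' @param points_per_decade Sweep-grid density.
#' @param gap_duration `SInact_t` gap duration, s.
#' @return An object of class `nsod_plane`: list with `points` (tibble with
#'   `nsod_onset`, `nsod_recovery`, `panel` per run) and `regions` (named
#'   list of hull coordinate matrices for families present).
#' @export
nsod_plane <- function(model, drugs = drug_grid(),
                       fixed_concentrations = c(FI = 14, SI = 81.75),
                       concentration_series = c(0.1, 10),
                       points_per_decade = 6, gap_duration = 0.01) {
  if (!is.data.frame(drugs)) {
    drugs <- tibble(name = vapply(drugs, `[[`, character(1), "name"),
                    family = NA_character_, factor = NA_real_,
                    drug = unname(drugs))
    fixed_concentrations <- NULL
    concentration_series <- NULL
  }
  st <- standard_protocol("SInact_t", points_per_decade = points_per_decade,
                          gap_duration = gap_duration)
  rt <- standard_protocol("Rec_t", points_per_decade = points_per_decade)
  ctrl_st <- run_condition(model, st, 2.5e-5)
  ctrl_rt <- run_condition(model, rt, 2.5e-5)
  run_point <- function(drug, conc) {
    d <- at_concentration(drug, conc)
    dmod <- if (conc > 0) extend_with_drug(model, d) else model
    c(onset = nsod(ctrl_st, run_condition(dmod, st, 2.5e-5)),
      recovery = nsod(ctrl_rt, run_condition(dmod, rt, 2.5e-5)))
  }
  one <- function(name, family, factor, drug, conc, panel) {
    v <- run_point(drug, conc)
    tibble(name = name, family = family, factor = factor,
           concentration = conc, panel = panel,
           nsod_onset = v[["onset"]], nsod_recovery = v[["recovery"]])
  }
  base <- drugs[c("name", "family", "factor", "drug")]
  pts <- purrr::pmap_dfr(base, function(name, family, factor, drug) {
    conc <- if (is.na(family)) drug$concentration else ic50(model, drug)
    one(name, family, factor, drug, conc, "ic50")
  })
  if (!is.null(fixed_concentrations)) {
    pts <- dplyr::bind_rows(pts, purrr::pmap_dfr(
      base, function(name, family, factor, drug) {
        one(name, family, factor, drug, fixed_concentrations[[family]],
            "fixed")
      }))
  }
  if (!is.null(concentration_series) && !is.null(fixed_concentrations)) {
    f10 <- base[!is.na(base$factor) & base$factor == 10, ]
    pts <- dplyr::bind_rows(pts, purrr::pmap_dfr(
      tidyr::expand_grid(f10, mult = concentration_series),
      function(name, family, factor, drug, mult) {
        one(name, family, factor, drug,
            mult * fixed_concentrations[[family]], "conc_series")
      }))
  }
  extra <- drugs[setdiff(names(drugs),
                         c("name", "family", "factor", "drug",
                           "concentration"))]
  if (ncol(extra)) {
    pts <- dplyr::left_join(pts, dplyr::bind_cols(drugs["name"], extra),
                            by = "name")
  }
  regions <- list()
  for (fam in intersect(c("FI", "SI"), unique(pts$family))) {
    xy <- as.matrix(pts[!is.na(pts$family) & pts$family == fam,
                        c("nsod_onset", "nsod_recovery")])
    if (nrow(xy) >= 3) regions[[fam]] <- xy[grDevices::chull(xy), ]
  }
  structure(list(points = pts, regions = regions), class = "nsod_plane")
}

#' @export
print.nsod_plane <- function(x, ...) {
  cat(sprintf("<nsod_plane> %d drugs; regions: %s\n", nrow(x$points),
              paste(names(x$regions), collapse = ", ")))
  invisible(x)
}

in_hull <- function(hull, x, y, pad = 1e-6) {
  # expand marginally about the centroid so hull vertices count as inside
  ctr <- colMeans(hull)
  hull <- t(ctr + (1 + pad) * (t(hull) - ctr))
  as.logical(mgcv::in.out(rbind(hull, hull[1, ]), cbind(x, y)))
}

#' Classify points on the effectiveness plane
#'
#' @param plane An [nsod_plane()] with both `FI` and `SI` regions.
#' @param points Tibble/data frame with columns `nsod_onset` and
#'   `nsod_recovery` (defaults to the plane's own points).
#' @return The points with an added `region` column: `"fast-only"`,
#'   `"slow-only"`, `"overlap"` or `"outside"`.
#' @export
classify_nsod <- function(plane, points = plane$points) {
  stopifnot(all(c("FI", "SI") %in% names(plane$regions)))
  fi <- in_hull(plane$regions$FI, points$nsod_onset, points$nsod_recovery)
  si <- in_hull(plane$regions$SI, points$nsod_onset, points$nsod_recovery)
  points$region <- dplyr::case_when(fi & si ~ "overlap",
                                    fi ~ "fast-only",
                                    si ~ "slow-only",
                                    TRUE ~ "outside")
  points
}

#' Signed area of a loop on the effectiveness plane
#'
#' Shoelace signed area of the polygon formed by a family of drugs ordered
#' by accelerating binding kinetics; a negative value means the loop is
#' traversed clockwise (in the nSOD(SInact_t) - x, nSOD(Rec_t) - y plane).
#'
#' @param x,y Loop coordinates in traversal order.
#' @return Signed area (negative = clockwise).
#' @export
loop_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}
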