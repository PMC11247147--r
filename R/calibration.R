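# Calibration: KRT prevalence targets by OLS extrapolation of historical
# datapoints, and a bisection search for scaling multipliers.

#' Extrapolate a KRT prevalence target from historical datapoints
#'
#' Fits an ordinary least-squares line through historical (year, prevalent
#' count) datapoints and evaluates it at the target year. A log-linear fit
#' (OLS on log counts, back-transformed) is available for settings where KRT
#' growth is closer to exponential.
#'
#' @param points data.frame(year, count) with at least two distinct years.
#' @param target_year Year at which to evaluate the fitted line.
#' @param family "linear" (default) or "loglinear".
#' @return Expected prevalent count at `target_year`.
#' @export
extrapolate_krt_target <- function(points, target_year,
                                   family = c("linear", "loglinear")) {
  family <- match.arg(family)
  if (nrow(points) < 2) stop("need at least two historical datapoints")
  if (length(unique(points$year)) < 2) {
    stop("historical datapoints must span at least two distinct years")
  }
  if (family == "loglinear") {
    if (any(points$count <= 0)) stop("log-linear fit needs positive counts")
    fit <- stats::lm(log(count) ~ year, data = points)
    return(unname(exp(stats::predict(fit,
                                     data.frame(year = target_year)))))
  }
  fit <- stats::lm(count ~ year, data = points)
  unname(stats::predict(fit, data.frame(year = target_year)))
}

#' Calibrate a scaling multiplier by bisection
#'
#' Finds the multiplier `m` such that a (monotone, deterministic given its
#' fixed seed) model summary matches an observed target within a relative
#' tolerance. Used with reduced-size cohorts to tune the KRT access, CKD
#' incidence or diagnosis knobs before a full-size run.
#'
#' @param simulate Function of one numeric multiplier returning the model
#'   summary being matched (e.g. simulated KRT prevalence); must be monotone
#'   over the bracket and internally use a fixed seed.
#' @param observed_target Target value (> 0).
#' @param bracket Numeric length-2 search interval for the multiplier.
#' @param tol Relative tolerance on |simulate(m) - target| / target.
#' @param max_iter Maximum bisection iterations.
#' @return The multiplier, with attributes `value` (simulate(m)),
#'   `relative_error` and `iterations`.
#' @export
calibrate_multiplier <- function(simulate, observed_target,
                                 bracket = c(0, 1), tol = 0.05,
                                 max_iter = 50) {
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- simulate(lo) - observed_target
  f_hi <- simulate(hi) - observed_target
  increasing <- f_hi >= f_lo
  if (sign(f_lo) == sign(f_hi) && f_lo != 0 && f_hi != 0) {
    stop("bracket [", lo, ", ", hi, "] does not straddle the target ",
         observed_target, " (f = ", signif(f_lo, 4), ", ",
         signif(f_hi, 4), ")")
  }
  best_m <- NA_real_; best_val <- NA_real_; best_err <- Inf
  for (i in seq_len(max_iter)) {
    m <- (lo + hi) / 2
    val <- simulate(m)
    err <- abs(val - observed_target) / abs(observed_target)
    if (err < best_err) {
      best_m <- m; best_val <- val; best_err <- err
    }
    if (err <= tol) {
      return(structure(m, value = val, relative_error = err, iterations = i))
    }
    if ((val < observed_target) == increasing) lo <- m else hi <- m
  }
  stop("calibrate_multiplier: max_iter (", max_iter,
       ") exceeded; best iterate m = ", signif(best_m, 6),
       " with relative error ", signif(best_err, 4))
}

#' Compare a projected series against a calibration target series
#'
#' @param projected,target Named numeric vectors (names = years) over the
#'   same years.
#' @param tol Maximum tolerated per-year relative error.
#' @return data.frame(year, projected, target, relative_error) with attribute
#'   `pass` (TRUE iff every year's error is within `tol`).
#' @export
validate_calibration <- function(projected, target, tol = 0.05) {
  if (!setequal(names(projected), names(target))) {
    stop("projected and target series cover different years")
  }
  target <- target[names(projected)]
  rel <- abs(projected - target) / abs(target)
  out <- data.frame(year = as.integer(names(projected)),
                    projected = unname(projected),
                    target = unname(target),
                    relative_error = unname(rel),
                    stringsAsFactors = FALSE)
  attr(out, "pass") <- all(rel <= tol)
  out
}
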