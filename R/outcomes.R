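#' Classify LVRS responders by pre-treatment heterogeneity
#'
#' Networks with lower-zone heterogeneity `beta` below the threshold
#' (default 3.5) are classified as LVRS responders; networks at or above the
#' threshold as marginal-responders.
#'
#' @param beta Numeric vector of [beta_index()] values.
#' @param threshold Classification threshold, default 3.5.
#' @return Character vector, `"responder"` or `"marginal"`.
#' @export
classify_responder <- function(beta, threshold = 3.5) {
  ifelse(beta < threshold, "responder", "marginal")
}

#' Rate of tissue failure over four progression steps
#'
#' The increase in compliance percent change over four stages of disease
#' progression, anchored at the row `ref` of the compliance trajectory
#' (first post-treatment stage for treated arms, post-initiation stage
#' untreated): `C_pct[ref + 4] - C_pct[ref]`.
#'
#' @param traj A trajectory: an `lvr_trajectory` or a tibble with a `C_pct`
#'   column ordered by stage.
#' @param ref Anchor row index (1-based).
#' @return The compliance-increase rate (percentage points per four stages).
#' @export
failure_rate <- function(traj, ref = 1L) {
  df <- if (inherits(traj, "lvr_trajectory")) traj$stages else traj
  if (nrow(df) < ref + 4) abort("need at least ref + 4 trajectory rows")
  df$C_pct[ref + 4] - df$C_pct[ref]
}

quadratic_root_at <- function(cf, thr, x_min) {
  # smallest real root >= x_min of cf[1] + cf[2] x + cf[3] x^2 = thr
  a <- cf[3]; b <- cf[2]; c0 <- cf[1] - thr
  roots <- if (abs(a) < 1e-300) {
    if (abs(b) < 1e-300) numeric() else -c0 / b
  } else {
    disc <- b^2 - 4 * a * c0
    if (disc < 0) numeric() else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- sort(roots[is.finite(roots) & roots >= x_min - 1e-9])
  if (length(roots) == 0) {
    abort("trajectory never reaches the threshold under quadratic extrapolation",
          class = "lvr_extrapolation_error")
  }
  roots[1]
}

#' Predicted survival: broken elements to a compliance threshold
#'
#' Survival is proxied by the cumulative ruptured-element count at which the
#' compliance increase first reaches `threshold_pct` (default 60%). A
#' crossing between observed stages is located by linear interpolation;
#' beyond the observed data a second-order polynomial fitted to the
#' trajectory (rows `fit_rows`) is extrapolated to the threshold and its
#' smallest admissible root returned.
#'
#' @param traj An `lvr_trajectory` or tibble with `cumulative_broken` and
#'   `C_pct` columns, ordered by stage.
#' @param threshold_pct Compliance-increase threshold in percent.
#' @param fit_rows Row indices used for the quadratic fit (default: all).
#' @return Broken-element count at crossing; attribute `method` records
#'   `"interpolated"` or `"extrapolated"`.
#' @export
predicted_survival <- function(traj, threshold_pct = 60, fit_rows = NULL) {
  df <- if (inherits(traj, "lvr_trajectory")) traj$stages else traj
  if (nrow(df) < 3) abort("need at least 3 trajectory points")
  x <- df$cumulative_broken; y <- df$C_pct
  if (y[1] >= threshold_pct) {
    warn("baseline already at or above the survival threshold")
    return(structure(x[1], method = "degenerate"))
  }
  hit <- which(y >= threshold_pct)
  if (length(hit) > 0) {
    i <- hit[1]
    x0 <- x[i - 1]; x1 <- x[i]; y0 <- y[i - 1]; y1 <- y[i]
    xs <- if (y1 == y0) x1 else x0 + (threshold_pct - y0) * (x1 - x0) / (y1 - y0)
    return(structure(unname(xs), method = "interpolated"))
  }
  fit_rows <- fit_rows %||% seq_len(nrow(df))
  fx <- x[fit_rows]; fy <- y[fit_rows]
  cf <- if (length(fit_rows) == 3) {
    # exact quadratic through three points
    solve(cbind(1, fx, fx^2), fy)
  } else {
    coef(lm(fy ~ fx + I(fx^2)))
  }
  cf <- unname(cf); cf[is.na(cf)] <- 0
  root <- tryCatch(quadratic_root_at(cf, threshold_pct, max(x)),
                   lvr_extrapolation_error = function(e) NULL)
  if (is.null(root)) {
    # concave-down fit never reaches the threshold: fall back to the secant
    # through the trailing points (a non-negative-curvature extrapolation)
    nlast <- min(3L, length(fx))
    sl <- coef(lm(tail(fy, nlast) ~ tail(fx, nlast)))
    if (!is.finite(sl[2]) || sl[2] <= 0) {
      abort("trajectory never reaches the threshold under quadratic or linear extrapolation",
            class = "lvr_extrapolation_error")
    }
    cf <- c(unname(sl[1]), unname(sl[2]), 0)
    root <- quadratic_root_at(cf, threshold_pct, max(x))
  }
  structure(unname(root), method = "extrapolated", fit = cf)
}

# area between the threshold line and the compliance curve, from x0 out to
# the arm's survival crossing; trapezoid over observed points plus the
# quadratic extrapolation segment
arm_area <- function(df, threshold_pct, x0, fit_rows = NULL, n_grid = 201L) {
  x <- df$cumulative_broken; y <- df$C_pct
  surv_full <- predicted_survival(df, threshold_pct, fit_rows)
  surv <- as.numeric(surv_full)
  keep <- x >= x0 & x <= surv
  xs <- x[keep]; ys <- pmax(threshold_pct - y[keep], 0)
  area <- 0
  if (length(xs) >= 2) {
    area <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  }
  if (attr(surv_full, "method") == "extrapolated") {
    cf <- attr(surv_full, "fit")
    xg <- seq(max(max(x), x0), surv, length.out = n_grid)
    yg <- pmax(threshold_pct - (cf[1] + cf[2] * xg + cf[3] * xg^2), 0)
    area <- area + sum(diff(xg) * (head(yg, -1) + tail(yg, -1)) / 2)
  } else if (length(xs) >= 1 && surv > max(xs)) {
    # crossing interpolated between the last kept point and the next
    area <- area + (surv - max(xs)) * tail(ys, 1) / 2
  }
  area
}

#' Relative benefit of a treatment arm
#'
#' The quality-of-life proxy: the area enclosed between the survival
#' threshold line and the compliance curve, integrated over cumulative
#' broken elements from the point where the arms diverge (the treatment
#' point; `from = "origin"` integrates from zero instead) out to each arm's
#' survival crossing, treated over untreated. Larger values mean lower
#' compliance sustained over a longer course. The untreated arm is
#' extrapolated with its fitted quadratic; the same rule extends a treated
#' arm that has not yet crossed.
#'
#' @param treated,untreated Trajectories (tibbles with `cumulative_broken`
#'   and `C_pct`, or `lvr_trajectory` objects). The treated table should
#'   contain the post-treatment rows; the untreated table the observed
#'   disease course.
#' @param threshold_pct Survival threshold in percent.
#' @param from `"treatment"` (default) or `"origin"`.
#' @param treat_x Cumulative-broken count at treatment; defaults to the last
#'   observed untreated point.
#' @return Ratio of treated to untreated area (untreated = 1).
#' @export
relative_benefit <- function(treated, untreated, threshold_pct = 60,
                             from = c("treatment", "origin"), treat_x = NULL) {
  from <- match.arg(from)
  tdf <- if (inherits(treated, "lvr_trajectory")) treated$stages else treated
  udf <- if (inherits(untreated, "lvr_trajectory")) untreated$stages else untreated
  x0 <- if (from == "origin") min(c(tdf$cumulative_broken, udf$cumulative_broken))
        else treat_x %||% max(udf$cumulative_broken)
  a_u <- arm_area(udf, threshold_pct, x0)
  if (a_u <= 0) abort("untreated area is zero: relative benefit undefined",
                      class = "lvr_metric_error")
  arm_area(tdf, threshold_pct, x0) / a_u
}
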