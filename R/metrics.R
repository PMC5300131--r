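# population moments: CVs and skewness follow the population (not sample)
# convention throughout
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
pop_cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(0)
  pop_sd(x) / m
}
pop_skew <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(0)  # degenerate: all values equal
  mean((x - mean(x))^3) / s^3
}

bbox_of <- function(net) {
  nd <- net$nodes
  c(xmin = min(nd$x), ymin = min(nd$y), xmax = max(nd$x), ymax = max(nd$y))
}

#' Apply a biaxial strain and re-equilibrate the interior
#'
#' Scales all node positions about the bounding-box centre by `1 + eps` in
#' both axes. Fixed nodes carry the strain; free nodes are re-equilibrated by
#' deterministic zero-temperature descent from the affinely strained start.
#'
#' @param net An equilibrated `lvr_network`.
#' @param eps Biaxial strain (e.g. `0.01` stretches by 1%).
#
#' @return The strained, re-equilibrated `lvr_network`.
#' @export
strain_network <- function(net, eps, conv_tol = 1e-8, max_sweeps = 2000L) {
  bb <- bbox_of(net)
  cx <- (bb["xmin"] + bb["xmax"]) / 2
  cy <- (bb["ymin"] + bb["ymax"]) / 2
  out <- net
  out$nodes$x <- cx + (1 + eps) * (net$nodes$x - cx)
  out$nodes$y <- cy + (1 + eps) * (net$nodes$y - cy)
  relax(out, descent_schedule(conv_tol = conv_tol, max_sweeps = max_sweeps))
}

#' Network stress by numerical energy differentiation
#'
#' The 2D network stress is the strain derivative of total energy at
#' equilibrium, estimated by central difference after stretching the network
#' by a small biaxial strain `+/- eps` (fixed nodes displaced affinely, free
#' nodes re-relaxed), normalised by the current bounding-box area:
#' `sigma = (E(+eps) - E(-eps)) / (2 * eps * A0)`.
#'
#' @param net An equilibrated `lvr_network`.
#' @param eps Probe strain, default `0.01`.
#' @return Stress (scalar, model units of energy / area).
#' @export
network_stress <- function(net, eps = 0.01) {
  bb <- bbox_of(net)
  A0 <- (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])
  if (!is.finite(A0) || A0 <= 0) abort("degenerate bounding box: stress undefined",
                                       class = "lvr_metric_error")
  ep <- total_energy(strain_network(net, +eps))
  em <- total_energy(strain_network(net, -eps))
  unname((ep - em) / (2 * eps * A0))
}

#' 2D bulk modulus and compliance
#'
#' The network is stretched through one sinusoidal strain cycle of amplitude
#' `amplitude` about equilibrium (`n_samples` strain points); the 2D bulk
#' modulus `B` is the ordinary least-squares slope of the stress-strain
#' relation, and compliance is its inverse, `C = 1/B`.
#'
#' @param net An equilibrated `lvr_network`.
#' @param amplitude Strain amplitude of the sinusoidal sweep, default `0.04`.
#' @param n_samples Strain points over one cycle, default 8 (the
#'   stress-strain relation is linear to well within the fit noise, so a
#'   denser cycle does not change the slope).
#' @param eps Probe strain for the per-point stress estimate.
#' @return List with `bulk_modulus`, `compliance`, and the sampled
#'   `stress_strain` tibble.
#' @export
bulk_modulus <- function(net, amplitude = 0.04, n_samples = 8, eps = 0.01) {
  strains <- amplitude * sin(2 * pi * seq(0, n_samples - 1) / n_samples)
  sigma <- map_dbl(strains, function(e) network_stress(strain_network(net, e), eps))
  fit <- lm(sigma ~ strains)
  B <- unname(coef(fit)[2])
  if (!is.finite(B) || B <= 0) {
    abort("non-positive bulk modulus: mechanically degenerate network",
          class = "lvr_metric_error")
  }
  list(bulk_modulus = B, compliance = 1 / B,
       stress_strain = tibble(strain = strains, stress = sigma))
}

#' Rasterize the network and label enclosed airspaces
#'
#' Unbroken springs are drawn as one-pixel-wide segments on a binary raster
#' (`resolution` pixels per unit length); enclosed background regions are
#' labeled by 4-connectivity and their pixel counts are the airspace areas.
#' Background connected to the raster frame (outside the network hull, or
#' open boundary cells) is excluded.
#'
#' @param net An `lvr_network`.
#' @param resolution Pixels per unit length; the default 16 puts 32 pixels
#'   across the two-unit diameter of an intact hexagonal cell, keeping the
#'   one-pixel strut bias on enclosed cell areas under 10%.
#' @param line_y Optional horizontal reference line (for [beta_index()])
#'   stored with the map.
#' @return An `lvr_airspace_map`: list with the integer `labels` matrix
#'   (0 strut, -1 outside, 1..K airspaces), an `airspaces` tibble
#'   (`label`, `area_px`, `cx`, `cy` in world coordinates), `resolution`, and
#'   `line_y`.
#' @export
rasterize_airspaces <- function(net, resolution = 16, line_y = NULL) {
  if (resolution < 3) abort("resolution too coarse: need >= 3 px per unit length",
                            class = "lvr_metric_error")
  sp <- filter(net$springs, !.data$broken)
  nd <- net$nodes
  bb <- bbox_of(net)
  if (nrow(sp) == 0) {
    map <- list(labels = matrix(-1L, 1, 1), airspaces = tibble(
      label = integer(), area_px = numeric(), cx = numeric(), cy = numeric()),
      resolution = resolution, bbox = bb, line_y = line_y)
    return(structure(map, class = "lvr_airspace_map"))
  }
  ia <- match(sp$a, nd$id); ib <- match(sp$b, nd$id)
  res <- cpp_airspace_map(nd$x[ia], nd$y[ia], nd$x[ib], nd$y[ib],
                          bb["xmin"], bb["ymin"], bb["xmax"], bb["ymax"],
                          resolution)
  if (length(res$area_px) == 0 && any(!net$springs$broken) &&
      nrow(nd) > 4) {
    abort("no enclosed airspaces found: raster resolution too coarse",
          class = "lvr_metric_error")
  }
  airspaces <- tibble(label = seq_along(res$area_px),
                      area_px = as.numeric(res$area_px),
                      cx = as.numeric(res$centroid_x),
                      cy = as.numeric(res$centroid_y))
  structure(list(labels = res$labels, airspaces = airspaces,
                 resolution = resolution, bbox = bb, line_y = line_y),
            class = "lvr_airspace_map")
}

#' @export
print.lvr_airspace_map <- function(x, ...) {
  cat(sprintf("<lvr_airspace_map> %d airspaces, raster %dx%d px at %g px/unit\n",
              nrow(x$airspaces), nrow(x$labels), ncol(x$labels), x$resolution))
  invisible(x)
}

#' Coefficient of variation of airspace areas
#'
#' Population SD over mean of the labeled airspace pixel areas: the overall
#' structural heterogeneity of the network.
#'
#' @param map An [rasterize_airspaces()] result.
#' @return Dimensionless CV.
#' @export
cv_area <- function(map) {
  a <- map$airspaces$area_px
  if (length(a) < 2) abort("cv_area undefined: fewer than 2 airspaces",
                           class = "lvr_metric_error")
  pop_cv(a)
}

#' Heterogeneity below the planned LVRS resection line
#'
#' The predictive index `beta` is the coefficient of variation of airspace
#' areas whose centroid lies below `line_y`, computed on the pre-treatment
#' configuration. Networks with `beta` below the responder threshold have
#' relatively spared lower tissue (upper-predominant disease) and respond
#' well to upper-network resection.
#'
#' @param map An [rasterize_airspaces()] result.
#' @param line_y Resection line height; defaults to the `line_y` stored in
#'   the map.
#' @return Dimensionless CV.
#' @export
beta_index <- function(map, line_y = NULL) {
  line_y <- line_y %||% map$line_y
  if (is.null(line_y)) abort("line_y required for beta_index")
  a <- map$airspaces$area_px[map$airspaces$cy < line_y]
  if (length(a) < 1) abort("beta undefined: no airspaces below the resection line",
                           class = "lvr_metric_error")
  if (length(a) == 1) return(0)
  pop_cv(a)
}

#' Dispersion and skewness of the spring force distribution
#'
#' CV and third-standardized-moment skewness of the tension magnitudes of
#' unbroken springs at the current configuration (population moments). A
#' degenerate all-equal distribution returns skewness 0 by convention.
#'
#' @param net An equilibrated `lvr_network`.
#' @return Named list with `cv_force` and `skew_force`.
#' @export
force_distribution_stats <- function(net) {
  f <- abs(spring_tensions(net)$tension)
  if (length(f) < 2) abort("force statistics undefined: fewer than 2 unbroken springs",
                           class = "lvr_metric_error")
  list(cv_force = pop_cv(f), skew_force = pop_skew(f))
}

#' Power-law fit to the tail of a force distribution
#'
#' Builds a histogram with log-spaced bins, scales counts by bin width and
#' normalises the area under the curve to unity (a probability density), then
#' fits `Probability ~ Force^alpha` by count-weighted least squares on the
#' log-log density over the upper tail (non-empty bins above the modal bin);
#' the weights damp the Poisson noise of sparse far-tail bins.
#'
#' @param values Positive sample (at least 100 values).
#' @param bins_per_decade Log-spaced bin density, default 30 per decade of
#'   sample range.
#' @return An `lvr_powerlaw` object with elements `alpha`, `r2`, `rmse`
#'   (log10 space), and the `bins` tibble. Supports [tidy()] and [glance()].
#' @export
powerlaw_tail_fit <- function(values, bins_per_decade = 30) {
  values <- values[is.finite(values)]
  if (length(values) < 100) abort("need >= 100 positive values")
  if (any(values <= 0)) abort("values must be positive")
  rng <- range(values)
  if (rng[1] == rng[2]) abort("degenerate sample: all values equal",
                              class = "lvr_metric_error")
  decades <- log10(rng[2] / rng[1])
  nb <- max(6L, ceiling(bins_per_decade * decades))
  edges <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = nb + 1)
  edges[1] <- edges[1] * (1 - 1e-12); edges[nb + 1] <- edges[nb + 1] * (1 + 1e-12)
  counts <- as.numeric(table(cut(values, edges)))
  width <- diff(edges)
  dens <- counts / width
  dens <- dens / sum(dens * width)   # unit area
  center <- sqrt(edges[-1] * edges[-(nb + 1)])
  bins <- tibble(center = center, width = width, count = counts, density = dens)
  mode_i <- which.max(dens)
  tail_i <- which(seq_len(nb) > mode_i & counts > 0)
  if (length(tail_i) < 3) abort("power-law fit failed: fewer than 3 tail bins",
                                class = "lvr_metric_error")
  lx <- log10(center[tail_i]); ly <- log10(dens[tail_i])
  # count-weighted least squares: sparse far-tail bins carry Poisson noise
  # that would otherwise bias the slope toward shallow exponents
  fit <- lm(ly ~ lx, weights = counts[tail_i])
  w <- counts[tail_i]
  rr <- 1 - sum(w * stats::residuals(fit)^2) /
    sum(w * (ly - stats::weighted.mean(ly, w))^2)
  structure(list(alpha = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = rr, rmse = sqrt(mean(stats::residuals(fit)^2)),
                 n_tail_bins = length(tail_i), bins = bins),
            class = "lvr_powerlaw")
}

#' @export
print.lvr_powerlaw <- function(x, ...) {
  cat(sprintf("<lvr_powerlaw> alpha = %.3f (R2 = %.3f, RMSE = %.3f, %d tail bins)\n",
              x$alpha, x$r2, x$rmse, x$n_tail_bins))
  invisible(x)
}

#' Power-law regression of compliance on force heterogeneity
#'
#' Least-squares line of `log(C)` on `log(CV_force)`: the slope is the
#' power-law exponent of `C ~ CV_force^exponent`.
#'
#' @param compliance,cv_force Paired positive values (n >= 3).
#' @return An `lvr_powerfit` with `exponent`, `r2`, `intercept`, `n`.
#'   Supports [tidy()] and [glance()].
#' @export
fit_compliance_cvforce <- function(compliance, cv_force) {
  if (length(compliance) != length(cv_force)) abort("inputs must be paired")
  keep <- is.finite(compliance) & is.finite(cv_force)
  compliance <- compliance[keep]; cv_force <- cv_force[keep]
  if (length(compliance) < 3) abort("need >= 3 pairs")
  if (any(compliance <= 0) || any(cv_force <= 0)) abort("values must be positive")
  lx <- log(cv_force); ly <- log(compliance)
  fit <- lm(ly ~ lx)
  ssr <- sum(stats::residuals(fit)^2)
  structure(list(exponent = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = 1 - ssr / sum((ly - mean(ly))^2),
                 n = length(compliance)),
            class = "lvr_powerfit")
}

#' @export
print.lvr_powerfit <- function(x, ...) {
  cat(sprintf("<lvr_powerfit> C ~ CV_force^%.3f (R2 = %.3f, n = %d)\n",
              x$exponent, x$r2, x$n))
  invisible(x)
}

#' All functional and structural metrics for one configuration
#'
#' Computes stress, bulk modulus, compliance (and their percent changes from
#' a baseline), airspace heterogeneity `CV_area`, force-distribution CV and
#' skewness, and optionally `beta` below a resection line. Metrics that are
#' undefined on a degenerate configuration are returned as `NA` with a
#' warning rather than failing the caller.
#'
#' @param net An equilibrated `lvr_network`.
#' @param baseline Optional list with `sigma` and `compliance` of the intact
#'   reference configuration; percent changes are relative to it. When
#'   `NULL`, percent changes are 0 (the configuration is its own baseline).
#' @param resolution Raster resolution for the airspace map.
#' @param line_y Optional resection line for `beta`.
#' @return One-row tibble.
#' @export
network_metrics <- function(net, baseline = NULL, resolution = 16,
                            line_y = NULL) {
  bm <- bulk_modulus(net)
  sig <- network_stress(net)
  fs <- force_distribution_stats(net)
  map <- rasterize_airspaces(net, resolution = resolution, line_y = line_y)
  cva <- tryCatch(cv_area(map), lvr_metric_error = function(e) {
    warn(conditionMessage(e)); NA_real_
  })
  beta <- if (!is.null(line_y)) {
    tryCatch(beta_index(map, line_y), lvr_metric_error = function(e) {
      warn(conditionMessage(e)); NA_real_
    })
  } else NA_real_
  if (is.null(baseline)) baseline <- list(sigma = sig, compliance = bm$compliance)
  tibble(
    sigma = sig, bulk_modulus = bm$bulk_modulus, compliance = bm$compliance,
    sigma_pct = 100 * (sig - baseline$sigma) / abs(baseline$sigma),
    C_pct = 100 * (bm$compliance - baseline$compliance) / baseline$compliance,
    cv_area = cva, n_airspaces = nrow(map$airspaces),
    cv_force = fs$cv_force, skew_force = fs$skew_force, beta = beta
  )
}
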