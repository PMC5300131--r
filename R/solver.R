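#' Annealing schedule for energy minimization
#'
#' Control parameters of the force-directed simulated-annealing minimizer.
#' Each free node is proposed a displacement proportional to (and in the
#' direction of) the resulting force on it; downhill moves are always
#' accepted, uphill moves with probability `exp(-dE/T)`, and `T` is cooled
#' multiplicatively each sweep.
#'
#' Defaults: `T0 = NULL` resolves at run time to `1e-3` times the initial
#' total energy; `step_gain = NULL` selects a per-node adaptive gain
#' `relax_factor / sum(k_incident)`, an over-relaxed locally-scaled step that
#' keeps convergence rates comparable across intact and heavily damaged
#' regions. Convergence is declared when the relative energy change per sweep
#' stays below `conv_tol` for three consecutive sweeps.
#'
#' @param T0 Initial control temperature (energy units), or `NULL` for
#'   `1e-3 * E_initial`.
#' @param cool_factor Multiplicative temperature reduction per sweep, in (0,1).
#' @param step_gain Displacement per unit force; `NULL` for the per-node
#'   adaptive gain.
#' @param relax_factor Over-relaxation factor of the adaptive gain (used only
#'   when `step_gain` is `NULL`); must be in (0, 2).
#' @param conv_tol Convergence threshold on relative energy change per sweep.
#' @param max_sweeps Sweep budget.
#' @param seed Integer seed driving sweep-order shuffles and Metropolis draws.
#' @return An `annealing_schedule` list.
#' @export
annealing_schedule <- function(T0 = NULL, cool_factor = 0.95, step_gain = NULL,
                               relax_factor = 1.7, conv_tol = 1e-9,
                               max_sweeps = 5000L, seed = 1L) {
  if (!is.null(T0) && T0 < 0) abort("T0 must be >= 0")
  if (cool_factor <= 0 || cool_factor >= 1) abort("cool_factor must be in (0,1)")
  if (!is.null(step_gain) && step_gain <= 0) abort("step_gain must be positive")
  if (relax_factor <= 0 || relax_factor >= 2) abort("relax_factor must be in (0,2)")
  if (conv_tol <= 0) abort("conv_tol must be positive")
  structure(list(T0 = T0, cool_factor = cool_factor, step_gain = step_gain,
                 relax_factor = relax_factor, conv_tol = conv_tol,
                 max_sweeps = as.integer(max_sweeps), seed = as.integer(seed)),
            class = "annealing_schedule")
}

# zero-temperature descent schedule used wherever determinism matters more
# than barrier crossing (metric strain sweeps, toy problems)
descent_schedule <- function(conv_tol = 1e-9, max_sweeps = 3000L, seed = 1L,
                             relax_factor = 1.7) {
  annealing_schedule(T0 = 0, conv_tol = conv_tol, max_sweeps = max_sweeps,
                     seed = seed, relax_factor = relax_factor)
}

#' Total elastic plus gravitational energy
#'
#' The elastic part sums `0.5 * k_i * (l_i - l0_i)^2` over unbroken springs;
#' the gravitational potential adds `g * n_below_i * y_i` per node.
#'
#' @param net An `lvr_network`.
#' @param positions Optional two-column matrix overriding node positions
#'   (rows in node order).
#' @return Total energy (scalar).
#' @export
total_energy <- function(net, positions = NULL) {
  ar <- net_arrays(net)
  if (!is.null(positions)) ar$pos <- as.matrix(positions)
  cpp_energy(ar$pos, ar$a, ar$b, ar$k, ar$l0, ar$broken, ar$gmass)
}

#' Resulting force on each node
#'
#' Analytic spring forces (tension `k * (l - l0)` directed along the spring
#' axis) summed per node, plus the gravity load. Fixed nodes are reported with
#' zero force since they do not move. Equals the negative gradient of
#' [total_energy()] with respect to node positions.
#'
#' @inheritParams total_energy
#' @param zero_fixed Report zero on fixed nodes (default `TRUE`).
#' @return Tibble with columns `id`, `fx`, `fy`.
#' @export
node_forces <- function(net, positions = NULL, zero_fixed = TRUE) {
  ar <- net_arrays(net)
  if (!is.null(positions)) ar$pos <- as.matrix(positions)
  f <- cpp_forces(ar$pos, ar$a, ar$b, ar$k, ar$l0, ar$broken, ar$gmass,
                  ar$fixed, zero_fixed)
  tibble(id = net$nodes$id, fx = f[, 1], fy = f[, 2])
}

#' Find a minimum-energy configuration
#'
#' Runs the simulated-annealing variant described in
#' [annealing_schedule()]. Free nodes whose incident springs are all broken
#' (orphans) are frozen in place and excluded from sweeps. With no free nodes
#' the input is returned unchanged after zero sweeps.
#'
#' @param net An `lvr_network`.
#' @param schedule An [annealing_schedule()].
#' @param trace Record per-sweep energy (retrievable as `result$trace`).
#' @return An `lvr_equilibrium` list: `network` (positions updated),
#'   `energy`, `initial_energy`, `sweeps`, `accepted_uphill`,
#'   `residual_force_max` (over free nodes).
#' @export
minimize_energy <- function(net, schedule = annealing_schedule(),
                            trace = FALSE) {
  ar <- net_arrays(net)
  T0 <- schedule$T0
  if (is.null(T0)) {
    T0 <- 1e-3 * cpp_energy(ar$pos, ar$a, ar$b, ar$k, ar$l0, ar$broken, ar$gmass)
  }
  res <- cpp_relax(ar$pos, ar$fixed, ar$a, ar$b, ar$k, ar$l0, ar$broken,
                   ar$gmass, T0, schedule$cool_factor,
                   schedule$step_gain %||% -1, schedule$relax_factor,
                   schedule$conv_tol, schedule$max_sweeps, schedule$seed,
                   trace)
  out <- net
  out$nodes$x <- res$pos[, 1]
  out$nodes$y <- res$pos[, 2]
  f <- cpp_forces(res$pos, ar$a, ar$b, ar$k, ar$l0, ar$broken, ar$gmass,
                  ar$fixed, TRUE)
  # residual over free, anchored, non-orphaned nodes only
  deg <- tabulate(c(ar$a[!ar$broken], ar$b[!ar$broken]), nbins = nrow(res$pos))
  active <- !ar$fixed & deg > 0 & res$anchored
  resid <- if (any(active)) max(sqrt(f[active, 1]^2 + f[active, 2]^2)) else 0
  structure(list(network = out, energy = res$energy,
                 initial_energy = res$initial_energy, sweeps = res$sweeps,
                 accepted_uphill = res$accepted_uphill,
                 residual_force_max = resid, trace = res$trace),
            class = "lvr_equilibrium")
}

#' @export
print.lvr_equilibrium <- function(x, ...) {
  cat(sprintf(
    "<lvr_equilibrium> E %.6g (from %.6g), %d sweeps, %g uphill, max|F| %.3g\n",
    x$energy, x$initial_energy, x$sweeps, x$accepted_uphill,
    x$residual_force_max))
  invisible(x)
}

#' Relax a network in place
#'
#' Convenience wrapper around [minimize_energy()] returning the relaxed
#' network only.
#'
#' @inheritParams minimize_energy
#' @return The relaxed `lvr_network`.
#' @export
relax <- function(net, schedule = annealing_schedule()) {
  minimize_energy(net, schedule)$network
}
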