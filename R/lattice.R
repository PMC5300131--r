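#' Spring parameter distributions
#'
#' Heterogeneous spring constants and resting lengths are drawn i.i.d. from
#' uniform distributions parameterised by mean and standard deviation. The
#' half-width of the uniform is `sd * sqrt(3)`, so the realised SD equals the
#' declared SD. Defaults follow the reference parenchymal network: spring
#' constants 1.0 +/- 0.4 and resting lengths 0.5 +/- 0.1 (dimensionless model
#' units). With unit strut length in the undeformed honeycomb, mean resting
#' length 0.5 leaves the network pre-stressed (taut) once the perimeter is
#' fixed.
#'
#' @param mean_k,sd_k Mean and SD of the spring-constant distribution.
#' @param mean_l0,sd_l0 Mean and SD of the resting-length distribution.
#' @param distribution Distribution family; only `"uniform"` is supported.
#' @return A `spring_params` list.
#' @export
spring_params <- function(mean_k = 1.0, sd_k = 0.4, mean_l0 = 0.5,
                          sd_l0 = 0.1, distribution = "uniform") {
  distribution <- match.arg(distribution, "uniform")
  if (mean_k <= 0 || mean_l0 <= 0) abort("mean_k and mean_l0 must be positive")
  if (sd_k < 0 || sd_l0 < 0) abort("sd_k and sd_l0 must be non-negative")
  structure(list(mean_k = mean_k, sd_k = sd_k, mean_l0 = mean_l0,
                 sd_l0 = sd_l0, distribution = distribution),
            class = "spring_params")
}

# uniform draws matched to (mean, sd); non-positive draws are resampled so
# sampled stiffnesses and rest lengths are strictly positive
sample_pos_uniform <- function(n, mean, sd) {
  hw <- sd * sqrt(3)
  x <- runif(n, mean - hw, mean + hw)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- runif(length(bad), mean - hw, mean + hw)
    bad <- bad[x[bad] <= 0]
  }
  x
}

# evaluate code under a local RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct an elastic network object
#'
#' Low-level constructor used by [build_hexagonal_network()] and by tests that
#' need small hand-made spring systems. Validates topology: spring endpoints
#' must reference existing nodes and no duplicate springs are allowed.
#'
#' @param nodes Tibble with columns `id`, `x`, `y`, `fixed` and optionally
#'   `col`, `row`, `n_below` (defaults 0).
#' @param springs Tibble with columns `a`, `b` and optionally `id`, `k`, `l0`,
#'   `broken`.
#' @param gravity_g Gravity proportionality constant: each node carries an
#'   external load `(0, -gravity_g * n_below)`.
#' @param template_shape Integer pair recording the generating hexagon
#'   template, or `NULL` for ad-hoc networks.
#' @param seed Seed recorded in the network metadata.
#' @return An `lvr_network` object.
#' @export
lvr_network <- function(nodes, springs, gravity_g = 0,
                        template_shape = NULL, seed = NA_integer_) {
  nodes <- as_tibble(nodes)
  springs <- as_tibble(springs)
  if (!all(c("x", "y", "fixed") %in% names(nodes))) {
    abort("nodes needs columns x, y, fixed")
  }
  if (is.null(nodes[["id"]])) nodes$id <- seq_len(nrow(nodes))
  if (is.null(nodes[["n_below"]])) nodes$n_below <- 0
  if (is.null(springs[["id"]])) springs$id <- seq_len(nrow(springs))
  if (is.null(springs[["k"]])) springs$k <- 1
  if (is.null(springs[["l0"]])) springs$l0 <- 1
  if (is.null(springs[["broken"]])) springs$broken <- FALSE
  net <- structure(list(nodes = nodes, springs = springs,
                        gravity_g = gravity_g,
                        template_shape = template_shape, seed = seed),
                   class = "lvr_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  nd <- net$nodes; sp <- net$springs
  bad <- which(!(sp$a %in% nd$id) | !(sp$b %in% nd$id))
  if (length(bad) > 0) {
    abort(sprintf("spring %s references a missing node", sp$id[bad[1]]))
  }
  key <- paste(pmin(sp$a, sp$b), pmax(sp$a, sp$b))
  if (anyDuplicated(key)) abort("duplicate springs present")
  if (any(sp$a == sp$b)) abort("self-loop spring present")
  invisible(net)
}

#' Build the pre-stressed hexagonal parenchymal network
#'
#' Generates a planar honeycomb from a `hex_rows x hex_cols` template of
#' hexagon units. Nodes form `hex_cols + 1` horizontal zigzag chains of
#' `2 * hex_rows + 1` nodes each; vertical struts connect alternating interior
#' columns of adjacent chains. At the default template (42 x 55) this yields
#' exactly 6,987 unit-length elastic elements over an 85 x 56 node array with
#' a nominal 2,310-cell template, and a straight clipped perimeter.
#'
#' All strut lengths are 1 before pre-stress; spring constants and resting
#' lengths are sampled from `params`, so the fixed perimeter holds the network
#' taut (resting lengths average 0.5). Gravity acts in -y with per-node load
#' proportional to the number of dependent nodes below in the same template
#' column; the column assignment and the counts are computed once here on the
#' intact lattice and frozen thereafter (a static body-force proxy for the
#' long-time-scale net effect of gravity).
#'
#' @param hex_rows Hexagon units per zigzag chain (network width). Default 42.
#' @param hex_cols Number of chain gaps (network height). Default 55.
#' @param params A [spring_params()] object.
#' @param gravity_g Gravity constant, or `NULL` (default) for the
#'   height-scaled value `0.28 / hex_cols^2`: the accumulated column load at
#'   the top of the network then raises tension there by roughly 30% of the
#'   mean spring tension while individual node loads stay ~1% of it -- a
#'   relatively weak influence that nonetheless biases rupture toward the
#'   upper network.
#' @param seed Integer seed for the parameter draws.
#' @return An `lvr_network`.
#' @examples
#' net <- build_hexagonal_network(4, 4, seed = 1)
#' net
#' @export
build_hexagonal_network <- function(hex_rows = 42, hex_cols = 55,
                                    params = spring_params(),
                                    gravity_g = NULL, seed = 1L) {
  if (hex_rows < 1 || hex_cols < 1) abort("hex_rows and hex_cols must be >= 1")
  if (is.null(gravity_g)) gravity_g <- 0.28 / hex_cols^2
  W <- as.integer(hex_rows); H <- as.integer(hex_cols)
  ncol_ <- 2L * W + 1L
  grid <- expand.grid(col = 0:(2L * W), row = 0:H)
  id <- function(c, r) r * ncol_ + c + 1L
  nodes <- tibble(
    id = id(grid$col, grid$row),
    col = grid$col, row = grid$row,
    x = grid$col * sqrt(3) / 2,
    y = 1.5 * grid$row + 0.5 * ((grid$col + grid$row) %% 2),
    fixed = grid$row == 0L | grid$row == H | grid$col == 0L | grid$col == 2L * W
  )
  nodes <- arrange(nodes, .data$id)
  # dependent nodes below, per template column, on the intact lattice
  nodes$n_below <- nodes$row

  ce <- expand.grid(c = 0:(2L * W - 1L), r = 0:H)          # chain struts
  vb <- expand.grid(c = 1:(2L * W - 1L), r = 0:(H - 1L))   # vertical struts
  vb <- vb[(vb$c + vb$r) %% 2 == 1, ]
  a <- c(id(ce$c, ce$r), id(vb$c, vb$r))
  b <- c(id(ce$c + 1L, ce$r), id(vb$c, vb$r + 1L))

  ns <- length(a)
  draws <- with_local_seed(seed, list(
    k = sample_pos_uniform(ns, params$mean_k, params$sd_k),
    l0 = sample_pos_uniform(ns, params$mean_l0, params$sd_l0)
  ))
  springs <- tibble(id = seq_len(ns), a = a, b = b,
                    k = draws$k, l0 = draws$l0, broken = FALSE)
  lvr_network(nodes, springs, gravity_g = gravity_g,
              template_shape = c(W, H), seed = as.integer(seed))
}

#' Number of springs, nodes, and template cells
#'
#' `n_cells()` reports the nominal hexagon-template count
#' `hex_rows * hex_cols` (2,310 at the default build); boundary cells clipped
#' by the straight perimeter are counted as template units.
#'
#' @param net An `lvr_network`.
#' @return Integer count.
#' @export
n_springs <- function(net) nrow(net$springs)

#' @rdname n_springs
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_springs
#' @export
n_cells <- function(net) {
  if (is.null(net$template_shape)) return(NA_integer_)
  as.integer(prod(net$template_shape))
}

#' Per-node gravity loads
#'
#' Each node carries a downward external force with magnitude proportional to
#' the number of dependent nodes below it in the same template column,
#' `(0, -gravity_g * n_below)`. Loads were assigned on the intact lattice and
#' are frozen as nodes move.
#'
#' @param net An `lvr_network`.
#' @return A tibble with columns `id`, `fx`, `fy`.
#' @export
gravity_loads <- function(net) {
  tibble(id = net$nodes$id, fx = 0, fy = -net$gravity_g * net$nodes$n_below)
}

#' @export
print.lvr_network <- function(x, ...) {
  nb <- sum(x$springs$broken)
  cat(sprintf("<lvr_network> %d nodes (%d fixed), %d springs (%d broken)",
              n_nodes(x), sum(x$nodes$fixed), n_springs(x), nb))
  if (!is.null(x$template_shape)) {
    cat(sprintf(", template %dx%d (%d cells)",
                x$template_shape[1], x$template_shape[2], n_cells(x)))
  }
  cat(sprintf(", g = %g\n", x$gravity_g))
  invisible(x)
}

#' Signed spring tensions at the current configuration
#'
#' Tension `k * (l - l0)` is positive for stretched springs. The "force" used
#' for rupture ranking and force-distribution statistics is the magnitude.
#'
#' @param net An `lvr_network`.
#' @param unbroken_only Drop broken springs (default `TRUE`).
#' @return Tibble with columns `id`, `length`, `tension`.
#' @export
spring_tensions <- function(net, unbroken_only = TRUE) {
  sp <- net$springs
  if (unbroken_only) sp <- filter(sp, !.data$broken)
  ia <- match(sp$a, net$nodes$id); ib <- match(sp$b, net$nodes$id)
  len <- sqrt((net$nodes$x[ia] - net$nodes$x[ib])^2 +
              (net$nodes$y[ia] - net$nodes$y[ib])^2)
  tibble(id = sp$id, length = len, tension = sp$k * (len - sp$l0))
}

#' Write and read network snapshots
#'
#' JSON snapshots store nodes (id, template indices, coordinates, fixed mask,
#' dependent-node counts), springs (endpoints, stiffness, resting length,
#' broken flag) and metadata (template shape, gravity constant, seed) at full
#' numeric precision, so a write/read roundtrip reproduces the network
#' exactly. A malformed file (a spring referencing a missing node) raises a
#' parse error naming the offending record.
#'
#' @param net An `lvr_network`.
#' @param path File path for the JSON snapshot.
#' @return `read_network()` returns the restored `lvr_network`;
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  payload <- list(
    meta = list(template_shape = net$template_shape,
                gravity_g = net$gravity_g, seed = net$seed),
    nodes = net$nodes, springs = net$springs
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- raw$meta$template_shape
  nodes <- as_tibble(raw$nodes)
  nodes$fixed <- as.logical(nodes$fixed)
  springs <- as_tibble(raw$springs)
  springs$broken <- as.logical(springs$broken)
  lvr_network(nodes, springs,
              gravity_g = raw$meta$gravity_g %||% 0,
              template_shape = if (length(ts)) as.integer(ts) else NULL,
              seed = raw$meta$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a network as a CSV pair for spreadsheet inspection
#'
#' Writes `nodes.csv` and `springs.csv` into `dir`. This is a convenience
#' export; the JSON snapshot ([write_network()]) is the roundtrip format.
#'
#' @param net An `lvr_network`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_network_csv <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(net$nodes, file.path(dir, "nodes.csv"))
  readr::write_csv(net$springs, file.path(dir, "springs.csv"))
  invisible(dir)
}

# internal: flat arrays for the C++ kernels
net_arrays <- function(net) {
  nd <- net$nodes; sp <- net$springs
  idx <- match(seq_len(max(nd$id)), nd$id)
  list(pos = cbind(nd$x, nd$y),
       fixed = nd$fixed,
       a = match(sp$a, nd$id), b = match(sp$b, nd$id),
       k = sp$k, l0 = sp$l0, broken = sp$broken,
       gmass = net$gravity_g * nd$n_below)
}
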