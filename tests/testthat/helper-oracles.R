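# Shared fixtures and independent oracles, built in code at test time.

# -- small hand-made spring systems -----------------------------------------

# two fixed anchors at distance 2 joined through one free node by two springs
# (k = 1, l0 = 0.5): the free node's equilibrium is the midpoint by symmetry
midpoint_toy <- function(start = c(0.7, 0.35)) {
  lvr_network(
    nodes = tibble::tibble(id = 1:3, x = c(0, 2, start[1]),
                           y = c(0, 0, start[2]),
                           fixed = c(TRUE, TRUE, FALSE)),
    springs = tibble::tibble(a = c(1, 2), b = c(3, 3), k = 1, l0 = 0.5)
  )
}

# one horizontal spring between fixed nodes plus two inert fixed corners so
# the bounding box is the unit square; E(s) = 0.5 k (s - l0)^2 under biaxial
# scale s, analytically differentiable
single_spring_toy <- function(k = 2, l0 = 0.5) {
  lvr_network(
    nodes = tibble::tibble(id = 1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                           fixed = TRUE),
    springs = tibble::tibble(a = 1, b = 2, k = k, l0 = l0)
  )
}

# closed-form stress of the single-spring toy at biaxial scale state s,
# mirroring the definition: central difference of E with +/- eps about the
# state, over the state's bounding-box area
toy_stress_oracle <- function(s, k = 2, l0 = 0.5, eps = 0.01) {
  E <- function(sc) 0.5 * k * (sc - l0)^2
  (E(s * (1 + eps)) - E(s * (1 - eps))) / (2 * eps * s^2)
}

# -- planar face-walking oracle ---------------------------------------------

# counts closed interior faces of a planar straight-line embedded graph by
# half-edge traversal with angular ordering; independent of the lattice
# generator's bookkeeping
count_interior_faces <- function(net) {
  nd <- net$nodes
  sp <- dplyr::filter(net$springs, !.data$broken)
  idx <- stats::setNames(seq_len(nrow(nd)), nd$id)
  ns <- nrow(sp)
  he_from <- c(idx[as.character(sp$a)], idx[as.character(sp$b)])
  he_to <- c(idx[as.character(sp$b)], idx[as.character(sp$a)])
  m <- length(he_from)
  twin <- c(seq_len(ns) + ns, seq_len(ns))
  ang <- atan2(nd$y[he_to] - nd$y[he_from], nd$x[he_to] - nd$x[he_from])
  # rotation system: CCW-sorted leaving half-edges per vertex
  leaving <- split(seq_len(m), he_from)
  leaving <- lapply(leaving, function(es) es[order(ang[es])])
  rank_in <- integer(m)
  for (es in leaving) rank_in[es] <- seq_along(es)
  # next(e) = CW-predecessor of twin(e) in the rotation at head(e)
  nxt <- integer(m)
  for (e in seq_len(m)) {
    t <- twin[e]
    es <- leaving[[as.character(he_from[t])]]
    pos <- rank_in[t] - 1L
    if (pos == 0L) pos <- length(es)
    nxt[e] <- es[pos]
  }
  visited <- logical(m)
  faces <- 0
  for (e in seq_len(m)) {
    if (visited[e]) next
    faces <- faces + 1
    cur <- e
    while (!visited[cur]) {
      visited[cur] <- TRUE
      cur <- nxt[cur]
    }
  }
  faces - 1L  # drop the outer face
}

# population moment oracles written from the defining formulas
oracle_cv <- function(x) sqrt(mean((x - mean(x))^2)) / mean(x)
oracle_skew <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  mean((x - mean(x))^3) / s^3
}

# shoelace polygon area of a convex hull of points
hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# inverse-CDF Pareto sampler: density ~ x^(-alpha_mag) for x >= 1
rpareto <- function(n, alpha_mag) (1 - runif(n))^(-1 / (alpha_mag - 1))

quick_schedule <- function(seed = 1L) {
  annealing_schedule(conv_tol = 1e-8, max_sweeps = 1500L, seed = seed)
}
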