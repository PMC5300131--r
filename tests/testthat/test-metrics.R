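test_that("network stress matches the closed-form derivative on a toy", {
  for (k in c(1, 2)) {
    net <- single_spring_toy(k = k, l0 = 0.5)
    expect_equal(network_stress(net), toy_stress_oracle(1, k = k),
                 tolerance = 1e-10)
  }
  # unstressed configuration: all springs at rest length, g = 0
  rest <- single_spring_toy(k = 3, l0 = 1)
  expect_lt(abs(network_stress(rest)), 1e-10)
})

test_that("pre-stressed intact networks carry positive stress", {
  net <- relax(build_hexagonal_network(4, 5, gravity_g = 0, seed = 3))
  sig <- network_stress(net)
  expect_gt(sig, 0)
  # sign cross-check: virial sum f_i * l_i over springs is positive for a
  # tension-dominated network
  tens <- spring_tensions(net)
  expect_gt(sum(tens$tension * tens$length), 0)
})

test_that("bulk modulus matches the closed form and C * B = 1", {
  net <- single_spring_toy(k = 2, l0 = 0.5)
  bm <- bulk_modulus(net)
  expect_equal(bm$compliance * bm$bulk_modulus, 1, tolerance = 1e-12)
  strains <- 0.04 * sin(2 * pi * seq(0, 7) / 8)
  oracle_B <- unname(coef(lm(toy_stress_oracle(1 + strains) ~ strains))[2])
  expect_equal(bm$bulk_modulus, oracle_B, tolerance = 1e-3)

  # doubling every stiffness doubles B and halves C
  net2 <- net; net2$springs$k <- net2$springs$k * 2
  bm2 <- bulk_modulus(net2)
  expect_equal(bm2$bulk_modulus, 2 * bm$bulk_modulus, tolerance = 1e-6)
  expect_equal(bm2$compliance, bm$compliance / 2, tolerance = 1e-6)
})

test_that("metric functions are pure: repeated calls agree exactly", {
  net <- relax(build_hexagonal_network(4, 4, seed = 9))
  expect_identical(network_stress(net), network_stress(net))
  expect_identical(bulk_modulus(net)$bulk_modulus,
                   bulk_modulus(net)$bulk_modulus)
  expect_identical(cv_area(rasterize_airspaces(net)),
                   cv_area(rasterize_airspaces(net)))
})

test_that("rasterization labels one airspace per closed cell on intact lattices", {
  net <- build_hexagonal_network(6, 8, gravity_g = 0, seed = 4)
  map <- rasterize_airspaces(net)
  euler_faces <- n_springs(net) - n_nodes(net) + 1L
  expect_equal(nrow(map$airspaces), euler_faces)
  expect_lt(cv_area(map), 0.2)
  # per-cell pixel area within 10% of the geometric hexagon area
  hex_px <- 3 * sqrt(3) / 2 * map$resolution^2
  expect_lt(abs(median(map$airspaces$area_px) - hex_px) / hex_px, 0.10)
})

test_that("breaking a shared wall merges two airspaces additively", {
  net <- build_hexagonal_network(6, 8, gravity_g = 0, seed = 4)
  before <- rasterize_airspaces(net)
  # an interior vertical strut separates two hexagons
  nd <- net$nodes
  interior <- !nd$fixed
  sp <- net$springs
  vert <- which(abs(nd$x[match(sp$a, nd$id)] - nd$x[match(sp$b, nd$id)]) < 1e-9 &
                interior[match(sp$a, nd$id)] & interior[match(sp$b, nd$id)])
  # central strut: both neighbouring faces are full interior hexagons
  mx <- (nd$x[match(sp$a[vert], nd$id)] - mean(nd$x))^2 +
    (nd$y[match(sp$a[vert], nd$id)] - mean(nd$y))^2
  target <- vert[which.min(mx)]
  ys <- (nd$y[match(sp$a[target], nd$id)] + nd$y[match(sp$b[target], nd$id)]) / 2
  xs <- nd$x[match(sp$a[target], nd$id)]
  net$springs$broken[target] <- TRUE
  after <- rasterize_airspaces(net)
  expect_equal(nrow(after$airspaces), nrow(before$airspaces) - 1L)
  # merged region area ~ sum of the two parents plus the freed strut pixels
  near <- function(map) {
    d <- (map$airspaces$cx - xs)^2 + (map$airspaces$cy - ys)^2
    order(d)
  }
  merged <- after$airspaces$area_px[near(after)[1]]
  parents <- sum(before$airspaces$area_px[near(before)[1:2]])
  expect_lt(abs(merged - parents) / parents, 0.15)
})

test_that("fully broken networks yield an empty airspace map", {
  net <- build_hexagonal_network(2, 2, gravity_g = 0, seed = 1)
  net$springs$broken <- TRUE
  map <- rasterize_airspaces(net)
  expect_equal(nrow(map$airspaces), 0L)
  expect_error(cv_area(map), "fewer than 2")
})

test_that("airspace CV and beta match the population-moment oracles", {
  fake_map <- structure(list(
    airspaces = tibble::tibble(label = 1:5, area_px = c(1, 3, 2, 2, 8),
                               cx = 0, cy = c(-1, -1, -1, 5, 5)),
    resolution = 6, line_y = 0), class = "lvr_airspace_map")
  expect_equal(cv_area(fake_map), oracle_cv(c(1, 3, 2, 2, 8)), tolerance = 1e-14)
  # equal areas -> 0
  eq_map <- fake_map
  eq_map$airspaces$area_px <- rep(4, 5)
  expect_equal(cv_area(eq_map), 0)
  # beta over the airspaces below the line only: {1,3,2} here
  expect_equal(beta_index(fake_map, 0), oracle_cv(c(1, 3, 2)), tolerance = 1e-14)
  # the documented toy: lower areas {1,1,4} -> sqrt(2)/2
  toy <- fake_map
  toy$airspaces <- tibble::tibble(label = 1:3, area_px = c(1, 1, 4),
                                  cx = 0, cy = -1)
  expect_equal(beta_index(toy, 0), sqrt(2) / 2, tolerance = 1e-14)
  # no airspace below the line -> undefined
  expect_error(beta_index(fake_map, -10), "no airspaces below")
})

test_that("force distribution statistics match the moment formulas", {
  net <- lvr_network(
    nodes = tibble::tibble(id = 1:4, x = c(0, 2, 4, 7), y = 0, fixed = TRUE),
    springs = tibble::tibble(a = 1:3, b = 2:4, k = 1, l0 = c(1, 0, -6)))
  # tensions |k (l - l0)| = {1, 2, 9} by construction
  tens <- abs(spring_tensions(net)$tension)
  expect_equal(sort(tens), c(1, 2, 9))
  fs <- force_distribution_stats(net)
  expect_equal(fs$cv_force, oracle_cv(tens), tolerance = 1e-14)
  expect_equal(fs$skew_force, oracle_skew(tens), tolerance = 1e-14)
  # degenerate all-equal tensions -> (0, 0)
  eqnet <- lvr_network(
    nodes = tibble::tibble(id = 1:3, x = c(0, 2, 4), y = 0, fixed = TRUE),
    springs = tibble::tibble(a = 1:2, b = 2:3, k = 1, l0 = 1))
  fs0 <- force_distribution_stats(eqnet)
  expect_equal(fs0$cv_force, 0)
  expect_equal(fs0$skew_force, 0)
})

test_that("power-law tail fit recovers a known Pareto exponent", {
  x <- local({set.seed(77); rpareto(1e5, 2.5)})
  fit <- powerlaw_tail_fit(x)
  expect_lt(abs(fit$alpha - (-2.5)), 0.1)
  expect_gt(fit$r2, 0.98)
  # an exponential sample is a poor power law by comparison
  y <- local({set.seed(78); rexp(1e5) + 1})
  fit_e <- powerlaw_tail_fit(y)
  expect_gt(fit$r2, fit_e$r2)
  # degenerate single repeated value
  expect_error(powerlaw_tail_fit(rep(2, 500)), "degenerate")
  tg <- glance(fit)
  expect_equal(tg$alpha, fit$alpha)
  expect_named(tidy(fit), c("term", "estimate"))
})

test_that("compliance vs force-heterogeneity regression recovers exponents", {
  x <- seq(0.2, 2, length.out = 40)
  fit <- fit_compliance_cvforce(2.3 * x^-0.7, x)
  expect_equal(fit$exponent, -0.7, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # multiplicative log-normal noise, sigma_log = 0.1
  noisy <- local({
    set.seed(5)
    2.3 * x^-0.7 * exp(rnorm(length(x), 0, 0.1))
  })
  fit_n <- fit_compliance_cvforce(noisy, x)
  expect_lt(abs(fit_n$exponent - (-0.7)), 0.05)
  expect_error(fit_compliance_cvforce(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_equal(glance(fit_n)$exponent, fit_n$exponent)
})

test_that("network_metrics assembles percent changes against a baseline", {
  net <- relax(build_hexagonal_network(4, 4, gravity_g = 0, seed = 10))
  m0 <- network_metrics(net)
  expect_equal(m0$C_pct, 0)
  expect_equal(m0$sigma_pct, 0)
  baseline <- list(sigma = m0$sigma, compliance = m0$compliance)
  soft <- net
  soft$springs$k <- soft$springs$k / 2   # uniform softening doubles C
  m1 <- network_metrics(relax(soft), baseline)
  expect_lt(abs(m1$C_pct - 100), 0.1)
})
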