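test_that("default build reproduces the reference network counts", {
  net <- build_hexagonal_network(42, 55, seed = 1)
  expect_equal(n_springs(net), 6987L)
  expect_equal(n_cells(net), 2310L)
  expect_equal(n_nodes(net), 4760L)
  # node array indexing is 85 x 56
  expect_equal(max(net$nodes$col) + 1L, 85L)
  expect_equal(max(net$nodes$row) + 1L, 56L)
  # intact struts all unit length before pre-stress
  len <- spring_tensions(net)$length
  expect_true(all(abs(len - 1) < 1e-12))
  # perimeter fixed
  nd <- net$nodes
  on_perim <- nd$row %in% c(0L, 55L) | nd$col %in% c(0L, 84L)
  expect_equal(nd$fixed, on_perim)
})

test_that("small builds match the enumeration of the zigzag-grid construction", {
  n1 <- build_hexagonal_network(1, 1, gravity_g = 0, seed = 0)
  expect_equal(n_nodes(n1), 6L)
  expect_equal(n_springs(n1), 5L)
  expect_equal(n_cells(n1), 1L)
  expect_true(all(n1$nodes$fixed))

  n2 <- build_hexagonal_network(2, 2, gravity_g = 0, seed = 0)
  expect_equal(n_nodes(n2), 15L)
  expect_equal(n_springs(n2), 15L)
  expect_equal(n_cells(n2), 4L)

  expect_error(build_hexagonal_network(0, 3), "must be >= 1")
})

test_that("spring parameter sampling matches the declared moments", {
  net <- build_hexagonal_network(42, 55, seed = 99)
  # pool several large builds for ~1e5 draws
  k <- c(net$springs$k, build_hexagonal_network(42, 55, seed = 100)$springs$k,
         build_hexagonal_network(42, 55, seed = 101)$springs$k,
         build_hexagonal_network(42, 55, seed = 102)$springs$k,
         build_hexagonal_network(42, 55, seed = 103)$springs$k,
         build_hexagonal_network(42, 55, seed = 104)$springs$k,
         build_hexagonal_network(42, 55, seed = 105)$springs$k,
         build_hexagonal_network(42, 55, seed = 106)$springs$k,
         build_hexagonal_network(42, 55, seed = 107)$springs$k,
         build_hexagonal_network(42, 55, seed = 108)$springs$k,
         build_hexagonal_network(42, 55, seed = 109)$springs$k,
         build_hexagonal_network(42, 55, seed = 110)$springs$k,
         build_hexagonal_network(42, 55, seed = 111)$springs$k,
         build_hexagonal_network(42, 55, seed = 112)$springs$k,
         build_hexagonal_network(42, 55, seed = 113)$springs$k)
  expect_gt(length(k), 1e5)
  expect_lt(abs(mean(k) - 1.0), 0.01)
  expect_lt(abs(sd(k) - 0.4), 0.008)
  l0 <- build_hexagonal_network(42, 55, seed = 7)$springs$l0
  expect_lt(abs(mean(l0) - 0.5), 0.005)
  expect_lt(abs(sd(l0) - 0.1), 0.004)
  expect_true(all(k > 0) && all(l0 > 0))
})

test_that("Euler consistency: springs - nodes + 1 interior faces by face walking", {
  for (dims in list(c(1, 1), c(2, 3), c(4, 4), c(5, 3))) {
    net <- build_hexagonal_network(dims[1], dims[2], gravity_g = 0, seed = 2)
    euler <- n_springs(net) - n_nodes(net) + 1L
    expect_equal(count_interior_faces(net), euler,
                 info = paste(dims, collapse = "x"))
  }
})

test_that("gravity loads count dependent nodes and vanish at g = 0", {
  net <- build_hexagonal_network(3, 4, gravity_g = 0.1, seed = 1)
  gl <- gravity_loads(net)
  expect_true(all(gl$fx == 0))
  expect_true(all(gl$fy <= 0))
  # bottom row carries nothing; a node in row r has r dependents below
  expect_equal(gl$fy[net$nodes$row == 0], rep(0, sum(net$nodes$row == 0)))
  expect_equal(gl$fy, -0.1 * net$nodes$row)
  expect_equal(sum(gl$fy), -0.1 * sum(net$nodes$n_below))
  net0 <- build_hexagonal_network(3, 4, gravity_g = 0, seed = 1)
  expect_true(all(gravity_loads(net0)$fy == 0))
  # monotone non-increasing magnitude from top to bottom of a column
  col5 <- dplyr::arrange(dplyr::filter(
    dplyr::left_join(gl, net$nodes, by = "id"), col == 5), dplyr::desc(y))
  expect_true(all(diff(abs(col5$fy)) <= 0))
})

test_that("network JSON roundtrip is exact and validates input", {
  net <- build_hexagonal_network(4, 5, seed = 3)
  net$springs$broken[sample.int(nrow(net$springs), 17)] <- TRUE
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$nodes$x, net$nodes$x, tolerance = 1e-12)
  expect_equal(back$nodes$y, net$nodes$y, tolerance = 1e-12)
  expect_identical(back$nodes$fixed, net$nodes$fixed)
  expect_identical(back$springs$broken, net$springs$broken)
  expect_equal(back$springs$k, net$springs$k, tolerance = 1e-12)
  expect_equal(back$springs$l0, net$springs$l0, tolerance = 1e-12)
  expect_identical(back$template_shape, net$template_shape)

  # malformed snapshot: spring referencing a missing node
  bad <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad$springs$a[1] <- 99999
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, digits = NA, auto_unbox = TRUE)
  expect_error(read_network(path2), "missing node")
})

test_that("csv export writes an inspectable pair", {
  net <- build_hexagonal_network(2, 2, seed = 1)
  dir <- withr::local_tempdir()
  write_network_csv(net, dir)
  nodes <- readr::read_csv(file.path(dir, "nodes.csv"), show_col_types = FALSE)
  expect_equal(nrow(nodes), n_nodes(net))
  springs <- readr::read_csv(file.path(dir, "springs.csv"), show_col_types = FALSE)
  expect_equal(nrow(springs), n_springs(net))
})
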