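sch <- annealing_schedule(T0 = 0, conv_tol = 1e-7, max_sweeps = 400L)

test_that("resection removes the upper fraction and fixes a straight border", {
  net <- relax(build_hexagonal_network(4, 4, gravity_g = 0, seed = 1), sch)
  y_line <- lvrs_line(net, lvrs_spec(0.30))
  lv <- apply_lvrs(net, lvrs_spec(0.30), schedule = sch)
  # coordinate-filter oracle: every node strictly above the line is gone
  gone <- net$nodes$id[net$nodes$y > y_line]
  expect_true(all(!gone %in% lv$nodes$id))
  expect_equal(attr(lv, "removed_nodes"), length(gone))
  # survivors sit at or below the line; the new top border is collinear and
  # fixed
  expect_true(all(lv$nodes$y <= y_line + 1e-9))
  top <- lv$nodes[abs(lv$nodes$y - max(lv$nodes$y)) < 1e-9, ]
  expect_true(all(top$fixed))
  expect_equal(max(lv$nodes$y), y_line, tolerance = 1e-9)
  # removed springs logged, and none of them flagged as ruptures
  expect_gt(attr(lv, "removed_springs"), 0)
  expect_equal(sum(lv$springs$broken), 0L)
})

test_that("a vanishing resection clips only the top zigzag crests", {
  net <- relax(build_hexagonal_network(4, 4, gravity_g = 0, seed = 1), sch)
  y_line <- lvrs_line(net, lvrs_spec(1e-9))
  lv <- apply_lvrs(net, lvrs_spec(1e-9), schedule = sch)
  # only the up-offset crests of the (already fixed) top chain sit above the
  # line; everything else survives and the border is flat and fixed
  expect_equal(attr(lv, "removed_nodes"), sum(net$nodes$y > y_line))
  expect_equal(n_nodes(net) - n_nodes(lv), sum(net$nodes$y > y_line))
  expect_true(all(lv$nodes$y <= y_line + 1e-9))
  expect_equal(sum(!lv$nodes$fixed), sum(!net$nodes$fixed))
  # resecting nearly everything leaves no free tissue
  expect_error(apply_lvrs(net, lvrs_spec(0.999), schedule = sch),
               class = "lvr_argument_error")
})

test_that("region selection targets enlarged airspaces only", {
  net <- build_hexagonal_network(6, 8, gravity_g = 0, seed = 5)
  # homogeneous intact map: nothing qualifies
  expect_warning(r0 <- select_affected_regions(net, spec = blvr_spec()),
                 "no airspace")
  expect_length(r0, 0)

  # knock out a cluster of interior walls around one node to merge cells
  nd <- net$nodes
  centre <- nd$id[!nd$fixed][order(abs(nd$x[!nd$fixed] - mean(nd$x)) +
                                   abs(nd$y[!nd$fixed] - mean(nd$y)))][1:4]
  hit <- net$springs$a %in% centre | net$springs$b %in% centre
  net$springs$broken[hit] <- TRUE
  net <- relax(net, sch)
  map <- rasterize_airspaces(net)
  regions <- select_affected_regions(net, map, blvr_spec())
  expect_gte(length(regions), 1)
  big_label <- map$airspaces$label[which.max(map$airspaces$area_px)]
  expect_equal(attr(regions, "labels")[1], big_label)
  # the merged region's rim nodes belong to the selected set
  expect_gt(length(regions[[1]]), 5)
})

test_that("ties at the selection cap resolve to the smallest label id", {
  # synthetic map: two equal 6x6 airspaces, cap 1
  labs <- matrix(0L, 30, 30)
  labs[5:10, 5:10] <- 1L
  labs[20:25, 20:25] <- 2L
  map <- structure(list(
    labels = labs,
    airspaces = tibble::tibble(label = 1:2, area_px = c(36, 36),
                               cx = c(1, 3), cy = c(1, 3)),
    resolution = 2, bbox = c(xmin = 0, ymin = 0, xmax = 14, ymax = 14),
    line_y = NULL), class = "lvr_airspace_map")
  net <- lvr_network(
    nodes = tibble::tibble(id = 1:2, x = c(3, 11), y = c(3, 11),
                           fixed = FALSE),
    springs = tibble::tibble(a = 1, b = 2))
  regions <- select_affected_regions(net, map,
                                     blvr_spec(min_area_factor = 1,
                                               max_regions = 1))
  expect_equal(attr(regions, "labels"), 1L)
})

test_that("regional collapse scales hull areas by the target fraction", {
  net <- relax(build_hexagonal_network(6, 8, gravity_g = 0, seed = 7), sch)
  nd <- net$nodes
  # a free interior disc of nodes
  cx <- mean(nd$x); cy <- mean(nd$y)
  member <- nd$id[!nd$fixed & (nd$x - cx)^2 + (nd$y - cy)^2 < 2.5^2]
  expect_gt(length(member), 6)
  before <- hull_area(nd$x[match(member, nd$id)], nd$y[match(member, nd$id)])
  bl <- apply_blvr(net, list(member), blvr_spec(target_fraction = 0.20),
                   schedule = sch)
  m <- match(member, bl$nodes$id)
  after <- hull_area(bl$nodes$x[m], bl$nodes$y[m])
  expect_lt(abs(after - 0.20 * before) / (0.20 * before), 0.05)
  # reduced nodes are pinned afterwards
  expect_true(all(bl$nodes$fixed[m]))

  # target 1.0 leaves positions unchanged
  bl1 <- apply_blvr(net, list(member), blvr_spec(target_fraction = 1))
  expect_equal(bl1$nodes$x, net$nodes$x)

  # overlapping regions are rejected
  expect_error(apply_blvr(net, list(member, member[1:3]),
                          blvr_spec(target_fraction = 0.2), schedule = sch),
               "disjoint")
  expect_error(blvr_spec(target_fraction = 1.2), "target_fraction")
})

test_that("border-touching regions compress toward the border, fixed nodes still", {
  net <- relax(build_hexagonal_network(6, 8, gravity_g = 0, seed = 8), sch)
  nd <- net$nodes
  # region touching the bottom fixed boundary
  member <- nd$id[nd$y < 2.5 & nd$x > mean(nd$x) - 3 & nd$x < mean(nd$x) + 3]
  fixed_before <- nd[match(member, nd$id), ]
  fixed_before <- fixed_before[fixed_before$fixed, ]
  bl <- apply_blvr(net, list(member), blvr_spec(target_fraction = 0.3),
                   schedule = sch)
  after <- bl$nodes[match(fixed_before$id, bl$nodes$id), ]
  expect_equal(after$x, fixed_before$x, tolerance = 1e-12)
  expect_equal(after$y, fixed_before$y, tolerance = 1e-12)
  # free members moved toward the border line, x unchanged
  free_m <- setdiff(member, fixed_before$id)
  expect_equal(bl$nodes$x[match(free_m, bl$nodes$id)],
               nd$x[match(free_m, nd$id)], tolerance = 1e-12)
  expect_true(all(bl$nodes$y[match(free_m, bl$nodes$id)] <=
                  nd$y[match(free_m, nd$id)] + 1e-12))
})

test_that("fixed nodes never move through intervention plus relaxation", {
  net <- relax(build_hexagonal_network(5, 6, seed = 9), sch)
  net <- initiate_emphysema(net, rupture_rule(), seed = 9, schedule = sch)
  fixed_ids <- net$nodes$id[net$nodes$fixed]
  pos0 <- net$nodes[match(fixed_ids, net$nodes$id), c("x", "y")]
  lv <- apply_lvrs(net, lvrs_spec(0.3), schedule = sch)
  surv <- intersect(fixed_ids, lv$nodes$id)
  expect_equal(lv$nodes[match(surv, lv$nodes$id), c("x", "y")],
               pos0[match(surv, fixed_ids), ])
})
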