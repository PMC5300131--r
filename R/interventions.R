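#' Lung volume reduction specifications
#'
#' `lvrs_spec()` parameterises surgical resection: the upper
#' `resect_fraction` of the current network height is removed and cells cut
#' by the resection line are stretched onto a new continuous, fixed
#' horizontal upper border.
#'
#' `blvr_spec()` parameterises bronchoscopic reduction: selected enlarged
#' airspaces (regions) are collapsed toward their geometric centre to
#' `target_fraction` of their original area. Region selection picks the
#' largest enclosed airspaces whose pixel area exceeds
#' `min_area_factor` times the intact single-cell area, capped at
#' `max_regions` (largest first; ties by smallest label id).
#'
#' @param resect_fraction Fraction of network height resected, in (0,1).
#' @param target_fraction Remaining area fraction after reduction, in (0,1].
#'   Clinically motivated values are 0.01, 0.20, 0.40.
#' @param min_area_factor Airspace qualifies when its area exceeds this
#'   multiple of the intact cell area; the default 3 treats any airspace of
#'   at least three coalesced acinar units as emphysematous.
#' @param max_regions Cap on the number of reduced regions; by default all
#'   qualifying airspaces are treated (`Inf`).
#' @return A spec list.
#' @export
lvrs_spec <- function(resect_fraction = 0.30) {
  if (resect_fraction <= 0 || resect_fraction >= 1) {
    abort("resect_fraction must be in (0,1)")
  }
  structure(list(resect_fraction = resect_fraction), class = "lvrs_spec")
}

#' @rdname lvrs_spec
#' @export
blvr_spec <- function(target_fraction = 0.20, min_area_factor = 3,
                      max_regions = Inf) {
  if (target_fraction <= 0 || target_fraction > 1) {
    abort("target_fraction must be in (0,1]")
  }
  structure(list(target_fraction = target_fraction,
                 min_area_factor = min_area_factor,
                 max_regions = max_regions), class = "blvr_spec")
}

#' Resection line height for a configuration
#'
#' @param net An `lvr_network`.
#' @param spec An [lvrs_spec()].
#' @return The y coordinate of the planned resection line on the current
#'   bounding box.
#' @export
lvrs_line <- function(net, spec = lvrs_spec()) {
  bb <- bbox_of(net)
  unname(bb["ymin"] + (1 - spec$resect_fraction) * (bb["ymax"] - bb["ymin"]))
}

#' Apply lung volume reduction surgery (upper-network resection)
#'
#' Removes all tissue strictly above the resection line of the current
#' bounding box. Regions intersected by the line are stretched up to close
#' the cut: each surviving node that was attached to removed tissue is
#' raised onto the line, and together these form the new continuous, fixed
#' horizontal upper border. The stretch loads the border springs, seeding
#' high-force elements along the resection margin. Removed springs are not
#' ruptures: they do not count toward the cumulative broken-element tally.
#'
#' @param net An equilibrated diseased `lvr_network`.
#' @param spec An [lvrs_spec()].
#' @param schedule Annealing schedule for the post-resection equilibration.
#' @return The re-equilibrated resected network; attributes
#'   `removed_springs` and `removed_nodes` log the resection size, and
#'   `y_line` the resection height.
#' @export
apply_lvrs <- function(net, spec = lvrs_spec(),
                       schedule = annealing_schedule()) {
  y_line <- lvrs_line(net, spec)
  nd <- net$nodes; sp <- net$springs
  above <- nd$y > y_line
  ia <- match(sp$a, nd$id); ib <- match(sp$b, nd$id)
  a_up <- above[ia]; b_up <- above[ib]
  drop_spring <- a_up | b_up

  # the ragged free edge left by the resection is stretched up onto the
  # straight border: every surviving node that held an unbroken spring into
  # the removed tissue is raised to the line and fixed there. The raised
  # nodes' remaining springs gain tension, seeding high-force elements along
  # the new border.
  tie <- !sp$broken & xor(a_up, b_up)
  edge_ids <- unique(c(sp$a[tie & !a_up], sp$b[tie & !b_up]))
  keep_nodes <- nd[!above, , drop = FALSE]
  # already-fixed perimeter nodes never move; only free edge nodes stretch up
  raise <- keep_nodes$id %in% edge_ids & !keep_nodes$fixed
  keep_nodes$y[raise] <- y_line
  keep_nodes$fixed <- keep_nodes$fixed | raise |
    keep_nodes$y >= y_line - 1e-9
  new_springs <- sp[!drop_spring, , drop = FALSE]
  if (!any(!keep_nodes$fixed)) {
    abort("resection leaves no free tissue", class = "lvr_argument_error")
  }
  out <- lvr_network(keep_nodes, new_springs, gravity_g = net$gravity_g,
                     template_shape = net$template_shape, seed = net$seed)
  out <- relax(out, schedule)
  attr(out, "removed_springs") <- sum(drop_spring)
  attr(out, "removed_nodes") <- sum(above)
  attr(out, "y_line") <- y_line
  out
}

# pixel-space node membership lookup for a labeled airspace
nodes_near_label <- function(net, map, label) {
  ppu <- map$resolution
  pad <- 2L
  labs <- map$labels
  ny <- nrow(labs); nx <- ncol(labs)
  px <- round((net$nodes$x - map$bbox["xmin"]) * ppu) + pad + 1
  py <- round((net$nodes$y - map$bbox["ymin"]) * ppu) + pad + 1
  r <- max(2L, round(0.4 * ppu))
  hit <- logical(nrow(net$nodes))
  for (i in seq_len(nrow(net$nodes))) {
    xs <- max(1, px[i] - r):min(nx, px[i] + r)
    ys <- max(1, py[i] - r):min(ny, py[i] + r)
    if (any(labs[ys, xs, drop = FALSE] == label)) hit[i] <- TRUE
  }
  net$nodes$id[hit]
}

#' Select affected regions for bronchoscopic reduction
#'
#' Identifies enlarged (emphysematous) airspaces to target: labeled
#' airspaces whose pixel area exceeds `min_area_factor` times the geometric
#' intact-cell area, ranked by area (largest first, ties by smallest label
#' id) and capped at `max_regions`. Each selected airspace is mapped back to
#' the set of nodes on or near its bounding perimeter. Overlapping node sets
#' are made disjoint in rank order.
#'
#' @param net The `lvr_network` the map was rasterized from.
#' @param map An [rasterize_airspaces()] result for `net` (computed at the
#'   default resolution when `NULL`).
#' @param spec A [blvr_spec()].
#' @return A list of integer node-id vectors (possibly empty, with a
#'   warning); attribute `labels` carries the selected airspace labels.
#' @export
select_affected_regions <- function(net, map = NULL, spec = blvr_spec()) {
  if (is.null(map)) map <- rasterize_airspaces(net)
  cell_px <- 3 * sqrt(3) / 2 * map$resolution^2   # unit-edge hexagon area
  qual <- filter(map$airspaces, .data$area_px > spec$min_area_factor * cell_px)
  if (nrow(qual) == 0) {
    warn("no airspace exceeds the selection threshold; no regions selected")
    return(structure(list(), labels = integer()))
  }
  qual <- arrange(qual, desc(.data$area_px), .data$label)
  qual <- head(qual, spec$max_regions)
  regions <- map(qual$label, function(l) nodes_near_label(net, map, l))
  taken <- integer()
  for (i in seq_along(regions)) {
    regions[[i]] <- setdiff(regions[[i]], taken)
    taken <- c(taken, regions[[i]])
  }
  keep <- lengths(regions) > 0
  structure(regions[keep], labels = qual$label[keep])
}

#' Apply bronchoscopic lung volume reduction (regional collapse)
#'
#' Moves the member nodes of each selected region toward the region's
#' geometric centre so its area shrinks to `target_fraction` of the original
#' (coordinates scale by `sqrt(target_fraction)`). Regions containing fixed
#' border nodes are reduced asymmetrically: nodes move only perpendicular to
#' the border, toward the border line (area scales by `target_fraction`
#' along that single axis), so fixed nodes never move. Displaced region
#' nodes become permanently fixed, modeling collapsed, sealed tissue; the
#' network is then re-equilibrated.
#'
#' @param net An equilibrated `lvr_network`.
#' @param regions List of disjoint node-id vectors
#'   (from [select_affected_regions()]).
#' @param spec A [blvr_spec()].
#' @param schedule Annealing schedule for the re-equilibration.
#' @return The re-equilibrated network.
#' @export
apply_blvr <- function(net, regions, spec = blvr_spec(),
                       schedule = annealing_schedule()) {
  if (spec$target_fraction > 1) abort("target_fraction must be <= 1")
  all_ids <- unlist(regions)
  if (anyDuplicated(all_ids)) abort("regions must be disjoint")
  if (!is.null(net$nodes[["reduced"]]) &&
      any(net$nodes$reduced[match(all_ids, net$nodes$id)])) {
    abort("region overlaps a previously reduced region")
  }
  tf <- spec$target_fraction
  if (tf == 1) return(net)   # identity scaling: nothing to collapse
  if (is.null(net$nodes[["reduced"]])) net$nodes$reduced <- FALSE
  for (ids in regions) {
    m <- match(ids, net$nodes$id)
    fx <- net$nodes$fixed[m]
    if (any(fx)) {
      # border-constrained region: compress free members perpendicular to the
      # border only, toward the border line; fixed nodes never move
      vx <- if (sum(fx) > 1) stats::var(net$nodes$x[m][fx]) else 0
      vy <- if (sum(fx) > 1) stats::var(net$nodes$y[m][fx]) else 0
      mf <- m[!fx]
      if (vx >= vy) {  # horizontal border
        yb <- mean(net$nodes$y[m][fx])
        net$nodes$y[mf] <- yb + tf * (net$nodes$y[mf] - yb)
      } else {         # vertical border
        xb <- mean(net$nodes$x[m][fx])
        net$nodes$x[mf] <- xb + tf * (net$nodes$x[mf] - xb)
      }
    } else {
      cx <- mean(net$nodes$x[m]); cy <- mean(net$nodes$y[m])
      s <- sqrt(tf)
      net$nodes$x[m] <- cx + s * (net$nodes$x[m] - cx)
      net$nodes$y[m] <- cy + s * (net$nodes$y[m] - cy)
    }
    net$nodes$fixed[m] <- TRUE
    net$nodes$reduced[m] <- TRUE
  }
  relax(net, schedule)
}
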