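#' Rupture rule for emphysema initiation and progression
#'
#' Emphysema is initiated by randomly breaking a fraction (default ~4%) of
#' all elastic elements; progression then repeatedly breaks each of the
#' highest-force elements (the top `top_fraction` of unbroken springs,
#' default 0.7%) independently with probability `p_break` (default 0.40),
#' re-equilibrating between stages. Surviving elements carry no fatigue
#' memory.
#'
#' @param init_fraction Fraction of all springs broken at initiation.
#' @param top_fraction Fraction of unbroken springs in the high-force
#'   candidate set at each stage.
#' @param p_break Rupture probability per candidate.
#' @param n_stages Default number of progression stages.
#' @return A `rupture_rule` list.
#' @export
rupture_rule <- function(init_fraction = 0.04, top_fraction = 0.007,
                         p_break = 0.40, n_stages = 5L) {
  for (v in c(init_fraction, top_fraction, p_break)) {
    if (v < 0 || v > 1) abort("rupture fractions and probabilities must be in [0,1]")
  }
  if (n_stages < 0) abort("n_stages must be >= 0")
  structure(list(init_fraction = init_fraction, top_fraction = top_fraction,
                 p_break = p_break, n_stages = as.integer(n_stages)),
            class = "rupture_rule")
}

#' Initiate emphysema by random rupture
#'
#' Breaks `round(init_fraction * n_springs)` distinct springs chosen
#' uniformly without replacement, then re-equilibrates. At the default
#' network and fraction this breaks 279 of 6,987 springs.
#'
#' @param net An intact (or already equilibrated) `lvr_network`.
#' @param rule A [rupture_rule()].
#' @param seed Integer seed for the draw.
#' @param schedule Annealing schedule template for the re-equilibration.
#' @return The re-equilibrated network with broken springs flagged.
#' @export
initiate_emphysema <- function(net, rule = rupture_rule(), seed = 1L,
                               schedule = annealing_schedule()) {
  n_break <- round(rule$init_fraction * n_springs(net))
  if (n_break > 0) {
    alive <- net$springs$id[!net$springs$broken]
    pick <- with_local_seed(seed, sample(alive, n_break, replace = FALSE))
    net$springs$broken[net$springs$id %in% pick] <- TRUE
  }
  schedule$seed <- derive_seed(seed, "init-relax")
  relax(net, schedule)
}

#' One force-based progression step
#'
#' Ranks unbroken springs by tension magnitude at the current equilibrium,
#' takes the top `ceiling(top_fraction * n_unbroken)` as rupture candidates
#' (ties broken deterministically by spring id), breaks each independently
#' with probability `p_break`, and re-equilibrates.
#'
#' @inheritParams initiate_emphysema
#' @return List with the new `network` and the integer ids of `ruptured`
#'   springs.
#' @export
progression_step <- function(net, rule = rupture_rule(), seed = 1L,
                             schedule = annealing_schedule()) {
  alive <- filter(net$springs, !.data$broken)
  if (nrow(alive) == 0) abort("progression exhausted: all springs broken",
                              class = "lvr_progression_exhausted")
  tens <- spring_tensions(net)
  n_cand <- ceiling(rule$top_fraction * nrow(alive))
  ord <- order(-abs(tens$tension), tens$id)
  candidates <- tens$id[ord][seq_len(n_cand)]
  u <- with_local_seed(seed, runif(n_cand))
  ruptured <- candidates[u < rule$p_break]
  if (length(ruptured) > 0) {
    net$springs$broken[net$springs$id %in% ruptured] <- TRUE
  }
  schedule$seed <- derive_seed(seed, "step-relax")
  list(network = relax(net, schedule), ruptured = ruptured)
}

new_trajectory <- function(stages, networks, baseline, rule) {
  structure(list(stages = stages, networks = networks, baseline = baseline,
                 rule = rule), class = "lvr_trajectory")
}

#' @export
print.lvr_trajectory <- function(x, ...) {
  cat(sprintf("<lvr_trajectory> %d stages, cumulative broken %d -> %d\n",
              nrow(x$stages), min(x$stages$cumulative_broken),
              max(x$stages$cumulative_broken)))
  print(x$stages)
  invisible(x)
}

#' @export
as_tibble.lvr_trajectory <- function(x, ...) x$stages

stage_row <- function(net, stage, label, cumulative, baseline, resolution,
                      line_y = NULL) {
  m <- network_metrics(net, baseline = baseline, resolution = resolution,
                       line_y = line_y)
  dplyr::bind_cols(tibble(stage = stage, label = label,
                          cumulative_broken = cumulative), m)
}

#' Run disease progression and record a trajectory
#'
#' Relaxes the intact network (stage 0, the baseline for all percent
#' changes), initiates emphysema, then advances `n_stages` force-based
#' progression steps, recording the full metric set at every stage.
#'
#' @inheritParams initiate_emphysema
#' @param n_stages Number of progression stages after initiation.
#' @param resolution Raster resolution for structural metrics.
#' @return An `lvr_trajectory`: `stages` tibble (stage, label,
#'   `cumulative_broken`, metrics), parallel `networks` list, and the
#'   `baseline` (absolute stress and compliance of stage 0).
#' @export
run_progression <- function(net, rule = rupture_rule(), seed = 1L,
                            n_stages = rule$n_stages, resolution = 16,
                            schedule = annealing_schedule()) {
  schedule$seed <- derive_seed(seed, "baseline-relax")
  net0 <- relax(net, schedule)
  m0 <- network_metrics(net0, baseline = NULL, resolution = resolution)
  baseline <- list(sigma = m0$sigma, compliance = m0$compliance)
  stages <- dplyr::bind_cols(
    tibble(stage = 0L, label = "baseline",
           cumulative_broken = sum(net0$springs$broken)), m0)
  networks <- list(net0)

  net1 <- initiate_emphysema(net0, rule, seed = derive_seed(seed, "init"),
                             schedule = schedule)
  stages <- bind_rows(stages, stage_row(net1, 1L, "initiation",
                                        sum(net1$springs$broken),
                                        baseline, resolution))
  networks <- c(networks, list(net1))

  cur <- net1
  if (n_stages > 0) {
    for (s in seq_len(n_stages)) {
      step <- progression_step(cur, rule, seed = derive_seed(seed, "stage", s),
                               schedule = schedule)
      cur <- step$network
      stages <- bind_rows(stages, stage_row(cur, s + 1L, paste0("stage_", s),
                                            sum(cur$springs$broken),
                                            baseline, resolution))
      networks <- c(networks, list(cur))
    }
  }
  new_trajectory(stages, networks, baseline, rule)
}

#' Continue progression from a treated or mid-course configuration
#'
#' Records the supplied configuration as the first row (e.g. the immediate
#' post-treatment state), then advances `n_stages` progression steps.
#' Percent changes are computed against the supplied `baseline` (the original
#' intact configuration), and `cumulative_broken` continues from
#' `cumulative_start` (elements removed by resection are not ruptures and do
#' not advance the count).
#'
#' @inheritParams run_progression
#' @param baseline List with `sigma` and `compliance` of the original intact
#'   configuration.
#' @param cumulative_start Cumulative ruptured-element count at entry.
#' @param first_label Label for the entry row.
#' @return An `lvr_trajectory`.
#' @export
extend_progression <- function(net, rule, baseline, seed = 1L,
                               n_stages = rule$n_stages,
                               cumulative_start = 0L, resolution = 16,
                               schedule = annealing_schedule(),
                               first_label = "treated") {
  cum <- cumulative_start
  stages <- stage_row(net, 0L, first_label, cum, baseline, resolution)
  networks <- list(net)
  cur <- net
  if (n_stages > 0) {
    for (s in seq_len(n_stages)) {
      step <- progression_step(cur, rule, seed = derive_seed(seed, "stage", s),
                               schedule = schedule)
      cur <- step$network
      cum <- cum + length(step$ruptured)
      stages <- bind_rows(stages, stage_row(cur, s, paste0(first_label, "_", s),
                                            cum, baseline, resolution))
      networks <- c(networks, list(cur))
    }
  }
  new_trajectory(stages, networks, baseline, rule)
}
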