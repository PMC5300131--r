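#' Study configuration
#'
#' Bundles every parameter of a multi-network lung volume reduction study:
#' an ensemble of `n_networks` networks with different random initial
#' conditions (inter-subject variability) is degraded through initiation and
#' `rule$n_stages` progression stages; LVRS and each bLVR reduction target
#' are then applied in parallel from the identical pre-treatment snapshot
#' and the treated networks degraded a further `post_stages` stages.
#'
#' @param n_networks Ensemble size (reference study: 14).
#' @param hex_rows,hex_cols Lattice template (reference: 42 x 55).
#' @param params [spring_params()].
#' @param gravity_g Gravity constant (`NULL`: height-scaled default, see
#'   [build_hexagonal_network()]).
#' @param rule [rupture_rule()].
#' @param lvrs [lvrs_spec()].
#' @param blvr_targets bLVR remaining-size fractions (reference:
#'   0.01, 0.20, 0.40).
#' @param blvr [blvr_spec()] carrying the region-selection parameters.
#' @param post_stages Progression stages after treatment.
#' @param resolution Raster resolution for structural metrics.
#' @param schedule [annealing_schedule()] template.
#' @param beta_threshold Responder classification threshold.
#' @param threshold_pct Survival threshold (% compliance increase).
#' @param master_seed Master seed; all per-network and per-arm seeds derive
#'   from it deterministically.
#' @return A `study_config` list.
#' @export
study_config <- function(n_networks = 14L, hex_rows = 42L, hex_cols = 55L,
                         params = spring_params(), gravity_g = NULL,
                         rule = rupture_rule(), lvrs = lvrs_spec(),
                         blvr_targets = c(0.01, 0.20, 0.40),
                         blvr = blvr_spec(), post_stages = 5L,
                         resolution = 16, schedule = annealing_schedule(),
                         beta_threshold = 3.5, threshold_pct = 60,
                         master_seed = 1L) {
  if (n_networks < 1) abort("n_networks must be >= 1")
  structure(list(n_networks = as.integer(n_networks),
                 hex_rows = as.integer(hex_rows),
                 hex_cols = as.integer(hex_cols), params = params,
                 gravity_g = gravity_g, rule = rule, lvrs = lvrs,
                 blvr_targets = blvr_targets, blvr = blvr,
                 post_stages = as.integer(post_stages),
                 resolution = resolution, schedule = schedule,
                 beta_threshold = beta_threshold,
                 threshold_pct = threshold_pct,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

arm_outcomes <- function(arm, arm_df, pre_df, beta, cfg, C_pct_pre, cum_pre) {
  thr <- cfg$threshold_pct
  surv_u <- predicted_survival(pre_df, thr)
  if (arm == "untreated") {
    return(tibble(
      arm = arm,
      immediate_dC = 0,
      failure_rate = failure_rate(pre_df, ref = 2L),
      survival_broken = as.numeric(surv_u),
      survival_ratio = 1,
      relative_benefit = 1,
      compliance_post = NA_real_, cv_force_post = NA_real_,
      skew_pre = pre_df$skew_force[nrow(pre_df)],
      skew_post = NA_real_))
  }
  surv_t <- predicted_survival(arm_df, thr)
  tibble(
    arm = arm,
    immediate_dC = C_pct_pre - arm_df$C_pct[1],
    failure_rate = failure_rate(arm_df, ref = 1L),
    survival_broken = as.numeric(surv_t),
    survival_ratio = as.numeric(surv_t) / as.numeric(surv_u),
    relative_benefit = relative_benefit(arm_df, pre_df, thr,
                                        treat_x = cum_pre),
    compliance_post = arm_df$compliance[1],
    cv_force_post = arm_df$cv_force[1],
    skew_pre = pre_df$skew_force[nrow(pre_df)],
    skew_post = arm_df$skew_force[1])
}

#' Run a full lung volume reduction study
#'
#' For each network: build, initiate emphysema, advance the pre-treatment
#' progression, record the predictive index `beta` below the planned
#' resection line, then branch LVRS and every bLVR target from the identical
#' pre-treatment snapshot (the untreated arm is the quadratic projection of
#' the pre-treatment course) and degrade each treated arm `post_stages`
#' further stages. Outcome indices are computed per arm, and group summary
#' statistics (mean, SD, n) are split by responder class.
#'
#' Arm failures are caught and recorded in `$failures`; the study continues.
#' More than 20% failed arms raises a warning and sets `$ok = FALSE`.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory: writes `trajectories.csv`,
#'   `outcomes.csv`, `summary.csv` and per-network pre-treatment snapshots.
#' @param progress Print per-network progress.
#' @return An `lvr_study`: `trajectories`, `networks` (per-network beta and
#'   responder class), `outcomes`, `summary`, `failures`, `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      progress = FALSE) {
  cfg <- config
  all_traj <- list(); all_out <- list(); net_meta <- list(); fails <- list()
  snapshots <- list()
  for (i in seq_len(cfg$n_networks)) {
    if (progress) message(sprintf("network %d/%d", i, cfg$n_networks))
    seed_i <- derive_seed(cfg$master_seed, "net", i)
    net0 <- build_hexagonal_network(cfg$hex_rows, cfg$hex_cols, cfg$params,
                                    cfg$gravity_g, seed = seed_i)
    pre <- run_progression(net0, cfg$rule,
                           seed = derive_seed(cfg$master_seed, "pre", i),
                           n_stages = cfg$rule$n_stages,
                           resolution = cfg$resolution,
                           schedule = cfg$schedule)
    pre_net <- pre$networks[[length(pre$networks)]]
    y_line <- lvrs_line(pre_net, cfg$lvrs)
    map_pre <- rasterize_airspaces(pre_net, cfg$resolution, line_y = y_line)
    beta <- tryCatch(beta_index(map_pre, y_line),
                     lvr_metric_error = function(e) NA_real_)
    cls <- classify_responder(beta, cfg$beta_threshold)
    cum_pre <- tail(pre$stages$cumulative_broken, 1)
    C_pct_pre <- tail(pre$stages$C_pct, 1)
    net_meta[[i]] <- tibble(network = i, seed = seed_i, beta = beta,
                            responder = cls, cumulative_pre = cum_pre,
                            C_pct_pre = C_pct_pre)
    all_traj[[length(all_traj) + 1]] <-
      mutate(pre$stages, network = i, arm = "untreated", .before = 1)
    snapshots[[i]] <- pre_net

    regions <- tryCatch(
      select_affected_regions(pre_net, map_pre, cfg$blvr),
      warning = function(w) structure(list(), labels = integer()))

    arms <- c("untreated", "lvrs",
              paste0("blvr_", round(cfg$blvr_targets * 100)))
    treat_of <- c(NA, NA, cfg$blvr_targets)
    for (ai in seq_along(arms)) {
      arm <- arms[ai]
      res <- tryCatch({
        arm_df <- NULL
        if (arm == "untreated") {
          arm_df <- pre$stages
        } else {
          treated <- if (arm == "lvrs") {
            apply_lvrs(pre_net, cfg$lvrs, schedule = cfg$schedule)
          } else {
            spec <- cfg$blvr; spec$target_fraction <- treat_of[ai]
            apply_blvr(pre_net, regions, spec, schedule = cfg$schedule)
          }
          atr <- extend_progression(treated, cfg$rule, pre$baseline,
                                    seed = derive_seed(cfg$master_seed, arm, i),
                                    n_stages = cfg$post_stages,
                                    cumulative_start = cum_pre,
                                    resolution = cfg$resolution,
                                    schedule = cfg$schedule,
                                    first_label = arm)
          arm_df <- atr$stages
          all_traj[[length(all_traj) + 1]] <-
            mutate(arm_df, network = i, arm = arm, .before = 1)
        }
        arm_outcomes(arm, arm_df, pre$stages, beta, cfg, C_pct_pre, cum_pre)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1]] <- tibble(network = i, arm = arm,
                                             message = conditionMessage(res))
      } else {
        all_out[[length(all_out) + 1]] <-
          mutate(res, network = i, beta = beta, responder = cls, .before = 1)
      }
    }
  }
  networks <- bind_rows(net_meta)
  outcomes <- bind_rows(all_out)
  failures <- if (length(fails)) bind_rows(fails) else
    tibble(network = integer(), arm = character(), message = character())
  n_arm_total <- cfg$n_networks * (2 + length(cfg$blvr_targets))
  ok <- nrow(failures) <= 0.2 * n_arm_total
  if (!ok) warn(sprintf("%d of %d study arms failed", nrow(failures), n_arm_total))
  study <- structure(list(
    trajectories = bind_rows(all_traj), networks = networks,
    outcomes = outcomes, summary = summarize_groups(outcomes),
    failures = failures, snapshots = snapshots, config = cfg, ok = ok),
    class = "lvr_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.lvr_study <- function(x, ...) {
  cat(sprintf("<lvr_study> %d networks (%d responders), arms: %s\n",
              x$config$n_networks,
              sum(x$networks$responder == "responder", na.rm = TRUE),
              paste(unique(x$outcomes$arm), collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' Group summary statistics of study outcomes
#'
#' Mean, SD and n per (responder class, arm, metric), plus the pooled
#' all-network groups. Survival ratios and relative benefit are already
#' normalized so the untreated arm is 1 by construction.
#'
#' @param outcomes The `outcomes` tibble of an `lvr_study`.
#' @return A long summary tibble (group, arm, metric, mean, sd, n).
#' @export
summarize_groups <- function(outcomes) {
  if (nrow(outcomes) == 0) {
    warn("no outcomes to summarize")
    return(tibble(group = character(), arm = character(), metric = character(),
                  mean = numeric(), sd = numeric(), n = integer()))
  }
  metrics <- c("immediate_dC", "failure_rate", "survival_broken",
               "survival_ratio", "relative_benefit", "skew_pre", "skew_post")
  long <- tidyr::pivot_longer(
    select(outcomes, "responder", "arm", dplyr::all_of(metrics)),
    dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  long <- filter(long, !is.na(.data$value))
  by_group <- long |>
    group_by(group = .data$responder, .data$arm, .data$metric) |>
    summarise(mean = mean(.data$value),
              sd = if (n() > 1) sd(.data$value) else 0,
              n = n(), .groups = "drop")
  pooled <- long |>
    group_by(group = "all", .data$arm, .data$metric) |>
    summarise(mean = mean(.data$value),
              sd = if (n() > 1) sd(.data$value) else 0,
              n = n(), .groups = "drop")
  arrange(bind_rows(pooled, by_group), .data$metric, .data$arm, .data$group)
}

#' Power-law relation between post-bLVR compliance and force heterogeneity
#'
#' Pools the immediate post-bLVR states of every network and reduction
#' target and fits `C ~ CV_force^exponent` (see
#' [fit_compliance_cvforce()]).
#'
#' @param study An `lvr_study`.
#' @return An `lvr_powerfit`.
#' @export
study_cvforce_fit <- function(study) {
  d <- filter(study$outcomes, grepl("^blvr", .data$arm),
              is.finite(.data$compliance_post), is.finite(.data$cv_force_post))
  fit_compliance_cvforce(d$compliance_post, d$cv_force_post)
}

#' Write study outputs to a directory
#'
#' Writes `trajectories.csv`, `outcomes.csv`, `summary.csv`,
#' `networks.csv`, and the per-network pre-treatment snapshots as JSON.
#'
#' @param study An `lvr_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(study$trajectories, file.path(dir, "trajectories.csv"))
  readr::write_csv(study$outcomes, file.path(dir, "outcomes.csv"))
  readr::write_csv(study$summary, file.path(dir, "summary.csv"))
  readr::write_csv(study$networks, file.path(dir, "networks.csv"))
  for (i in seq_along(study$snapshots)) {
    write_network(study$snapshots[[i]],
                  file.path(dir, sprintf("network_%02d_pretreat.json", i)))
  }
  invisible(dir)
}
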