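#' Read a study configuration from YAML or JSON
#'
#' Sections `lattice`, `gravity`, `annealing`, `disease`, `interventions`,
#' `metrics`, `outcomes`, and `seeds` map onto the corresponding
#' [study_config()] fields; omitted entries keep the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  g <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  defaults <- study_config()
  params <- spring_params(
    mean_k = g("lattice", "mean_k", 1.0), sd_k = g("lattice", "sd_k", 0.4),
    mean_l0 = g("lattice", "mean_l0", 0.5), sd_l0 = g("lattice", "sd_l0", 0.1))
  sched_args <- raw$annealing %||% list()
  schedule <- do.call(annealing_schedule, sched_args)
  study_config(
    n_networks = g("experiment", "n_networks", defaults$n_networks),
    hex_rows = g("lattice", "hex_rows", defaults$hex_rows),
    hex_cols = g("lattice", "hex_cols", defaults$hex_cols),
    params = params,
    gravity_g = g("gravity", "g", defaults$gravity_g),
    rule = rupture_rule(
      init_fraction = g("disease", "init_fraction", 0.04),
      top_fraction = g("disease", "top_fraction", 0.007),
      p_break = g("disease", "p_break", 0.40),
      n_stages = g("disease", "n_stages", 5L)),
    lvrs = lvrs_spec(g("interventions", "resect_fraction", 0.30)),
    blvr_targets = g("interventions", "blvr_targets", defaults$blvr_targets),
    blvr = blvr_spec(
      min_area_factor = g("interventions", "min_area_factor", 10),
      max_regions = g("interventions", "max_regions", 3L)),
    post_stages = g("experiment", "post_stages", defaults$post_stages),
    resolution = g("metrics", "resolution", defaults$resolution),
    schedule = schedule,
    beta_threshold = g("outcomes", "beta_threshold", 3.5),
    threshold_pct = g("outcomes", "threshold_pct", 60),
    master_seed = g("seeds", "master_seed", 1L))
}
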