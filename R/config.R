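#' Default configuration
#'
#' Every tunable named in the package (block geometry, feature binning,
#' network training, GA operators, graph-cut energy, phantom rendering)
#' lives in one nested list so a single YAML file can override any of it.
#'
#' @return nested list of defaults
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$blocks$block_size
default_config <- function() {
  list(
    blocks = list(
      block_size   = 32L,   # square block edge, px
      overlap_step = 16L,   # sliding stride, px
      aggregate    = "mean" # "mean" probability averaging or "vote"
    ),
    features = list(
      hist_bins  = 32L, # entropy histogram bins
      glcm_levels = 8L  # co-occurrence quantization levels
    ),
    bpnn = list(
      n_hidden      = 6L,   # block-head hidden nodes (5-class problem)
      balance_per_class = 1200L, # class-rebalanced training rows per class
      learning_rate = 0.5,
      max_epochs    = 200L,
      error_goal    = 1e-3,
      mode          = "online", # or "batch"
      momentum      = 0,
      weight_decay  = 0
    ),
    ga = list(
      population_size        = 40L,
      max_generations        = 60L,
      n_fitness_groups       = 4L,
      gmm_offspring_fraction = 0.3,
      gmm_components         = 2L,
      crossover_rate         = 0.8,
      mutation_rate          = 0.05,
      mutation_sd            = 0.1,
      pressure               = 1.8,
      plateau_window         = 20L,
      plateau_tol            = 1e-6,
      elitism_count          = 1L,
      init_range             = c(-0.5, 0.5)
    ),
    graphcut = list(
      lambda = 1.0,          # module-level default smoothness weight
      lambda_grid = c(1, 2, 5, 10), # pipeline selects on the training set
      sigma  = 0.1,          # intensity-similarity scale
      enabled = TRUE
    ),
    phantom = list(
      size        = 256L,
      background  = 0.40,
      air_level   = 0.05,
      fluid_level = 0.85,
      noise_sd    = 0.05
    )
  )
}

#' Load configuration from YAML, merged over the defaults
#'
#' @param path YAML file; keys mirror [default_config()]
#' @return merged configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  check(file.exists(path), sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}
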