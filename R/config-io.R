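#' Read a simulation configuration from YAML
#'
#' Builds a [simulation_config()] from a YAML file. Top-level keys map to
#' the `simulation_config()` arguments (`lunch_duration`,
#' `pr_unsatisfied`, `ef_prob`, `repetitions`, `walking_delay`, `seed`,
#' `ideal_mode`); the blocks `menu:`, `population:`, `waste_fractions:` and
#' `competitive:` override fields of the corresponding sub-configuration.
#' Menu component distributions are given as
#' `{family, location, scale, bounds: [min, max]}`; unknown family names
#' are rejected at load. Omitted keys keep their defaults, so a minimal
#' scenario file needs only the fields it changes.
#'
#' @param path Path to a YAML file. See
#'   `system.file("extdata", "default-config.yaml", package = "platewaste")`
#'   for a full example.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a YAML mapping.")

  as_dist <- function(x, nm) {
    if (!is.list(x) || is.null(x$family)) {
      stop("distribution for '", nm,
           "' must be a mapping with at least a `family` key.")
    }
    component_dist(x$family, x$location,
                   scale = x$scale %||% NA_real_,
                   bounds = if (is.null(x$bounds)) c(-Inf, Inf)
                            else as.numeric(x$bounds))
  }
  as_frac <- function(x, nm) {
    if (!is.list(x) || is.null(x$family)) {
      stop("waste fraction for '", nm, "' must have a `family` key.")
    }
    if (x$family == "constant") list("constant", x$location)
    else list(x$family, x$location, x$scale)
  }

  menu <- menu_config()
  if (!is.null(raw$menu)) {
    m <- raw$menu
    args <- list()
    if (!is.null(m$menu_probs)) args$menu_probs <- unlist(m$menu_probs)
    if (!is.null(m$bread_prob)) args$bread_prob <- m$bread_prob
    if (!is.null(m$dessert_probs)) args$dessert_probs <- unlist(m$dessert_probs)
    if (!is.null(m$optional_probs)) {
      args$optional_probs <- unlist(m$optional_probs)
    }
    comps <- menu$components
    for (nm in intersect(names(m$components %||% list()), meal_components())) {
      comps[[nm]] <- as_dist(m$components[[nm]], nm)
    }
    args$components <- comps
    if (!is.null(m$joint_ms)) {
      args$joint_ms <- list(m = as_dist(m$joint_ms$m, "joint_ms$m"),
                            s = as_dist(m$joint_ms$s, "joint_ms$s"))
    }
    if (!is.null(m$joint_d)) {
      args$joint_d <- list(sd = as_dist(m$joint_d$sd, "joint_d$sd"),
                           ld = as_dist(m$joint_d$ld, "joint_d$ld"))
    }
    menu <- do.call(menu_config, args)
  }

  pop_args <- raw$population %||% list()
  population <- do.call(population_config, pop_args)

  waste <- waste_fraction_config()
  if (!is.null(raw$waste_fractions)) {
    w <- raw$waste_fractions
    fr <- waste$fractions
    for (nm in intersect(names(w$fractions %||% list()), meal_components())) {
      fr[[nm]] <- as_frac(w$fractions[[nm]], nm)
    }
    waste <- waste_fraction_config(
      fractions = fr,
      soup_skip_prob = w$soup_skip_prob %||% waste$soup_skip_prob,
      main_skip_prob = w$main_skip_prob %||% waste$main_skip_prob,
      skips_on_hated_days_only = w$skips_on_hated_days_only %||%
        waste$skips_on_hated_days_only
    )
  }

  competitive <- competitive_config()
  if (!is.null(raw$competitive)) {
    ct <- raw$competitive
    competitive <- competitive_config(
      k_values = unlist(ct$k_values %||% competitive$k_values),
      k_sd = ct$k_sd %||% competitive$k_sd,
      semantics = ct$semantics %||% competitive$semantics,
      complement_weights = unlist(ct$complement_weights %||%
                                    competitive$complement_weights)
    )
  }

  simulation_config(
    lunch_duration = raw$lunch_duration %||% 25,
    pr_unsatisfied = raw$pr_unsatisfied %||% 0.27,
    ef_prob = raw$ef_prob %||% 0.30,
    repetitions = raw$repetitions %||% 10000,
    walking_delay = raw$walking_delay %||% 6,
    seed = raw$seed,
    ideal_mode = raw$ideal_mode %||% FALSE,
    menu = menu, population = population, waste = waste,
    competitive = competitive
  )
}
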