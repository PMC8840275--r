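# Portion components, in eating order: main part (m, s), dessert (sd, ld),
# optional items (b, fp, mk). Liquids are drunk at the liquid rate.
meal_components <- function() c("m", "s", "sd", "ld", "b", "fp", "mk")
liquid_components <- function() c("s", "ld", "mk")

#' Menu-generation configuration
#'
#' Distribution parameters and category probabilities for generating daily
#' lunch portions. A portion is the sum of seven components (Eq.:
#' `p = m + s + sd + ld + b + fp + mk`): main dish, soup, solid dessert,
#' liquid dessert (a drink such as juice or sweet tea), bread, fresh
#' product, and milk.
#'
#' The main part follows the regulated menu types: main dish and soup (MS,
#' which uses its own joint pair of distributions), main dish and dessert
#' (MD), or soup and dessert (SD). A dessert is always generated, its type
#' (solid / liquid / both) uniform; bread is added with probability 1/2;
#' exactly one of fresh product, milk, or neither is added (1/3 each).
#'
#' @param menu_probs Named probabilities for menu types `MS`, `MD`, `SD`;
#'   must sum to 1.
#' @param bread_prob Probability that bread is served.
#' @param dessert_probs Probabilities for dessert type
#'   `c(solid, liquid, both)`; must sum to 1.
#' @param optional_probs Probabilities for the optional part
#'   `c(fresh, milk, none)`; must sum to 1.
#' @param components Named list of [component_dist()] objects for the seven
#'   marginal components `m, s, sd, ld, b, fp, mk`.
#' @param joint_ms [component_dist()] pair (`m`, `s`) used when the menu
#'   type is MS.
#' @param joint_d [component_dist()] pair (`sd`, `ld`) used when the dessert
#'   type is "both".
#' @return An object of class `menu_config`.
#' @export
menu_config <- function(menu_probs = c(MS = 0.65, MD = 0.30, SD = 0.05),
                        bread_prob = 0.5,
                        dessert_probs = c(solid = 1 / 3, liquid = 1 / 3,
                                          both = 1 / 3),
                        optional_probs = c(fresh = 1 / 3, milk = 1 / 3,
                                           none = 1 / 3),
                        components = list(
                          m  = component_dist("gumbel", 225, 37.5, c(150, 430)),
                          s  = component_dist("normal", 225, 37.5, c(150, 300)),
                          sd = component_dist("normal", 75, 12.5, c(50, 100)),
                          ld = component_dist("normal", 200, 25, c(150, 250)),
                          b  = component_dist("exponential", 20, 1.2, c(20, 35)),
                          fp = component_dist("normal", 75, 12.5, c(50, 100)),
                          mk = component_dist("constant", 200)
                        ),
                        joint_ms = list(
                          m = component_dist("normal", 200, 25, c(150, 250)),
                          s = component_dist("normal", 175, 12.5, c(150, 200))
                        ),
                        joint_d = list(
                          sd = component_dist("normal", 32.5, 8.75, c(15, 50)),
                          ld = component_dist("normal", 150, 25, c(100, 200))
                        )) {
  check_probs <- function(p, nm, labels) {
    if (!is.numeric(p) || length(p) != length(labels) ||
        any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
      stop("`", nm, "` must be ", length(labels),
           " probabilities in [0,1] summing to 1.")
    }
    stats::setNames(as.numeric(p), labels)
  }
  menu_probs <- check_probs(menu_probs, "menu_probs", c("MS", "MD", "SD"))
  dessert_probs <- check_probs(dessert_probs, "dessert_probs",
                               c("solid", "liquid", "both"))
  optional_probs <- check_probs(optional_probs, "optional_probs",
                                c("fresh", "milk", "none"))
  if (!is.numeric(bread_prob) || bread_prob < 0 || bread_prob > 1) {
    stop("`bread_prob` must be a probability in [0,1].")
  }
  stopifnot(all(meal_components() %in% names(components)))
  lapply(components, function(d) stopifnot(inherits(d, "component_dist")))
  structure(list(menu_probs = menu_probs, bread_prob = bread_prob,
                 dessert_probs = dessert_probs,
                 optional_probs = optional_probs, components = components,
                 joint_ms = joint_ms, joint_d = joint_d),
            class = "menu_config")
}

#' Draw menu types
#'
#' Categorical draw of the regulated lunch composition: `MS` (main dish and
#' soup), `MD` (main dish and dessert) or `SD` (soup and dessert).
#'
#' @param n Number of draws.
#' @param cfg A [menu_config()].
#' @return Character vector of length `n` with values in
#'   `c("MS", "MD", "SD")`.
#' @export
draw_menu_type <- function(n = 1, cfg = menu_config()) {
  stopifnot(inherits(cfg, "menu_config"))
  sample(names(cfg$menu_probs), n, replace = TRUE, prob = cfg$menu_probs)
}

#' Generate daily lunch portions
#'
#' Draws `n` independent daily portions: the main part according to the menu
#' type, a dessert (type uniform among solid / liquid / both, the "both"
#' case using its joint pair of distributions), bread with probability 1/2,
#' and exactly one of fresh product / milk / neither. Components that are
#' not served are 0 g.
#'
#' @param n Number of portions.
#' @param cfg A [menu_config()].
#' @param menu_type Optional fixed menu type (`"MS"`, `"MD"` or `"SD"`)
#'   overriding the categorical draw, e.g. to inspect one branch.
#' @return A tibble with `n` rows and columns `m, s, sd, ld, b, fp, mk`
#'   (grams).
#' @examples
#' generate_portions(3)
#' @export
generate_portions <- function(n, cfg = menu_config(), menu_type = NULL) {
  stopifnot(inherits(cfg, "menu_config"), n >= 1)
  P <- matrix(0, nrow = n, ncol = 7,
              dimnames = list(NULL, meal_components()))

  k <- if (is.null(menu_type)) {
    draw_menu_type(n, cfg)
  } else {
    rep(match.arg(menu_type, c("MS", "MD", "SD")), n)
  }
  i_ms <- which(k == "MS"); i_md <- which(k == "MD"); i_sd <- which(k == "SD")
  if (length(i_ms)) {
    P[i_ms, "m"] <- draw_component(cfg$joint_ms$m, length(i_ms))
    P[i_ms, "s"] <- draw_component(cfg$joint_ms$s, length(i_ms))
  }
  if (length(i_md)) P[i_md, "m"] <- draw_component(cfg$components$m, length(i_md))
  if (length(i_sd)) P[i_sd, "s"] <- draw_component(cfg$components$s, length(i_sd))

  d <- sample(names(cfg$dessert_probs), n, replace = TRUE,
              prob = cfg$dessert_probs)
  i_s <- which(d == "solid"); i_l <- which(d == "liquid"); i_b <- which(d == "both")
  if (length(i_s)) P[i_s, "sd"] <- draw_component(cfg$components$sd, length(i_s))
  if (length(i_l)) P[i_l, "ld"] <- draw_component(cfg$components$ld, length(i_l))
  if (length(i_b)) {
    P[i_b, "sd"] <- draw_component(cfg$joint_d$sd, length(i_b))
    P[i_b, "ld"] <- draw_component(cfg$joint_d$ld, length(i_b))
  }

  has_b <- which(stats::runif(n) < cfg$bread_prob)
  if (length(has_b)) P[has_b, "b"] <- draw_component(cfg$components$b, length(has_b))

  o <- sample(names(cfg$optional_probs), n, replace = TRUE,
              prob = cfg$optional_probs)
  i_fp <- which(o == "fresh"); i_mk <- which(o == "milk")
  if (length(i_fp)) P[i_fp, "fp"] <- draw_component(cfg$components$fp, length(i_fp))
  if (length(i_mk)) P[i_mk, "mk"] <- draw_component(cfg$components$mk, length(i_mk))

  tibble::as_tibble(as.data.frame(P))
}

#' @rdname generate_portions
#' @export
generate_portion <- function(cfg = menu_config(), menu_type = NULL) {
  generate_portions(1, cfg, menu_type = menu_type)
}

#' Generate a week menu
#'
#' Five independent daily portions, Monday to Friday. The simulation's time
#' unit is one school week; no weekday effect is modelled.
#'
#' @param cfg A [menu_config()].
#' @return A tibble with 5 rows, a `day` column (`Mon`..`Fri`) and the seven
#'   component columns in grams.
#' @export
generate_week <- function(cfg = menu_config()) {
  dplyr::bind_cols(
    tibble::tibble(day = c("Mon", "Tue", "Wed", "Thu", "Fri")),
    generate_portions(5, cfg)
  )
}

#' Total portion mass
#'
#' Sums the seven portion components, `p = m + s + sd + ld + b + fp + mk`.
#'
#' @param portions A data frame with the seven component columns (extra
#'   columns such as `day` are ignored).
#' @return Numeric vector of portion masses in grams, one per row.
#' @examples
#' portion_mass(observed_week_menu) # Table of monitored school menus
#' @export
portion_mass <- function(portions) {
  stopifnot(is.data.frame(portions),
            all(meal_components() %in% names(portions)))
  rowSums(as.matrix(portions[meal_components()]))
}

#' Monitored school week menu
#'
#' The lunch menu content observed during the field-study week, in grams per
#' component, with the printed total portion size `p`.
#'
#' @format A tibble with 5 rows (Mon--Fri) and columns `day`, `m`, `s`,
#'   `sd`, `ld`, `b`, `fp`, `mk`, `p`.
#' @export
observed_week_menu <- tibble::tibble(
  day = c("Mon", "Tue", "Wed", "Thu", "Fri"),
  m   = c(300, 205, 230, 230, 240),
  s   = c(0, 0, 255, 0, 125),
  sd  = c(40, 180, 0, 180, 0),
  ld  = c(210, 200, 200, 200, 200),
  b   = c(25, 25, 25, 25, 25),
  fp  = c(0, 25, 30, 30, 0),
  mk  = c(0, 0, 0, 0, 0),
  p   = c(575, 635, 740, 665, 590)
)
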