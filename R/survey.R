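#' Parent-survey answers on competitive-food sources
#'
#' Shares of survey answers (percent) on whether children eat competitive
#' food, by source: food brought from home, the school's optional
#' (a-la-carte) menu, and purchases outside the school.
#'
#' @format A tibble with 3 rows and columns `source`, `yes`, `no`,
#'   `sometimes` (percent).
#' @export
competitive_food_survey <- tibble::tibble(
  source = c("home_food", "school_optional_menu", "outside_school"),
  yes = c(12.5, 33.3, 16.7),
  no = c(75.0, 45.8, 54.2),
  sometimes = c(12.5, 20.8, 29.2)
)

#' Children's stable food dislikes
#'
#' Survey shares of children who never eat a served category: half do not
#' eat soup, 8% do not eat the main dish, none refuse sweet drinks. These
#' feed the every-day soup/main skips of the rejected-food stage.
#'
#' @format A tibble with columns `category` and `do_not_eat` (probability).
#' @export
food_preference_survey <- tibble::tibble(
  category = c("soup", "main_dish", "sweet_drinks"),
  do_not_eat = c(0.50, 0.08, 0.00)
)

#' Aggregate the competitive-food probability from the survey
#'
#' Averages one answer column of the competitive-food survey across the
#' three sources. The mean of the "yes" shares gives the headline
#' competitive-food probability (20.83%, printed as 21.0% when rounded).
#'
#' @param survey A survey tibble shaped like [competitive_food_survey].
#' @param answer Which answer column to average (default `"yes"`).
#' @return The mean share in percent.
#' @examples
#' round(competitive_food_probability()) # 21
#' @export
competitive_food_probability <- function(survey = competitive_food_survey,
                                         answer = c("yes", "sometimes",
                                                    "no")) {
  answer <- match.arg(answer)
  stopifnot(is.data.frame(survey), answer %in% names(survey))
  mean(survey[[answer]])
}
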