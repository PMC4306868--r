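# Range validation shared by the measure constructors: out-of-range values
# become NA so that missingness propagates instead of silently miscoding.
check_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi | x != floor(x))
  if (any(bad)) {
    warning(sum(bad), " out-of-range ", what, " value(s) set to missing")
    x[bad] <- NA
  }
  x
}

#' Meal deprivation: proportion of weekly meals skipped
#'
#' From the number of days in the past week on which breakfast, lunch and
#' dinner were eaten (each 0--7), returns the proportion of the 21 possible
#' meals that were *not* eaten.  0 means no meal skipped, 1 means every meal
#' skipped.  Missing or out-of-range inputs yield a missing result.
#'
#' @param breakfast_days,lunch_days,dinner_days Integer vectors, 0--7.
#' @return Numeric vector of proportions in \[0, 1\].
#' @examples
#' meal_deprivation(7, 7, 7)  # 0
#' meal_deprivation(0, 7, 7)  # 7/21
#' @export
meal_deprivation <- function(breakfast_days, lunch_days, dinner_days) {
  b <- check_range(breakfast_days, 0, 7, "breakfast-day")
  l <- check_range(lunch_days, 0, 7, "lunch-day")
  d <- check_range(dinner_days, 0, 7, "dinner-day")
  ((7 - b) + (7 - l) + (7 - d)) / 21
}

#' Low vegetable consumption indicator
#'
#' Codes 1 for respondents who ate none of the twelve vegetables asked about
#' on the previous day, 0 for respondents who ate any.  Any observed "ate"
#' flag forces 0 regardless of missingness elsewhere; if all observed flags
#' are 0 but some are missing, the result is missing (consumption cannot be
#' ruled out).
#'
#' @param veg_flags A matrix or data frame with 12 binary (0/1) columns, one
#'   row per respondent; a bare vector of length 12 is treated as one
#'   respondent.
#' @return Integer vector of 0/1 indicators (NA where indeterminate).
#' @export
low_vegetable <- function(veg_flags) {
  if (is.null(dim(veg_flags))) veg_flags <- matrix(veg_flags, nrow = 1L)
  veg_flags <- as.matrix(veg_flags)
  if (ncol(veg_flags) != 12L)
    stop("expected 12 vegetable flags, got ", ncol(veg_flags))
  if (any(!is.na(veg_flags) & !(veg_flags %in% c(0, 1))))
    stop("vegetable flags must be 0, 1 or NA")
  any_ate <- apply(veg_flags, 1L, function(r) any(r == 1, na.rm = TRUE))
  any_na <- apply(veg_flags, 1L, anyNA)
  out <- ifelse(any_ate, 0L, ifelse(any_na, NA_integer_, 1L))
  as.integer(out)
}

#' Reverse-code a 4-level activity frequency category
#'
#' Activity items are recorded as 0 (not at all), 1 (1--2 times), 2 (3--4
#' times), 3 (5+ times a week); reverse coding (`3 - x`) makes higher scores
#' mean *less* frequent activity, so that the measure reads as a risk
#' factor.  Applying the function twice returns the original coding.
#'
#' @param category Integer vector with values in `0:3` (NA allowed).
#' @return Integer vector, `3 - category`.
#' @export
reverse_activity <- function(category) {
  if (any(!is.na(category) & !(category %in% 0:3)))
    stop("activity categories must lie in 0:3")
  as.integer(3L - category)
}

#' Insufficient-exercise indicator from three activity items
#'
#' Converts the raw (not reverse-coded) sport, cycling/skating and general
#' exercise frequency categories into approximate weekly bout counts, sums
#' them, and flags respondents with fewer than `threshold` total bouts —
#' the five-sessions-a-week guideline.  The default category-to-bout map
#' uses interval midpoints (0, 1.5, 3.5) and 5 for the open-ended top
#' category.  Any missing item yields a missing result.
#'
#' @param sport_cat,cycle_cat,exercise_cat Integer vectors in `0:3`
#'   (raw coding: higher = more frequent).
#' @param bouts_map Numeric length-4 map from category 0--3 to bout counts.
#' @param threshold Total-bout cutoff; the flag is 1 when the sum is
#'   strictly below it.
#' @return Integer vector of 0/1 indicators.
#' @examples
#' insufficient_exercise(0, 0, 0)  # 1: zero bouts
#' insufficient_exercise(3, 0, 0)  # 0: 5 bouts, not < 5
#' @export
insufficient_exercise <- function(sport_cat, cycle_cat, exercise_cat,
                                  bouts_map = c(0, 1.5, 3.5, 5),
                                  threshold = 5) {
  stopifnot(length(bouts_map) == 4L)
  for (x in list(sport_cat, cycle_cat, exercise_cat))
    if (any(!is.na(x) & !(x %in% 0:3)))
      stop("activity categories must lie in 0:3")
  total <- bouts_map[sport_cat + 1L] + bouts_map[cycle_cat + 1L] +
    bouts_map[exercise_cat + 1L]
  as.integer(total < threshold)
}

#' Build the seven derived nutrition and activity measures
#'
#' From a raw survey table with columns `fastfood_days`, `veg_1` ... `veg_12`,
#' `breakfast_days`, `lunch_days`, `dinner_days`, `sport_cat`, `cycle_cat`,
#' `exercise_cat` (raw codings), appends the derived columns `fast_food`,
#' `low_veg`, `meal_dep`, `low_sport`, `low_cycle`, `low_exercise`,
#' `insuff_ex` to the identifier columns.  Fast-food days pass through after
#' range validation; missing inputs propagate to missing outputs (no
#' imputation), matching listwise-deletion workflows.
#'
#' @param raw Data frame of raw survey items, one row per twin, including
#'   identifier columns `pair_id`, `twin_index`, `zygosity` and (optionally)
#'   `outcome`.
#' @param bouts_map,threshold Passed to [insufficient_exercise()].
#' @return Data frame with the identifier columns plus the seven derived
#'   measures.
#' @export
add_measures <- function(raw, bouts_map = c(0, 1.5, 3.5, 5), threshold = 5) {
  veg_cols <- paste0("veg_", 1:12)
  need <- c("fastfood_days", veg_cols, "breakfast_days", "lunch_days",
            "dinner_days", "sport_cat", "cycle_cat", "exercise_cat")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("raw survey table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  ids <- intersect(c("pair_id", "twin_index", "zygosity", "outcome"),
                   names(raw))
  out <- raw[ids]
  out$fast_food <- check_range(raw$fastfood_days, 0, 7, "fast-food-day")
  out$low_veg <- low_vegetable(raw[veg_cols])
  out$meal_dep <- meal_deprivation(raw$breakfast_days, raw$lunch_days,
                                   raw$dinner_days)
  out$low_sport <- reverse_activity(raw$sport_cat)
  out$low_cycle <- reverse_activity(raw$cycle_cat)
  out$low_exercise <- reverse_activity(raw$exercise_cat)
  out$insuff_ex <- insufficient_exercise(raw$sport_cat, raw$cycle_cat,
                                         raw$exercise_cat,
                                         bouts_map = bouts_map,
                                         threshold = threshold)
  out
}
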