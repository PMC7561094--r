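#' The 6-category subjective risk scale
#'
#' Perioperative teams estimate each patient's risk of death within 30 days of
#' surgery on an ordered categorical scale with six interval response options:
#' <1%, 1%--2.5%, 2.6%--5%, 5.1%--10%, 10.1%--50% and >50%. When a point
#' estimate of risk is needed (calibration plots, net reclassification,
#' decision curves) each category is represented by the midpoint of its
#' interval: 0.5%, 1.75%, 3.8%, 7.55%, 30.05% and, for the open-ended top
#' category, a configurable midpoint defaulting to 75% (the arithmetic
#' midpoint of 50--100%).
#'
#' @param top_midpoint Midpoint in percent assigned to the open-ended ">50%"
#'   category. Must lie strictly inside (50, 100).
#'
#' @return An object of class `subjective_scale`: a data frame with one row
#'   per category and columns `category`, `label`, `lower`, `upper` (interval
#'   bounds in percent) and `midpoint` (percent).
#'
#' @examples
#' sc <- subjective_scale()
#' midpoint_of(1:6, sc)
#' @export
subjective_scale <- function(top_midpoint = 75) {
  stopifnot(is.numeric(top_midpoint), length(top_midpoint) == 1L)
  if (!(top_midpoint > 50 && top_midpoint < 100)) {
    stop("`top_midpoint` must lie strictly inside the >50% interval (50, 100)")
  }
  sc <- data.frame(
    category = 1:6,
    label    = c("<1%", "1%-2.5%", "2.6%-5%", "5.1%-10%", "10.1%-50%", ">50%"),
    lower    = c(0, 1, 2.6, 5.1, 10.1, 50),
    upper    = c(1, 2.5, 5, 10, 50, 100),
    midpoint = c(0.5, 1.75, 3.8, 7.55, 30.05, top_midpoint),
    stringsAsFactors = FALSE
  )
  # invariants: strictly increasing midpoints, each inside its interval
  stopifnot(all(diff(sc$midpoint) > 0),
            all(sc$midpoint >= sc$lower & sc$midpoint <= sc$upper))
  class(sc) <- c("subjective_scale", "data.frame")
  sc
}

#' Midpoint risk of a subjective category
#'
#' @param category Integer vector of categories in 1..6.
#' @param scale A [subjective_scale()] object.
#' @return Numeric vector of interval midpoints, in percent.
#' @export
midpoint_of <- function(category, scale = subjective_scale()) {
  stopifnot(inherits(scale, "subjective_scale"))
  category <- as.integer(category)
  if (any(is.na(category)) || any(category < 1L | category > 6L)) {
    stop("`category` must be an integer in 1..6 with no missing values")
  }
  scale$midpoint[category]
}

#' Bin continuous risks into subjective categories
#'
#' Assigns a probability (on the 0--1 scale) to the subjective category whose
#' interval contains it. The published intervals have small typographical gaps
#' (2.5% vs 2.6%); for binning a continuous probability the upper bound of
#' each interval is used as the cut point, so e.g. 3% falls in "2.6%-5%".
#'
#' @param p Numeric vector of probabilities in [0, 1].
#' @param scale A [subjective_scale()] object.
#' @return Integer vector of categories in 1..6.
#' @export
bin_risk <- function(p, scale = subjective_scale()) {
  stopifnot(inherits(scale, "subjective_scale"))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("`p` must be probabilities in [0, 1]")
  }
  cuts <- scale$upper[-nrow(scale)] / 100  # 0.01, 0.025, 0.05, 0.10, 0.50
  findInterval(p, cuts, left.open = TRUE) + 1L
}
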