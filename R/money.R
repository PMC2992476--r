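#' Round money values half-up
#'
#' Conventional ("commercial") rounding: exact halves round away from zero,
#' so `money_round(0.125)` is `0.13`, not the `0.12` that banker's rounding
#' (and base [round()]) would give. All displayed dollar amounts in this
#' package go through this function; internal arithmetic keeps full double
#' precision so that sums are associative and itemized components reconcile
#' with totals before rounding.
#'
#' @param x numeric vector of dollar amounts (or percentages).
#' @param digits decimal places to keep; 2 (cents) by default.
#' @return numeric vector rounded half-up to `digits` places.
#' @details A guard of 1e-9 is added before truncation so that values such as
#'   `2.675`, which binary floating point stores as `2.67499999...`, round the
#'   way their decimal reading demands. The guard is far below the half-cent
#'   conservation tolerance used throughout, so it can never flip a
#'   genuinely-below-half value upward at money magnitudes.
#' @examples
#' money_round(c(79.5454545, 0.125, 2.675))
#' money_round(11.1111, digits = 0) # attrition percentage to whole percent
#' @export
money_round <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format money for display
#'
#' @param x numeric vector of dollar amounts.
#' @param digits decimal places (default 2).
#' @return character vector with exactly `digits` decimals, half-up rounded.
#' @examples
#' money_format(1750 / 22) # "79.55"
#' @export
money_format <- function(x, digits = 2L) {
  sprintf(paste0("%.", digits, "f"), money_round(x, digits))
}

#' Annualize a capital asset purchase
#'
#' Converts a one-off equipment purchase into an equivalent yearly cost over
#' its useful life, scaled by the share of the year the asset serves this
#' activity. With a zero discount rate this is straight-line depreciation,
#' `price / lifespan * share`; with a positive rate it is the equivalent
#' annual cost from the annuity formula
#' `price * r / (1 - (1 + r)^-lifespan) * share`.
#'
#' @param purchase_price non-negative purchase price in dollars.
#' @param lifespan_years useful life in years; must be positive.
#' @param utilization_share fraction of the asset's annual service attributed
#'   to this activity, in (0, 1]. Default 1.
#' @param discount_rate annual discount rate, >= 0. Default 0 (straight-line).
#' @return annual cost in dollars (unrounded).
#' @examples
#' annualize_asset(1000, 5)                      # 200
#' annualize_asset(1000, 5, utilization_share = 0.1) # 20
#' money_round(annualize_asset(1000, 5, discount_rate = 0.03)) # 218.35
#' @export
annualize_asset <- function(purchase_price, lifespan_years,
                            utilization_share = 1, discount_rate = 0) {
  purchase_price <- check_number(purchase_price, "purchase_price", min = 0)
  lifespan_years <- check_number(lifespan_years, "lifespan_years")
  if (lifespan_years <= 0) stop_invalid("`lifespan_years` must be positive")
  utilization_share <- check_number(utilization_share, "utilization_share",
                                    min = 0, max = 1)
  if (utilization_share == 0) stop_invalid("`utilization_share` must be in (0, 1]")
  discount_rate <- check_number(discount_rate, "discount_rate", min = 0)

  annual <- if (discount_rate == 0) {
    purchase_price / lifespan_years
  } else {
    purchase_price * discount_rate /
      (1 - (1 + discount_rate)^(-lifespan_years))
  }
  annual * utilization_share
}

#' Convert a monthly wage to an hourly wage
#'
#' Field data in this setting quote incomes per month. The package convention
#' is 30 days per month and 8 working hours per day, i.e. 240 paid hours per
#' month, so a $108/month salary is $0.45/hour.
#'
#' @param monthly_wage wage in dollars per month.
#' @param days_per_month working days per month (default 30).
#' @param hours_per_day working hours per day (default 8).
#' @return wage in dollars per hour.
#' @export
hourly_from_monthly <- function(monthly_wage, days_per_month = 30,
                                hours_per_day = 8) {
  monthly_wage <- check_number(monthly_wage, "monthly_wage", min = 0)
  monthly_wage / (days_per_month * hours_per_day)
}

#' Define a labour step
#'
#' A unit of work with a fixed per-run (per-batch, per-session or
#' per-shipment) time cost and a marginal per-specimen time cost, priced at
#' an hourly wage. The per-run minutes amortize over the batch, which is what
#' makes labour cost per specimen fall with batch size.
#'
#' @param name label for the step.
#' @param per_run_minutes minutes incurred once per run, >= 0.
#' @param per_specimen_minutes minutes incurred per specimen, >= 0.
#' @param hourly_wage wage in dollars per hour, >= 0.
#' @return an object of class `labour_step`.
#' @seealso [labour_step_cost()], [hourly_from_monthly()]
#' @export
labour_step <- function(name, per_run_minutes = 0, per_specimen_minutes = 0,
                        hourly_wage = 0) {
  structure(
    list(
      name = as.character(name)[1],
      per_run_minutes = check_number(per_run_minutes, "per_run_minutes", min = 0),
      per_specimen_minutes = check_number(per_specimen_minutes,
                                          "per_specimen_minutes", min = 0),
      hourly_wage = check_number(hourly_wage, "hourly_wage", min = 0)
    ),
    class = "labour_step"
  )
}

#' @export
print.labour_step <- function(x, ...) {
  cat(sprintf("<labour_step> %s: %.4g min/run + %.4g min/specimen @ $%s/h\n",
              x$name, x$per_run_minutes, x$per_specimen_minutes,
              money_format(x$hourly_wage)), sep = "")
  invisible(x)
}

#' Labour cost per specimen at a given batch size
#'
#' `(per_run_minutes / n + per_specimen_minutes) * hourly_wage / 60`:
#' non-increasing in `n`, approaching the pure marginal cost as the batch
#' grows.
#'
#' @param step a [labour_step()].
#' @param n batch size (specimens per run), >= 1. May be a vector.
#' @return dollars per specimen (unrounded), same length as `n`.
#' @examples
#' st <- labour_step("prep", per_run_minutes = 30, per_specimen_minutes = 2,
#'                   hourly_wage = 3)
#' labour_step_cost(st, 10) # 0.25
#' @export
labour_step_cost <- function(step, n) {
  if (!inherits(step, "labour_step")) stop_invalid("`step` must be a labour_step")
  if (!is.numeric(n) || length(n) < 1 || anyNA(n) || any(n < 1)) {
    stop_invalid("batch size `n` must be >= 1")
  }
  (step$per_run_minutes / n + step$per_specimen_minutes) * step$hourly_wage / 60
}
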