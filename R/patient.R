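#' Patient locations
#'
#' A table of places of residence within a collection site's catchment, one
#' row per location, with the per-visit cost inputs and the number of
#' patients travelling from there. `patient_location()` builds a single row;
#' `patient_locations()` validates a full table (for example one read from
#' CSV with [read_locations_csv()]).
#'
#' Columns: `name`, `distance_km`, `round_trip_fare`, `lodging_nights`,
#' `nightly_rate`, `food_cost_total`, `days_away`, `daily_wage`,
#' `patient_count`. Money fields are dollars; `days_away` may be fractional
#' (a half-day visit costs half a day's wage).
#'
#' @param name location label.
#' @param distance_km distance from home to the collection site, >= 0.
#' @param round_trip_fare transport fare there and back, dollars.
#' @param lodging_nights whole nights of accommodation, >= 0.
#' @param nightly_rate dollars per night.
#' @param food_cost_total dollars spent on food for the whole visit.
#' @param days_away days of work lost, >= 0, fractional allowed.
#' @param daily_wage dollars per day of lost income.
#' @param patient_count patients resident at this location, >= 0.
#' @return a `data.frame` with class `patient_locations`.
#' @export
patient_location <- function(name, distance_km = 0, round_trip_fare = 0,
                             lodging_nights = 0, nightly_rate = 0,
                             food_cost_total = 0, days_away = 0,
                             daily_wage = 0, patient_count = 1) {
  patient_locations(data.frame(
    name = as.character(name), distance_km = distance_km,
    round_trip_fare = round_trip_fare, lodging_nights = lodging_nights,
    nightly_rate = nightly_rate, food_cost_total = food_cost_total,
    days_away = days_away, daily_wage = daily_wage,
    patient_count = patient_count, stringsAsFactors = FALSE))
}

location_columns <- c("name", "distance_km", "round_trip_fare",
                      "lodging_nights", "nightly_rate", "food_cost_total",
                      "days_away", "daily_wage", "patient_count")

#' @rdname patient_location
#' @param locations a data frame with the columns listed above.
#' @export
patient_locations <- function(locations) {
  if (!is.data.frame(locations) || nrow(locations) < 1) {
    stop_invalid("`locations` must be a data frame with at least one row")
  }
  missing_cols <- setdiff(location_columns, names(locations))
  if (length(missing_cols)) {
    stop_invalid(paste("missing location columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  locations <- locations[location_columns]
  num_cols <- setdiff(location_columns, "name")
  for (cl in num_cols) {
    v <- locations[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      stop_invalid(sprintf("location column `%s` must be numeric and >= 0", cl))
    }
  }
  if (any(locations$lodging_nights != floor(locations$lodging_nights))) {
    stop_invalid("`lodging_nights` must be whole nights")
  }
  if (any(locations$patient_count != floor(locations$patient_count))) {
    stop_invalid("`patient_count` must be whole patients")
  }
  class(locations) <- c("patient_locations", "data.frame")
  locations
}

#' Catchment of a specimen collection site
#'
#' @param site_name label of the collection site.
#' @param locations a [patient_locations()] table (or coercible data frame).
#' @return an object of class `catchment`.
#' @export
catchment <- function(site_name, locations) {
  locations <- patient_locations(as.data.frame(locations))
  structure(list(site_name = as.character(site_name)[1],
                 locations = locations),
            class = "catchment")
}

#' @export
print.catchment <- function(x, ...) {
  cat(sprintf("<catchment> %s: %d location(s), %d patient(s)\n",
              x$site_name, nrow(x$locations), sum(x$locations$patient_count)))
  invisible(x)
}

#' Per-visit patient cost components
#'
#' Transportation is the round-trip fare; lodging is nights times nightly
#' rate; food is the per-visit food total; lost income is days away times the
#' daily wage. `visit_cost()` returns a [cost_breakdown()] for a single
#' location; `visit_cost_table()` computes all rows of a locations table at
#' once.
#'
#' @param location a single-row [patient_locations()] table (or a
#'   [patient_location()]).
#' @return `visit_cost()`: a `cost_breakdown` with components
#'   `transportation`, `lodging`, `food`, `lost_income`.
#' @examples
#' visit_cost(patient_location("near town", round_trip_fare = 0.42,
#'                             food_cost_total = 0.81, days_away = 0.26,
#'                             daily_wage = 3.50)) # total 2.14
#' @export
visit_cost <- function(location) {
  location <- patient_locations(as.data.frame(location))
  if (nrow(location) != 1) {
    stop_invalid("`visit_cost()` expects one location; see visit_cost_table()")
  }
  tab <- visit_cost_table(location)
  cost_breakdown(c(transportation = tab$transportation,
                   lodging = tab$lodging,
                   food = tab$food,
                   lost_income = tab$lost_income))
}

#' @rdname visit_cost
#' @param locations a [patient_locations()] table.
#' @return `visit_cost_table()`: a data frame with one row per location and
#'   columns `name`, `patient_count`, `transportation`, `lodging`, `food`,
#'   `lost_income`, `total` (all unrounded dollars).
#' @export
visit_cost_table <- function(locations) {
  locations <- patient_locations(as.data.frame(locations))
  out <- data.frame(
    name = locations$name,
    patient_count = locations$patient_count,
    transportation = locations$round_trip_fare,
    lodging = locations$lodging_nights * locations$nightly_rate,
    food = locations$food_cost_total,
    lost_income = locations$days_away * locations$daily_wage,
    stringsAsFactors = FALSE
  )
  out$total <- out$transportation + out$lodging + out$food + out$lost_income
  out
}

#' Catchment-weighted average patient cost
#'
#' Each cost component is averaged over locations with weights equal to the
#' location patient counts; by linearity the weighted average of totals
#' equals the total of the weighted-average components.
#'
#' @param catch a [catchment()].
#' @return a `cost_breakdown` (components `transportation`, `lodging`,
#'   `food`, `lost_income`) with attribute `n_patients`.
#' @export
weighted_average_catchment <- function(catch) {
  if (!inherits(catch, "catchment")) stop_invalid("`catch` must be a catchment")
  tab <- visit_cost_table(catch$locations)
  n <- sum(tab$patient_count)
  if (n < 1) stop_invalid("catchment has no patients to weight by")
  w <- tab$patient_count / n
  bd <- cost_breakdown(c(
    transportation = sum(w * tab$transportation),
    lodging = sum(w * tab$lodging),
    food = sum(w * tab$food),
    lost_income = sum(w * tab$lost_income)
  ))
  attr(bd, "n_patients") <- n
  bd
}

# patient-weighted median taking the lower of the two middle patients
weighted_median_lower <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  pos <- floor((sum(w) + 1) / 2)
  x[which(cumsum(w) >= pos)[1]]
}

#' Summarize per-location visit costs across a catchment
#'
#' Patient-weighted median (the lower of the two middle patients when the
#' count is even), minimum and maximum of per-location visit totals, and the
#' patient-weighted fraction of patients whose visit total falls strictly
#' below each threshold.
#'
#' @param catch a [catchment()].
#' @param thresholds dollar thresholds for the below-threshold fractions;
#'   default `c(5, 10)`.
#' @return a list with `site_name`, `n_patients`, `median`, `min`, `max`,
#'   and `fraction_below` (named numeric, one entry per threshold).
#' @export
catchment_summary <- function(catch, thresholds = c(5, 10)) {
  if (!inherits(catch, "catchment")) stop_invalid("`catch` must be a catchment")
  thresholds <- check_number(thresholds, "thresholds", min = 0,
                             len = length(thresholds))
  tab <- visit_cost_table(catch$locations)
  n <- sum(tab$patient_count)
  if (n < 1) stop_invalid("catchment has no patients")
  frac <- vapply(thresholds, function(th) {
    sum(tab$patient_count[tab$total < th]) / n
  }, numeric(1))
  names(frac) <- sprintf("below_%s", format(thresholds, trim = TRUE))
  list(
    site_name = catch$site_name,
    n_patients = n,
    median = weighted_median_lower(tab$total, tab$patient_count),
    min = min(tab$total),
    max = max(tab$total),
    fraction_below = frac
  )
}

#' Read patient locations from CSV
#'
#' Expects columns `site,location,distance_km,fare,lodging_nights,
#' nightly_rate,food_total,days_away,daily_wage,patients` and returns one
#' [catchment()] per distinct site.
#'
#' @param path path to a CSV file.
#' @return a named list of `catchment` objects.
#' @export
read_locations_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "location", "distance_km", "fare", "lodging_nights",
            "nightly_rate", "food_total", "days_away", "daily_wage",
            "patients")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_schema(paste("locations CSV missing columns:",
                      paste(missing_cols, collapse = ", ")))
  }
  locs <- data.frame(
    name = raw$location, distance_km = raw$distance_km,
    round_trip_fare = raw$fare, lodging_nights = raw$lodging_nights,
    nightly_rate = raw$nightly_rate, food_cost_total = raw$food_total,
    days_away = raw$days_away, daily_wage = raw$daily_wage,
    patient_count = raw$patients, stringsAsFactors = FALSE
  )
  sites <- split(locs, raw$site)
  out <- lapply(names(sites), function(s) catchment(s, sites[[s]]))
  names(out) <- names(sites)
  out
}
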