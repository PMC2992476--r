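#' Specimen-collection supply item
#'
#' @param name label (e.g. "latex gloves", "vacutainer").
#' @param unit_cost dollars per unit.
#' @param units_per_specimen units consumed per specimen collected, >= 0.
#' @return an object of class `supply_item`.
#' @export
supply_item <- function(name, unit_cost, units_per_specimen = 1) {
  structure(
    list(name = as.character(name)[1],
         unit_cost = check_number(unit_cost, "unit_cost", min = 0),
         units_per_specimen = check_number(units_per_specimen,
                                           "units_per_specimen", min = 0)),
    class = "supply_item"
  )
}

#' Specimen shipment profile
#'
#' Costs of one shipment trip from the collection site to the central
#' laboratory, and the number of specimens batched per shipment that the trip
#' cost amortizes over. Airfare may only be non-zero when the mode includes
#' air.
#'
#' @param mode one of `"ground"`, `"air"`, `"mixed"`.
#' @param driver_labour_per_trip dollars of driver labour per trip.
#' @param fuel_per_trip dollars of fuel per trip.
#' @param vehicle_depreciation_per_trip dollars of vehicle depreciation per
#'   trip (see [annualize_asset()] for deriving this from a purchase price).
#' @param airfare_per_trip dollars of airfare per trip; 0 unless mode is
#'   `"air"` or `"mixed"`.
#' @param specimens_per_shipment specimens per shipment, integer >= 1.
#' @return an object of class `shipment_profile`.
#' @export
shipment_profile <- function(mode = c("ground", "air", "mixed"),
                             driver_labour_per_trip = 0, fuel_per_trip = 0,
                             vehicle_depreciation_per_trip = 0,
                             airfare_per_trip = 0,
                             specimens_per_shipment = 1) {
  mode <- match.arg(mode)
  airfare_per_trip <- check_number(airfare_per_trip, "airfare_per_trip", min = 0)
  if (mode == "ground" && airfare_per_trip > 0) {
    stop_invalid("airfare must be 0 for ground shipment")
  }
  structure(
    list(mode = mode,
         driver_labour_per_trip = check_number(driver_labour_per_trip,
                                               "driver_labour_per_trip", min = 0),
         fuel_per_trip = check_number(fuel_per_trip, "fuel_per_trip", min = 0),
         vehicle_depreciation_per_trip =
           check_number(vehicle_depreciation_per_trip,
                        "vehicle_depreciation_per_trip", min = 0),
         airfare_per_trip = airfare_per_trip,
         specimens_per_shipment = check_count(specimens_per_shipment,
                                              "specimens_per_shipment", min = 1L)),
    class = "shipment_profile"
  )
}

#' Shipment transport cost per specimen
#'
#' Total trip cost (driver + fuel + vehicle depreciation + airfare) divided
#' by the number of specimens batched per shipment. Batching shipments is
#' what drives this component down.
#'
#' @param shipment a [shipment_profile()].
#' @return dollars per specimen (unrounded).
#' @examples
#' transport_per_specimen(shipment_profile("air", airfare_per_trip = 13.30,
#'                                         specimens_per_shipment = 10)) # 1.33
#' @export
transport_per_specimen <- function(shipment) {
  if (!inherits(shipment, "shipment_profile")) {
    stop_invalid("`shipment` must be a shipment_profile")
  }
  trip <- shipment$driver_labour_per_trip + shipment$fuel_per_trip +
    shipment$vehicle_depreciation_per_trip + shipment$airfare_per_trip
  trip / shipment$specimens_per_shipment
}

#' Specimen collection site cost profile
#'
#' Each of the four components can be supplied either itemized (lists of
#' [supply_item()] / [labour_step()] objects, a [shipment_profile()]) or
#' pre-aggregated as a single per-specimen dollar amount — the two entry
#' modes are mutually exclusive per component. Facility overhead is
#' deliberately out of scope: at low HIV prevalence the share of general
#' facility overhead attributable to specimen collection is negligible.
#'
#' @param site_name label of the site.
#' @param supplies list of [supply_item()]s, or a per-specimen dollar amount.
#' @param labour list of [labour_step()]s, or a per-specimen dollar amount.
#' @param accommodation_per_specimen dollars of patient accommodations/food
#'   the site provides, per specimen.
#' @param transport a [shipment_profile()], or a per-specimen dollar amount.
#' @return an object of class `scs_profile`.
#' @export
scs_profile <- function(site_name, supplies = 0, labour = 0,
                        accommodation_per_specimen = 0, transport = 0) {
  check_component <- function(x, what, item_class) {
    if (is.numeric(x)) {
      check_number(x, what, min = 0)
    } else if (is.list(x) && !inherits(x, item_class)) {
      if (!all(vapply(x, inherits, logical(1), item_class))) {
        stop_invalid(sprintf("`%s` must be a number or a list of %s objects",
                             what, item_class))
      }
      x
    } else if (inherits(x, item_class)) {
      list(x)
    } else {
      stop_invalid(sprintf("`%s` must be a number or a list of %s objects",
                           what, item_class))
    }
  }
  transport <- if (inherits(transport, "shipment_profile")) transport else
    check_number(transport, "transport", min = 0)
  structure(
    list(site_name = as.character(site_name)[1],
         supplies = check_component(supplies, "supplies", "supply_item"),
         labour = check_component(labour, "labour", "labour_step"),
         accommodation_per_specimen =
           check_number(accommodation_per_specimen,
                        "accommodation_per_specimen", min = 0),
         transport = transport),
    class = "scs_profile"
  )
}

#' Collection-site cost per specimen
#'
#' Sums the four per-specimen components: supplies, labour, patient
#' accommodations and shipment transport. Itemized labour amortizes per-run
#' minutes (e.g. site preparation) over `specimens_per_session`; per-specimen
#' minutes (counselling, collection, processing, packaging) are charged in
#' full. An itemized shipment amortizes over its own
#' `specimens_per_shipment`.
#'
#' @param profile an [scs_profile()].
#' @param specimens_per_session specimens handled per collection session,
#'   integer >= 1; only used for itemized labour.
#' @return a [cost_breakdown()] with components `supplies`, `labour`,
#'   `accommodations`, `transport`.
#' @export
scs_cost_per_specimen <- function(profile, specimens_per_session = 1) {
  if (!inherits(profile, "scs_profile")) {
    stop_invalid("`profile` must be an scs_profile")
  }
  specimens_per_session <- check_count(specimens_per_session,
                                       "specimens_per_session", min = 1L)
  supplies <- if (is.numeric(profile$supplies)) profile$supplies else
    sum(vapply(profile$supplies,
               function(it) it$unit_cost * it$units_per_specimen, numeric(1)))
  labour <- if (is.numeric(profile$labour)) profile$labour else
    sum(vapply(profile$labour, labour_step_cost, numeric(1),
               n = specimens_per_session))
  transport <- if (is.numeric(profile$transport)) profile$transport else
    transport_per_specimen(profile$transport)
  cost_breakdown(c(supplies = supplies, labour = labour,
                   accommodations = profile$accommodation_per_specimen,
                   transport = transport))
}
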