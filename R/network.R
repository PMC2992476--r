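#' Aggregated patient cost entry
#'
#' Catchment-level patient costs entered directly as weighted-average
#' components plus a total, for use when only consolidated figures are known
#' rather than per-location detail. Unlike [cost_breakdown()], the total is
#' carried verbatim: consolidated sources report weighted averages whose
#' underlying location weights may be unavailable, so the printed total can
#' differ from the sum of the printed (independently rounded) component
#' means. The summary fields (`median`, `min`, `max`) are optional.
#'
#' @param transportation,lodging,food,lost_income weighted-average component
#'   costs in dollars.
#' @param total weighted-average total; defaults to the component sum.
#' @param median,min,max optional summary of per-patient totals.
#' @return an object of class `patient_aggregate`.
#' @export
patient_aggregate <- function(transportation = 0, lodging = 0, food = 0,
                              lost_income = 0, total = NULL,
                              median = NA_real_, min = NA_real_,
                              max = NA_real_) {
  comp <- c(transportation = check_number(transportation, "transportation", min = 0),
            lodging = check_number(lodging, "lodging", min = 0),
            food = check_number(food, "food", min = 0),
            lost_income = check_number(lost_income, "lost_income", min = 0))
  if (is.null(total)) total <- sum(comp)
  structure(
    list(components = comp, total = check_number(total, "total", min = 0),
         median = median, min = min, max = max),
    class = "patient_aggregate"
  )
}

#' Network site entry
#'
#' One specimen collection site of a testing network: its patient tier
#' (either a [catchment()] of locations or a [patient_aggregate()]), its
#' [scs_profile()], its [delivery_chain()], and the number of specimens per
#' collection session over which per-session SCS labour amortizes.
#'
#' @param name site label.
#' @param patient a `catchment` or `patient_aggregate`.
#' @param scs an `scs_profile`.
#' @param delivery a `delivery_chain`.
#' @param specimens_per_session integer >= 1.
#' @return an object of class `network_site`.
#' @export
network_site <- function(name, patient, scs, delivery,
                         specimens_per_session = 1) {
  if (!inherits(patient, c("catchment", "patient_aggregate"))) {
    stop_invalid("`patient` must be a catchment or patient_aggregate")
  }
  if (!inherits(scs, "scs_profile")) stop_invalid("`scs` must be an scs_profile")
  if (!inherits(delivery, "delivery_chain")) {
    stop_invalid("`delivery` must be a delivery_chain")
  }
  structure(
    list(name = as.character(name)[1], patient = patient, scs = scs,
         delivery = delivery,
         specimens_per_session = check_count(specimens_per_session,
                                             "specimens_per_session", min = 1L)),
    class = "network_site"
  )
}

#' Testing network configuration
#'
#' The complete input of the costing pipeline: the sites, the central
#' laboratory profile with its operating batch sizes, the display rounding
#' policy and the patient-cost reporting thresholds.
#'
#' @param sites list of [network_site()] entries (site names must be unique).
#' @param lab_profile a [lab_cost_profile()].
#' @param batch_sizes batch sizes reported in the laboratory table.
#' @param operating_batch_size the batch size the laboratory actually runs,
#'   used for the network-level cost per test.
#' @param rounding display rounding policy,
#'   `list(display_decimals = 2, mode = "half_up")`.
#' @param thresholds dollar thresholds for patient-cost fractions.
#' @param provenance optional list recording where the configuration came
#'   from (file path and hash, or generator seed).
#' @return an object of class `network_config`.
#' @export
network_config <- function(sites, lab_profile, batch_sizes = c(10, 22),
                           operating_batch_size = max(batch_sizes),
                           rounding = list(display_decimals = 2,
                                           mode = "half_up"),
                           thresholds = c(5, 10), provenance = list()) {
  if (!is.list(sites) || length(sites) < 1 ||
      !all(vapply(sites, inherits, logical(1), "network_site"))) {
    stop_invalid("`sites` must be a non-empty list of network_site entries")
  }
  nm <- vapply(sites, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_invalid("site names must be unique")
  if (!inherits(lab_profile, "lab_cost_profile")) {
    stop_invalid("`lab_profile` must be a lab_cost_profile")
  }
  batch_sizes <- check_count(batch_sizes, "batch_sizes", min = 1L)
  operating_batch_size <- check_count(operating_batch_size,
                                      "operating_batch_size", min = 1L)
  if (!identical(rounding$mode, "half_up")) {
    stop_invalid("only rounding mode \"half_up\" is supported")
  }
  structure(
    list(sites = sites, lab_profile = lab_profile,
         batch_sizes = unique(batch_sizes),
         operating_batch_size = operating_batch_size,
         rounding = rounding,
         thresholds = check_number(thresholds, "thresholds", min = 0,
                                   len = length(thresholds)),
         provenance = provenance),
    class = "network_config"
  )
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %d site(s); lab kit %d tests @ $%s; operating batch %d\n",
              length(x$sites), x$lab_profile$kit$tests_per_kit,
              money_format(x$lab_profile$kit$kit_price),
              x$operating_batch_size))
  invisible(x)
}
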