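#' Results delivery chain
#'
#' Attrition in results reporting, modelled as two independent multiplicative
#' survival fractions: the fraction of performed tests whose results reach
#' the specimen collection site, and the fraction of those that then reach
#' the patient. Mean turnaround days are carried as metadata only — delay is
#' reported but never enters the cost arithmetic.
#'
#' @param fraction_to_scs fraction of results delivered to the SCS, in (0, 1].
#' @param fraction_to_patient fraction of SCS-delivered results that reach
#'   the patient, in (0, 1].
#' @param mean_turnaround_days mean days from specimen shipment to result
#'   receipt; metadata, >= 0 (default `NA`).
#' @return an object of class `delivery_chain`.
#' @export
delivery_chain <- function(fraction_to_scs = 1, fraction_to_patient = 1,
                           mean_turnaround_days = NA_real_) {
  check_fraction <- function(x, name) {
    x <- check_number(x, name)
    if (x <= 0 || x > 1) stop_invalid(sprintf("`%s` must be in (0, 1]", name))
    x
  }
  if (!is.na(mean_turnaround_days)) {
    mean_turnaround_days <- check_number(mean_turnaround_days,
                                         "mean_turnaround_days", min = 0)
  }
  structure(
    list(fraction_to_scs = check_fraction(fraction_to_scs, "fraction_to_scs"),
         fraction_to_patient = check_fraction(fraction_to_patient,
                                              "fraction_to_patient"),
         mean_turnaround_days = mean_turnaround_days),
    class = "delivery_chain"
  )
}

#' Cost per result delivered
#'
#' Dividing the cost per test performed by the delivery fractions spreads the
#' cost of all tests over the results that actually arrive:
#' `cost / f_scs` per result delivered to the SCS, `cost / (f_scs *
#' f_patient)` per result reaching the patient. The attrition increase is
#' `(1 / (f_scs * f_patient) - 1) * 100`, reported to the nearest whole
#' percent (half-up).
#'
#' @param cost_per_test cost of performing one test, dollars.
#' @param chain a [delivery_chain()].
#' @return an object of class `delivered_cost_report`: a list with
#'   `cost_per_test`, `cost_per_result_scs`, `cost_per_result_patient`
#'   (unrounded dollars) and `attrition_increase_pct` (whole percent).
#' @examples
#' r <- cost_per_delivered_result(124.58, delivery_chain(0.81, 1))
#' money_round(r$cost_per_result_scs) # 153.80
#' @export
cost_per_delivered_result <- function(cost_per_test, chain) {
  cost_per_test <- check_number(cost_per_test, "cost_per_test", min = 0)
  if (!inherits(chain, "delivery_chain")) {
    stop_invalid("`chain` must be a delivery_chain")
  }
  f1 <- chain$fraction_to_scs
  f2 <- chain$fraction_to_patient
  structure(
    list(cost_per_test = cost_per_test,
         cost_per_result_scs = cost_per_test / f1,
         cost_per_result_patient = cost_per_test / (f1 * f2),
         attrition_increase_pct = money_round((1 / (f1 * f2) - 1) * 100,
                                              digits = 0)),
    class = "delivered_cost_report"
  )
}

#' @export
print.delivered_cost_report <- function(x, ...) {
  cat(sprintf(paste0("<delivered_cost_report>\n",
                     "  per test performed      %8s\n",
                     "  per result at SCS       %8s\n",
                     "  per result to patient   %8s\n",
                     "  attrition increase      %7d%%\n"),
              money_format(x$cost_per_test),
              money_format(x$cost_per_result_scs),
              money_format(x$cost_per_result_patient),
              as.integer(x$attrition_increase_pct)))
  invisible(x)
}

#' Network-wide delivery cost summary
#'
#' Per-site delivered-cost reports summarized as minimum, mean, median and
#' maximum (median of an even count is the average of the middle two).
#'
#' @param sites data frame with columns `cost_per_test`, `fraction_to_scs`,
#'   `fraction_to_patient` (one row per site; an optional `site` column is
#'   carried through to the per-site detail).
#' @return a list with `per_site` (data frame of per-site reports, unrounded)
#'   and `summary` (data frame with one row per measure and columns
#'   `minimum`, `mean`, `median`, `maximum`).
#' @export
network_delivery_summary <- function(sites) {
  need <- c("cost_per_test", "fraction_to_scs", "fraction_to_patient")
  if (!is.data.frame(sites) || nrow(sites) < 1 ||
      !all(need %in% names(sites))) {
    stop_invalid(paste("`sites` must be a non-empty data frame with columns",
                       paste(need, collapse = ", ")))
  }
  reports <- lapply(seq_len(nrow(sites)), function(i) {
    cost_per_delivered_result(
      sites$cost_per_test[i],
      delivery_chain(sites$fraction_to_scs[i], sites$fraction_to_patient[i]))
  })
  per_site <- data.frame(
    site = if ("site" %in% names(sites)) sites$site else seq_len(nrow(sites)),
    cost_per_test = sites$cost_per_test,
    fraction_to_scs = sites$fraction_to_scs,
    cost_per_result_scs =
      vapply(reports, `[[`, numeric(1), "cost_per_result_scs"),
    fraction_to_patient = sites$fraction_to_patient,
    cost_per_result_patient =
      vapply(reports, `[[`, numeric(1), "cost_per_result_patient"),
    attrition_increase_pct =
      vapply(reports, `[[`, numeric(1), "attrition_increase_pct")
  )
  measures <- c("fraction_to_scs", "cost_per_result_scs",
                "fraction_to_patient", "cost_per_result_patient",
                "attrition_increase_pct")
  summarize <- function(v) {
    c(minimum = min(v), mean = mean(v), median = stats::median(v),
      maximum = max(v))
  }
  stats_tab <- t(vapply(measures, function(m) summarize(per_site[[m]]),
                        numeric(4)))
  list(per_site = per_site,
       summary = data.frame(measure = measures,
                            minimum = stats_tab[, "minimum"],
                            mean = stats_tab[, "mean"],
                            median = stats_tab[, "median"],
                            maximum = stats_tab[, "maximum"],
                            row.names = NULL))
}
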