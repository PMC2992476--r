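#' Itemized cost breakdown
#'
#' The universal output record of the costing pipeline: named non-negative
#' component amounts plus a total. Construction enforces conservation — the
#' stored total must equal the component sum to within half a cent before any
#' display rounding.
#'
#' @param components named numeric vector of non-negative dollar amounts.
#' @param total optional explicit total; defaults to `sum(components)`.
#' @param tolerance allowed absolute discrepancy between `total` and the
#'   component sum (default 0.005, half a cent).
#' @return an object of class `cost_breakdown` with fields `components` and
#'   `total`.
#' @examples
#' cost_breakdown(c(supplies = 0.61, labour = 6.66,
#'                  accommodations = 2.89, transport = 10.76))
#' @export
cost_breakdown <- function(components, total = NULL, tolerance = 0.005) {
  if (!is.numeric(components) || is.null(names(components)) ||
      any(!nzchar(names(components)))) {
    stop_invalid("`components` must be a fully named numeric vector")
  }
  if (anyNA(components) || any(components < 0)) {
    stop_invalid("cost components must be non-negative and non-missing")
  }
  s <- sum(components)
  if (is.null(total)) total <- s
  total <- check_number(total, "total", min = 0)
  if (abs(total - s) > tolerance + 1e-9) {
    stop_invalid(sprintf(
      "total %.6f does not equal component sum %.6f (tolerance %g)",
      total, s, tolerance))
  }
  structure(list(components = components, total = total),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  w <- max(nchar(names(x$components)), nchar("total"))
  for (nm in names(x$components)) {
    cat(sprintf("  %-*s  %8s\n", w, nm, money_format(x$components[[nm]])))
  }
  cat(sprintf("  %-*s  %8s\n", w, "total", money_format(x$total)))
  invisible(x)
}

#' @export
as.data.frame.cost_breakdown <- function(x, ...) {
  data.frame(as.list(x$components), total = x$total)
}

# internal: component accessor tolerant of absent names
bd_component <- function(x, name) {
  if (name %in% names(x$components)) unname(x$components[[name]]) else 0
}
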