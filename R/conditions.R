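# Structured conditions so callers (and tests) can distinguish bad input,
# infeasible inverse problems, ambiguity, schema violations and I/O failures.

vl_stop <- function(msg, class, data = NULL, call = sys.call(-1)) {
  cond <- errorCondition(msg, class = c(class, "vlcost_error"), call = call)
  if (!is.null(data)) cond$data <- data
  stop(cond)
}

stop_invalid <- function(msg, call = sys.call(-1)) {
  vl_stop(msg, "vlcost_invalid_input", call = call)
}

stop_schema <- function(msg, field = NULL, call = sys.call(-1)) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  vl_stop(msg, "vlcost_schema_error", data = list(field = field), call = call)
}

stop_io <- function(msg, call = sys.call(-1)) {
  vl_stop(msg, "vlcost_io_error", call = call)
}

# scalar numeric validators used across constructors
check_number <- function(x, name, min = -Inf, max = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_invalid(sprintf("`%s` must be a numeric of length %d", name, len))
  }
  if (any(x < min) || any(x > max)) {
    stop_invalid(sprintf("`%s` must be in [%s, %s], got %s",
                         name, format(min), format(max),
                         paste(format(x), collapse = ", ")))
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 0L) {
  x <- check_number(x, name, min = min, len = max(length(x), 1L))
  if (any(x != floor(x))) stop_invalid(sprintf("`%s` must be a whole number", name))
  as.integer(x)
}
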