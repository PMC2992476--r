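# YAML/JSON network configuration loading, validation and writing.
# The schema is strict: unknown keys are rejected with the offending field
# named, so typos in hand-written configs fail loudly instead of silently
# falling back to defaults.

vl_log <- function(fmt, ...) {
  if (isTRUE(getOption("vlcost.verbose", FALSE))) message(sprintf(fmt, ...))
}

check_keys <- function(x, allowed, context) {
  if (is.null(names(x)) && length(x) > 0) {
    stop_schema(sprintf("`%s` must be a mapping", context))
  }
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop_schema(sprintf("unknown key(s) in `%s`: %s", context,
                        paste(unknown, collapse = ", ")),
                field = paste(context, unknown[1], sep = "."))
  }
  invisible(x)
}

need_key <- function(x, key, context) {
  if (is.null(x[[key]])) {
    stop_schema(sprintf("`%s` is required in `%s`", key, context),
                field = paste(context, key, sep = "."))
  }
  x[[key]]
}

as_schema_error <- function(expr, field) {
  withCallingHandlers(expr, vlcost_invalid_input = function(e) {
    stop_schema(conditionMessage(e), field = field)
  })
}

parse_labour_steps <- function(lst, context) {
  lapply(seq_along(lst), function(i) {
    ctx <- sprintf("%s[%d]", context, i)
    st <- check_keys(lst[[i]], c("name", "per_run_minutes",
                                 "per_specimen_minutes", "hourly_wage"), ctx)
    as_schema_error(
      labour_step(need_key(st, "name", ctx),
                  per_run_minutes = st$per_run_minutes %||% 0,
                  per_specimen_minutes = st$per_specimen_minutes %||% 0,
                  hourly_wage = st$hourly_wage %||% 0),
      field = ctx)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_patient <- function(p, context) {
  check_keys(p, c("aggregated", "locations"), context)
  if (!is.null(p$aggregated) && !is.null(p$locations)) {
    stop_schema(sprintf("`%s` must use either `aggregated` or `locations`, not both",
                        context), field = context)
  }
  if (!is.null(p$aggregated)) {
    a <- check_keys(p$aggregated,
                    c("transportation", "lodging", "food", "lost_income",
                      "total", "median", "min", "max"),
                    paste0(context, ".aggregated"))
    as_schema_error(
      patient_aggregate(a$transportation %||% 0, a$lodging %||% 0,
                        a$food %||% 0, a$lost_income %||% 0,
                        total = a$total,
                        median = a$median %||% NA_real_,
                        min = a$min %||% NA_real_,
                        max = a$max %||% NA_real_),
      field = paste0(context, ".aggregated"))
  } else if (!is.null(p$locations)) {
    rows <- lapply(p$locations, function(lc) {
      check_keys(lc, location_columns, paste0(context, ".locations"))
      as.data.frame(lc, stringsAsFactors = FALSE)
    })
    as_schema_error(patient_locations(do.call(rbind, rows)),
                    field = paste0(context, ".locations"))
  } else {
    stop_schema(sprintf("`%s` needs `aggregated` or `locations`", context),
                field = context)
  }
}

parse_scs <- function(s, site_name, context) {
  check_keys(s, c("aggregated", "itemized"), context)
  if (!is.null(s$aggregated) && !is.null(s$itemized)) {
    stop_schema(sprintf("`%s` must use either `aggregated` or `itemized`, not both",
                        context), field = context)
  }
  if (!is.null(s$aggregated)) {
    a <- check_keys(s$aggregated,
                    c("supplies", "labour", "accommodations", "transport"),
                    paste0(context, ".aggregated"))
    as_schema_error(
      scs_profile(site_name, supplies = a$supplies %||% 0,
                  labour = a$labour %||% 0,
                  accommodation_per_specimen = a$accommodations %||% 0,
                  transport = a$transport %||% 0),
      field = paste0(context, ".aggregated"))
  } else if (!is.null(s$itemized)) {
    it <- check_keys(s$itemized,
                     c("supplies", "labour", "accommodation_per_specimen",
                       "shipment"),
                     paste0(context, ".itemized"))
    supplies <- lapply(it$supplies %||% list(), function(sp) {
      ctx <- paste0(context, ".itemized.supplies")
      check_keys(sp, c("name", "unit_cost", "units_per_specimen"), ctx)
      as_schema_error(supply_item(need_key(sp, "name", ctx),
                                  need_key(sp, "unit_cost", ctx),
                                  sp$units_per_specimen %||% 1),
                      field = ctx)
    })
    labour <- parse_labour_steps(it$labour %||% list(),
                                 paste0(context, ".itemized.labour"))
    shipment <- if (is.null(it$shipment)) 0 else {
      ctx <- paste0(context, ".itemized.shipment")
      sh <- check_keys(it$shipment,
                       c("mode", "driver_labour_per_trip", "fuel_per_trip",
                         "vehicle_depreciation_per_trip", "airfare_per_trip",
                         "specimens_per_shipment"), ctx)
      as_schema_error(
        shipment_profile(sh$mode %||% "ground",
                         driver_labour_per_trip = sh$driver_labour_per_trip %||% 0,
                         fuel_per_trip = sh$fuel_per_trip %||% 0,
                         vehicle_depreciation_per_trip =
                           sh$vehicle_depreciation_per_trip %||% 0,
                         airfare_per_trip = sh$airfare_per_trip %||% 0,
                         specimens_per_shipment =
                           sh$specimens_per_shipment %||% 1),
        field = ctx)
    }
    as_schema_error(
      scs_profile(site_name, supplies = supplies, labour = labour,
                  accommodation_per_specimen =
                    it$accommodation_per_specimen %||% 0,
                  transport = shipment),
      field = paste0(context, ".itemized"))
  } else {
    stop_schema(sprintf("`%s` needs `aggregated` or `itemized`", context),
                field = context)
  }
}

parse_lab <- function(l, context = "lab") {
  check_keys(l, c("kit", "disposables", "labour",
                  "facilities_equipment_per_specimen", "batch_sizes",
                  "operating_batch_size"), context)
  kit_raw <- check_keys(need_key(l, "kit", context),
                        c("tests_per_kit", "kit_price", "controls_per_run"),
                        paste0(context, ".kit"))
  kit <- as_schema_error(
    kit_configuration(need_key(kit_raw, "tests_per_kit", "lab.kit"),
                      need_key(kit_raw, "kit_price", "lab.kit"),
                      kit_raw$controls_per_run %||% 2),
    field = paste0(context, ".kit"))
  disposables <- lapply(l$disposables %||% list(), function(d) {
    ctx <- paste0(context, ".disposables")
    check_keys(d, c("name", "per_run", "per_specimen"), ctx)
    as_schema_error(lab_cost_line(need_key(d, "name", ctx),
                                  per_run = d$per_run %||% 0,
                                  per_specimen = d$per_specimen %||% 0),
                    field = ctx)
  })
  labour <- parse_labour_steps(l$labour %||% list(),
                               paste0(context, ".labour"))
  profile <- as_schema_error(
    lab_cost_profile(kit, disposables, labour,
                     l$facilities_equipment_per_specimen %||% 0),
    field = context)
  list(profile = profile,
       batch_sizes = unlist(l$batch_sizes %||% list(10, 22)),
       operating_batch_size = l$operating_batch_size)
}

#' Load a network configuration from YAML or JSON
#'
#' Parses and validates a testing-network configuration file. The schema is
#' strict: unknown keys and out-of-range values raise an error of class
#' `vlcost_schema_error` naming the offending field. Provenance (path and
#' MD5 hash) is recorded on the returned object.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return a validated [network_config()].
#' @seealso [write_network_config()] for the inverse, and
#'   `system.file("extdata", "demo_network.yaml", package = "vlcost")` for a
#'   worked example file.
#' @export
load_network_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  raw <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) {
      stop_schema(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
    })
  if (is.null(raw) || length(raw) == 0) {
    stop_schema(sprintf("configuration file is empty: %s", path))
  }
  check_keys(raw, c("rounding", "thresholds", "lab", "sites"), "config")
  rounding <- check_keys(raw$rounding %||%
                           list(display_decimals = 2, mode = "half_up"),
                         c("display_decimals", "mode"), "rounding")
  lab <- parse_lab(need_key(raw, "lab", "config"))
  sites_raw <- need_key(raw, "sites", "config")
  sites <- lapply(seq_along(sites_raw), function(i) {
    ctx <- sprintf("sites[%d]", i)
    s <- check_keys(sites_raw[[i]],
                    c("name", "specimens_per_session", "patient", "scs",
                      "delivery"), ctx)
    name <- need_key(s, "name", ctx)
    d <- check_keys(need_key(s, "delivery", ctx),
                    c("fraction_to_scs", "fraction_to_patient",
                      "mean_turnaround_days"), paste0(ctx, ".delivery"))
    chain <- as_schema_error(
      delivery_chain(d$fraction_to_scs %||% 1, d$fraction_to_patient %||% 1,
                     d$mean_turnaround_days %||% NA_real_),
      field = paste0(ctx, ".delivery"))
    patient <- parse_patient(need_key(s, "patient", ctx),
                             paste0(ctx, ".patient"))
    if (inherits(patient, "patient_locations")) {
      patient <- catchment(name, patient)
    }
    as_schema_error(
      network_site(name,
                   patient = patient,
                   scs = parse_scs(need_key(s, "scs", ctx), name,
                                   paste0(ctx, ".scs")),
                   delivery = chain,
                   specimens_per_session = s$specimens_per_session %||% 1),
      field = ctx)
  })
  net <- network_config(
    sites, lab$profile, batch_sizes = lab$batch_sizes,
    operating_batch_size = lab$operating_batch_size %||%
      max(lab$batch_sizes),
    rounding = list(display_decimals = rounding$display_decimals %||% 2,
                    mode = rounding$mode %||% "half_up"),
    thresholds = unlist(raw$thresholds %||% list(5, 10)),
    provenance = list(path = path,
                      md5 = unname(tools::md5sum(path)))
  )
  vl_log("loaded network config %s (md5 %s): %d site(s)", path,
         net$provenance$md5, length(net$sites))
  net
}

serialize_labour <- function(steps) {
  lapply(steps, function(st) {
    list(name = st$name, per_run_minutes = st$per_run_minutes,
         per_specimen_minutes = st$per_specimen_minutes,
         hourly_wage = st$hourly_wage)
  })
}

#' Write a network configuration to YAML
#'
#' Serializes a [network_config()] so that [load_network_config()] restores
#' an equivalent object; used both for sharing configurations and for
#' persisting synthetic networks from [generate_network()].
#'
#' @param network a [network_config()].
#' @param path output file path (`.yaml`).
#' @return invisibly, `path`.
#' @export
write_network_config <- function(network, path) {
  if (!inherits(network, "network_config")) {
    stop_invalid("`network` must be a network_config")
  }
  lab <- network$lab_profile
  out <- list(
    rounding = network$rounding,
    thresholds = as.numeric(network$thresholds),
    lab = list(
      kit = list(tests_per_kit = lab$kit$tests_per_kit,
                 kit_price = lab$kit$kit_price,
                 controls_per_run = lab$kit$controls_per_run),
      disposables = lapply(lab$disposables, function(d) {
        list(name = d$name, per_run = d$per_run,
             per_specimen = d$per_specimen)
      }),
      labour = serialize_labour(lab$labour_steps),
      facilities_equipment_per_specimen =
        lab$facilities_equipment_per_specimen,
      batch_sizes = as.integer(network$batch_sizes),
      operating_batch_size = network$operating_batch_size
    ),
    sites = lapply(network$sites, function(site) {
      patient <- if (inherits(site$patient, "patient_aggregate")) {
        p <- site$patient
        list(aggregated = list(
          transportation = p$components[["transportation"]],
          lodging = p$components[["lodging"]],
          food = p$components[["food"]],
          lost_income = p$components[["lost_income"]],
          total = p$total, median = p$median, min = p$min, max = p$max))
      } else {
        locs <- site$patient$locations
        list(locations = lapply(seq_len(nrow(locs)), function(i) {
          as.list(locs[i, , drop = FALSE])
        }))
      }
      scs <- site$scs
      scs_out <- if (is.numeric(scs$supplies) && is.numeric(scs$labour) &&
                     is.numeric(scs$transport)) {
        list(aggregated = list(
          supplies = scs$supplies, labour = scs$labour,
          accommodations = scs$accommodation_per_specimen,
          transport = scs$transport))
      } else {
        sh <- scs$transport
        list(itemized = list(
          supplies = lapply(scs$supplies, function(sp) {
            list(name = sp$name, unit_cost = sp$unit_cost,
                 units_per_specimen = sp$units_per_specimen)
          }),
          labour = serialize_labour(scs$labour),
          accommodation_per_specimen = scs$accommodation_per_specimen,
          shipment = if (inherits(sh, "shipment_profile")) {
            list(mode = sh$mode,
                 driver_labour_per_trip = sh$driver_labour_per_trip,
                 fuel_per_trip = sh$fuel_per_trip,
                 vehicle_depreciation_per_trip =
                   sh$vehicle_depreciation_per_trip,
                 airfare_per_trip = sh$airfare_per_trip,
                 specimens_per_shipment = sh$specimens_per_shipment)
          } else NULL))
      }
      list(name = site$name,
           specimens_per_session = site$specimens_per_session,
           patient = patient, scs = scs_out,
           delivery = list(
             fraction_to_scs = site$delivery$fraction_to_scs,
             fraction_to_patient = site$delivery$fraction_to_patient,
             mean_turnaround_days =
               if (is.na(site$delivery$mean_turnaround_days)) NULL else
                 site$delivery$mean_turnaround_days))
    })
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
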