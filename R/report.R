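#' Unrounded tier costs per site
#'
#' The three cost tiers of one test, per site: the patient tier (weighted
#' average visit cost, computed from locations or taken from the aggregated
#' entry), the clinic tier ([scs_cost_per_specimen()]), and the laboratory
#' tier ([lab_cost_per_specimen()] at the network's operating batch size,
#' identical across sites of a centralized network).
#'
#' @param network a [network_config()].
#' @return a data frame with columns `site`, `patient`, `clinic`,
#'   `laboratory` (unrounded dollars per test).
#' @export
tier_cost_table <- function(network) {
  if (!inherits(network, "network_config")) {
    stop_invalid("`network` must be a network_config")
  }
  lab_cost <- lab_cost_per_specimen(network$operating_batch_size,
                                    network$lab_profile)$total
  rows <- lapply(network$sites, function(site) {
    patient <- if (inherits(site$patient, "patient_aggregate")) {
      site$patient$total
    } else {
      weighted_average_catchment(site$patient)$total
    }
    clinic <- scs_cost_per_specimen(site$scs, site$specimens_per_session)$total
    data.frame(site = site$name, patient = patient, clinic = clinic,
               laboratory = lab_cost)
  })
  do.call(rbind, rows)
}

#' Tier costs, totals and percentage shares per site
#'
#' The headline report of the pipeline. The displayed total of a site is the
#' sum of its cent-rounded tier amounts (the way consolidated tier reports
#' are combined); percentage shares are computed from the unrounded tier
#' amounts against the unrounded site total and only then rounded to one
#' decimal, so the three shares of a site sum to 100.0 within 0.2.
#'
#' @param network a [network_config()], or a data frame with columns `site`,
#'   `patient`, `clinic`, `laboratory` of unrounded tier costs.
#' @return a data frame with columns `site`, `patient`, `patient_share`,
#'   `clinic`, `clinic_share`, `laboratory`, `laboratory_share`, `total`
#'   (money cent-rounded, shares in percent to one decimal).
#' @export
tier_share_report <- function(network) {
  tiers <- if (is.data.frame(network)) network else tier_cost_table(network)
  need <- c("site", "patient", "clinic", "laboratory")
  if (!all(need %in% names(tiers))) {
    stop_invalid(paste("tier table must have columns",
                       paste(need, collapse = ", ")))
  }
  unrounded_total <- tiers$patient + tiers$clinic + tiers$laboratory
  data.frame(
    site = tiers$site,
    patient = money_round(tiers$patient),
    patient_share = money_round(tiers$patient / unrounded_total * 100, 1),
    clinic = money_round(tiers$clinic),
    clinic_share = money_round(tiers$clinic / unrounded_total * 100, 1),
    laboratory = money_round(tiers$laboratory),
    laboratory_share = money_round(tiers$laboratory / unrounded_total * 100, 1),
    total = money_round(tiers$patient) + money_round(tiers$clinic) +
      money_round(tiers$laboratory)
  )
}

# per-site patient cost table (components, total, summary)
patient_cost_report <- function(network) {
  rows <- lapply(network$sites, function(site) {
    p <- site$patient
    if (inherits(p, "patient_aggregate")) {
      data.frame(site = site$name,
                 transportation = p$components[["transportation"]],
                 lodging = p$components[["lodging"]],
                 food = p$components[["food"]],
                 lost_income = p$components[["lost_income"]],
                 total = p$total, median = p$median, min = p$min, max = p$max)
    } else {
      avg <- weighted_average_catchment(p)
      s <- catchment_summary(p, network$thresholds)
      data.frame(site = site$name,
                 transportation = bd_component(avg, "transportation"),
                 lodging = bd_component(avg, "lodging"),
                 food = bd_component(avg, "food"),
                 lost_income = bd_component(avg, "lost_income"),
                 total = avg$total, median = s$median, min = s$min,
                 max = s$max)
    }
  })
  do.call(rbind, rows)
}

# per-site SCS cost table
scs_cost_report <- function(network) {
  rows <- lapply(network$sites, function(site) {
    bd <- scs_cost_per_specimen(site$scs, site$specimens_per_session)
    data.frame(site = site$name,
               supplies = bd_component(bd, "supplies"),
               labour = bd_component(bd, "labour"),
               accommodations = bd_component(bd, "accommodations"),
               transport = bd_component(bd, "transport"),
               total = bd$total)
  })
  do.call(rbind, rows)
}

# itemized laboratory table at the configured batch sizes
lab_cost_report <- function(network) {
  cols <- lapply(network$batch_sizes, function(n) {
    bd <- lab_cost_per_specimen(n, network$lab_profile)
    disp <- attr(bd, "disposable_items")
    lab <- attr(bd, "labour_items")
    data.frame(
      category = c("reagents",
                   rep("disposables", length(disp)), "total disposables",
                   rep("labour", length(lab)), "total labour",
                   "facilities and equipment", "total cost per specimen"),
      item = c("test kit", names(disp), "", names(lab), "", "", ""),
      cost = c(bd_component(bd, "reagents"),
               unname(disp), sum(disp),
               unname(lab), sum(lab),
               bd_component(bd, "facilities"), bd$total)
    )
  })
  out <- cols[[1]][c("category", "item")]
  for (i in seq_along(network$batch_sizes)) {
    out[[sprintf("batch_%d", network$batch_sizes[i])]] <- cols[[i]]$cost
  }
  out
}

# delivery summary over the network, costed at the displayed per-test totals
delivery_report <- function(network) {
  shares <- tier_share_report(network)
  sites <- data.frame(
    site = shares$site,
    cost_per_test = shares$total,
    fraction_to_scs = vapply(network$sites, function(s)
      s$delivery$fraction_to_scs, numeric(1)),
    fraction_to_patient = vapply(network$sites, function(s)
      s$delivery$fraction_to_patient, numeric(1))
  )
  network_delivery_summary(sites)
}

round_report <- function(df, money_cols, share_cols = character(),
                         frac_cols = character()) {
  for (cl in money_cols) df[[cl]] <- money_format(df[[cl]])
  for (cl in share_cols) df[[cl]] <- sprintf("%.1f", money_round(df[[cl]], 1))
  for (cl in frac_cols) df[[cl]] <- sprintf("%.3f", df[[cl]])
  df
}

#' Write the standard report tables for a network
#'
#' Emits five CSV tables plus a JSON run manifest into `out_dir`:
#' `table1.csv` (per-site tier costs, shares and totals), `table2.csv`
#' (patient costs), `table3.csv` (collection-site costs), `table4.csv`
#' (itemized laboratory costs at the configured batch sizes), `table5.csv`
#' (network delivery summary). Money is written with exactly two decimals
#' and shares with one, so the files are diffable; the manifest carries the
#' configuration provenance (path/hash or generator seed) and package
#' version. Output is deterministic: the same network yields byte-identical
#' files.
#'
#' @param network a [network_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths of the files written.
#' @export
emit_report_tables <- function(network, out_dir) {
  if (!inherits(network, "network_config")) {
    stop_invalid("`network` must be a network_config")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create output directory: %s", out_dir))
  }
  write_one <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }

  t1 <- round_report(tier_share_report(network),
                     money_cols = c("patient", "clinic", "laboratory", "total"),
                     share_cols = c("patient_share", "clinic_share",
                                    "laboratory_share"))
  t2 <- round_report(patient_cost_report(network),
                     money_cols = c("transportation", "lodging", "food",
                                    "lost_income", "total", "median", "min",
                                    "max"))
  t3 <- round_report(scs_cost_report(network),
                     money_cols = c("supplies", "labour", "accommodations",
                                    "transport", "total"))
  t4 <- lab_cost_report(network)
  t4 <- round_report(t4, money_cols = grep("^batch_", names(t4), value = TRUE))
  t5raw <- delivery_report(network)$summary
  frac_rows <- grepl("^fraction", t5raw$measure)
  pct_rows <- t5raw$measure == "attrition_increase_pct"
  for (cl in c("minimum", "mean", "median", "maximum")) {
    v <- t5raw[[cl]]
    t5raw[[cl]] <- ifelse(frac_rows, sprintf("%.3f", v),
                          ifelse(pct_rows, sprintf("%.0f", money_round(v, 0)),
                                 money_format(v)))
  }

  paths <- c(
    write_one(t1, "table1.csv"), write_one(t2, "table2.csv"),
    write_one(t3, "table3.csv"), write_one(t4, "table4.csv"),
    write_one(t5raw, "table5.csv")
  )

  manifest <- list(
    package = "vlcost",
    version = as.character(utils::packageVersion("vlcost")),
    n_sites = length(network$sites),
    batch_sizes = network$batch_sizes,
    operating_batch_size = network$operating_batch_size,
    provenance = network$provenance,
    files = basename(paths)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, manifest_path))
}
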