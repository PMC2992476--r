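#' Test kit configuration
#'
#' A commercial assay kit packages a fixed number of tests; every run
#' consumes whole kits (partial kits cannot be split across runs) and a fixed
#' number of control tests (typically one negative and one positive). The
#' configuration must fit at least one specimen into one kit, i.e.
#' `controls_per_run < tests_per_kit`.
#'
#' @param tests_per_kit tests packaged per kit, integer >= 1.
#' @param kit_price dollars per kit.
#' @param controls_per_run control tests consumed per run, integer >= 0.
#' @return an object of class `kit_configuration`.
#' @export
kit_configuration <- function(tests_per_kit, kit_price, controls_per_run = 2) {
  tests_per_kit <- check_count(tests_per_kit, "tests_per_kit", min = 1L)
  controls_per_run <- check_count(controls_per_run, "controls_per_run", min = 0L)
  if (controls_per_run >= tests_per_kit) {
    stop_invalid("`controls_per_run` must be < `tests_per_kit` so a run fits at least one specimen in one kit")
  }
  structure(
    list(tests_per_kit = tests_per_kit,
         kit_price = check_number(kit_price, "kit_price", min = 0),
         controls_per_run = controls_per_run),
    class = "kit_configuration"
  )
}

#' @export
print.kit_configuration <- function(x, ...) {
  cat(sprintf("<kit_configuration> %d tests/kit @ $%s, %d control(s)/run\n",
              x$tests_per_kit, money_format(x$kit_price), x$controls_per_run))
  invisible(x)
}

#' Whole kits consumed by a run
#'
#' `ceiling((n + controls_per_run) / tests_per_kit)`: the run must cover its
#' specimens plus the per-run controls, and opened kits are consumed whole.
#'
#' @param n specimens in the run, integer >= 1 (vectorized).
#' @param kit a [kit_configuration()].
#' @return integer vector of kits consumed.
#' @examples
#' kit <- kit_configuration(12, 875, 2)
#' kits_required(c(10, 22, 12), kit) # 1, 2, 2
#' @export
kits_required <- function(n, kit) {
  if (!inherits(kit, "kit_configuration")) {
    stop_invalid("`kit` must be a kit_configuration")
  }
  n <- check_count(n, "n", min = 1L)
  as.integer(ceiling((n + kit$controls_per_run) / kit$tests_per_kit))
}

#' Reagent cost per specimen
#'
#' Whole kits consumed by the run, priced, divided over the specimens:
#' `kits_required(n, kit) * kit_price / n`. The resulting curve is a sawtooth
#' with local minima exactly at `n = k * tests_per_kit - controls_per_run`,
#' which is what makes some batch sizes much cheaper than slightly larger
#' ones.
#'
#' @inheritParams kits_required
#' @return dollars per specimen (unrounded), vectorized over `n`.
#' @examples
#' kit <- kit_configuration(12, 875, 2)
#' money_round(reagent_cost_per_specimen(c(10, 22, 11), kit))
#' # 87.50 79.55 159.09
#' @export
reagent_cost_per_specimen <- function(n, kit) {
  kits_required(n, kit) * kit$kit_price / n
}

#' Disposable cost line
#'
#' A consumable whose spend has a fixed per-run part (items consumed by
#' controls and run setup) and a marginal per-specimen part. Same
#' amortization form as [labour_step()], but entered directly in dollars.
#'
#' @param name label (e.g. "RNA extraction").
#' @param per_run dollars consumed once per run.
#' @param per_specimen dollars consumed per specimen.
#' @return an object of class `lab_cost_line`.
#' @export
lab_cost_line <- function(name, per_run = 0, per_specimen = 0) {
  structure(
    list(name = as.character(name)[1],
         per_run = check_number(per_run, "per_run", min = 0),
         per_specimen = check_number(per_specimen, "per_specimen", min = 0)),
    class = "lab_cost_line"
  )
}

cost_line_cost <- function(line, n) line$per_run / n + line$per_specimen

#' Central laboratory cost profile
#'
#' Everything needed to price one specimen at the central laboratory as a
#' function of batch size: the kit configuration (reagents), disposable cost
#' lines, labour steps, and a per-specimen facilities-and-equipment constant
#' (an annualized-equipment figure already divided by annual throughput; see
#' [annualize_asset()]).
#'
#' @param kit a [kit_configuration()].
#' @param disposables list of [lab_cost_line()]s.
#' @param labour_steps list of [labour_step()]s.
#' @param facilities_equipment_per_specimen dollars per specimen.
#' @return an object of class `lab_cost_profile`.
#' @export
lab_cost_profile <- function(kit, disposables = list(), labour_steps = list(),
                             facilities_equipment_per_specimen = 0) {
  if (!inherits(kit, "kit_configuration")) {
    stop_invalid("`kit` must be a kit_configuration")
  }
  if (inherits(disposables, "lab_cost_line")) disposables <- list(disposables)
  if (inherits(labour_steps, "labour_step")) labour_steps <- list(labour_steps)
  if (!all(vapply(disposables, inherits, logical(1), "lab_cost_line"))) {
    stop_invalid("`disposables` must be a list of lab_cost_line objects")
  }
  if (!all(vapply(labour_steps, inherits, logical(1), "labour_step"))) {
    stop_invalid("`labour_steps` must be a list of labour_step objects")
  }
  structure(
    list(kit = kit, disposables = disposables, labour_steps = labour_steps,
         facilities_equipment_per_specimen =
           check_number(facilities_equipment_per_specimen,
                        "facilities_equipment_per_specimen", min = 0)),
    class = "lab_cost_profile"
  )
}

#' Laboratory cost per specimen at a given batch size
#'
#' Reagents via [reagent_cost_per_specimen()], disposables and labour with
#' per-run parts amortized over the batch, plus the facilities constant.
#'
#' @param n batch size, integer >= 1.
#' @param profile a [lab_cost_profile()].
#' @return a [cost_breakdown()] with components `reagents`, `disposables`,
#'   `labour`, `facilities`, plus fields `batch_size`, `disposable_items` and
#'   `labour_items` (named numeric vectors of the itemized per-specimen
#'   costs) as attributes.
#' @examples
#' prof <- reference_lab_profile()
#' money_round(lab_cost_per_specimen(22, prof)$total) # 88.73
#' @export
lab_cost_per_specimen <- function(n, profile) {
  if (!inherits(profile, "lab_cost_profile")) {
    stop_invalid("`profile` must be a lab_cost_profile")
  }
  n <- check_count(n, "n", min = 1L)
  disp <- vapply(profile$disposables, cost_line_cost, numeric(1), n = n)
  names(disp) <- vapply(profile$disposables, `[[`, character(1), "name")
  lab <- vapply(profile$labour_steps, labour_step_cost, numeric(1), n = n)
  names(lab) <- vapply(profile$labour_steps, `[[`, character(1), "name")
  bd <- cost_breakdown(c(
    reagents = reagent_cost_per_specimen(n, profile$kit),
    disposables = sum(disp),
    labour = sum(lab),
    facilities = profile$facilities_equipment_per_specimen
  ))
  attr(bd, "batch_size") <- n
  attr(bd, "disposable_items") <- disp
  attr(bd, "labour_items") <- lab
  bd
}

#' Laboratory cost curve over batch sizes
#'
#' @param profile a [lab_cost_profile()].
#' @param n_max largest batch size, integer >= 1.
#' @return a data frame with columns `n`, `reagents`, `disposables`,
#'   `labour`, `facilities`, `total` for `n = 1..n_max` (unrounded dollars
#'   per specimen).
#' @export
batch_cost_curve <- function(profile, n_max = 24) {
  n_max <- check_count(n_max, "n_max", min = 1L)
  rows <- lapply(seq_len(n_max), function(n) {
    bd <- lab_cost_per_specimen(n, profile)
    data.frame(n = n,
               reagents = bd_component(bd, "reagents"),
               disposables = bd_component(bd, "disposables"),
               labour = bd_component(bd, "labour"),
               facilities = bd_component(bd, "facilities"),
               total = bd$total)
  })
  do.call(rbind, rows)
}

#' Cost-optimal batch size
#'
#' Minimizes total cost per specimen over batch sizes `1..n_max`; ties break
#' toward the smallest batch.
#'
#' @inheritParams batch_cost_curve
#' @return a list with `n_opt` (the minimizing batch size) and `curve` (the
#'   full [batch_cost_curve()] data frame).
#' @examples
#' optimal_batch(reference_lab_profile(), 24)$n_opt # 22
#' @export
optimal_batch <- function(profile, n_max = 24) {
  curve <- batch_cost_curve(profile, n_max)
  list(n_opt = curve$n[which.min(curve$total)], curve = curve)
}

#' Infer a kit configuration from observed reagent costs
#'
#' Inverse problem: given per-specimen reagent costs observed at one or more
#' batch sizes, plus structural constraints (controls per run, which batch
#' size is optimal within a range, which batch sizes are dominated), recover
#' the kit configuration by exhaustive search over the number of tests per
#' kit. For each candidate, the kit price is solved from the first
#' observation; the candidate survives if every observation matches to within
#' half a cent after display rounding and every constraint holds on the
#' implied reagent-cost curve.
#'
#' @param observations data frame with columns `n` (batch size) and `cost`
#'   (observed per-specimen reagent cost in dollars, as printed, i.e. cent
#'   rounded).
#' @param controls_per_run known controls per run (default 2).
#' @param tests_per_kit_range candidate kit sizes to search (default `1:48`).
#' @param optimal_n if given, this batch size must minimize the reagent cost
#'   curve over `1..n_max` (smallest-argmin convention).
#' @param n_max upper end of the optimality search range (default 24).
#' @param dominant,dominated if given, the reagent cost at `dominant` must be
#'   strictly below the cost at every batch size in `dominated`.
#' @param tolerance match tolerance in dollars after rounding (default
#'   0.005).
#' @return the unique consistent [kit_configuration()]. If no candidate is
#'   consistent an error of class `vlcost_infeasible` is thrown; if several
#'   are, an error of class `vlcost_ambiguous` whose `data$candidates` lists
#'   the surviving `(tests_per_kit, kit_price)` pairs.
#' @examples
#' obs <- data.frame(n = c(10, 22), cost = c(87.50, 79.55))
#' infer_kit_config(obs, controls_per_run = 2, optimal_n = 22, n_max = 24,
#'                  dominant = 10, dominated = 11:19)
#' @export
infer_kit_config <- function(observations, controls_per_run = 2,
                             tests_per_kit_range = 1:48,
                             optimal_n = NULL, n_max = 24,
                             dominant = NULL, dominated = NULL,
                             tolerance = 0.005) {
  if (!is.data.frame(observations) || nrow(observations) < 1 ||
      !all(c("n", "cost") %in% names(observations))) {
    stop_invalid("`observations` must be a data frame with columns n, cost")
  }
  controls_per_run <- check_count(controls_per_run, "controls_per_run", min = 0L)
  n_max <- check_count(n_max, "n_max", min = 1L)
  obs_n <- check_count(observations$n, "observations$n", min = 1L)
  obs_cost <- observations$cost

  candidates <- list()
  for (t in tests_per_kit_range) {
    if (t <= controls_per_run) next # run must fit a specimen in one kit
    kits <- ceiling((obs_n + controls_per_run) / t)
    price <- obs_cost[1] * obs_n[1] / kits[1]
    if (price <= 0) next
    fitted <- money_round(kits * price / obs_n)
    if (any(abs(fitted - obs_cost) > tolerance + 1e-9)) next

    curve <- ceiling((seq_len(n_max) + controls_per_run) / t) * price /
      seq_len(n_max)
    if (!is.null(optimal_n) && which.min(curve) != optimal_n) next
    if (!is.null(dominant) && !is.null(dominated) &&
        any(curve[dominant] >= curve[dominated])) next

    candidates[[length(candidates) + 1L]] <-
      list(tests_per_kit = t, kit_price = price)
  }

  if (length(candidates) == 0) {
    vl_stop("no kit configuration is consistent with the observations and constraints",
            "vlcost_infeasible")
  }
  if (length(candidates) > 1) {
    desc <- vapply(candidates, function(cand) {
      sprintf("%d tests/kit @ $%s", cand$tests_per_kit,
              money_format(cand$kit_price))
    }, character(1))
    vl_stop(paste0("ambiguous kit configuration; candidates: ",
                   paste(desc, collapse = "; ")),
            "vlcost_ambiguous", data = list(candidates = candidates))
  }
  kit_configuration(candidates[[1]]$tests_per_kit, candidates[[1]]$kit_price,
                    controls_per_run)
}
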