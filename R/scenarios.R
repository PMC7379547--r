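#' @title Reallocation scenarios
#' @description
#' Named network scenarios: `S0` prices the current configuration (every bank
#' recollects its own holdings from its own region); `SUC` is the
#' unconstrained least-cost reallocation with cross-region collection; `SC50`
#' adds the cryotank capacities; `single:<bank>` forces all storage into one
#' bank. Costs of optimized scenarios are reported relative to `S0`.
#' @name scenarios
NULL

scenario_names <- function(instance)
  c("S0", "SUC", "SC50", paste0("single:", instance$banks$id))

#' Parse a scenario name
#'
#' @param name one of `"S0"`, `"SUC"`, `"SC50"` or `"single:<bank_id>"`.
#' @return list with `name` and, for single-bank scenarios, `bank`.
#' @export
scenario_spec <- function(name) {
  if (name %in% c("S0", "SUC", "SC50"))
    return(list(name = name, bank = NULL))
  if (grepl("^single:", name))
    return(list(name = name, bank = sub("^single:", "", name)))
  stop("unknown scenario: ", name, call. = FALSE)
}

#' Price the baseline configuration
#'
#' Builds the fixed allocation in which each bank collects its current
#' holdings from its own region — no cross-region travel, no reallocation —
#' choosing farm or collection-point mode per (breed, bank) to minimize cost,
#' and prices it with the cost engine. No optimization across banks takes
#' place; the result is bit-for-bit reproducible from the inventory.
#'
#' @param instance a [gb_instance()].
#' @param costing_mode `"campaign"` or `"per_dose"`.
#' @param fixed_cost_rule see [price_allocation()].
#' @return object of class `gb_scenario_result` with fields `name`,
#'   `breakdown`, `allocation`, `summary` (bank x species doses) and
#'   `total`.
#' @export
run_s0 <- function(instance, costing_mode = c("campaign", "per_dose"),
                   fixed_cost_rule = c("always", "active_only")) {
  costing_mode <- match.arg(costing_mode)
  fixed_cost_rule <- match.arg(fixed_cost_rule)
  inv <- instance$inventory[instance$inventory$A > 0, , drop = FALSE]
  if (any(inv$e == 0))
    stop("baseline requires stored breeds to be available in their bank's region",
         call. = FALSE)
  mode <- character(nrow(inv))
  for (i in seq_len(nrow(inv))) {
    cf_cost <- collection_cost(instance, inv$species[i], inv$bank[i], "farm",
                               inv$A[i], costing_mode) +
      travel_cost(instance, inv$bank[i], inv$bank[i], "farm", inv$A[i])
    cp_cost <- collection_cost(instance, inv$species[i], inv$bank[i], "point",
                               inv$A[i], costing_mode) +
      travel_cost(instance, inv$bank[i], inv$bank[i], "point", inv$A[i])
    mode[i] <- if (cf_cost < cp_cost) "farm" else "point"
  }
  alloc <- data.frame(breed = inv$breed, species = inv$species,
                      bank = inv$bank, region = inv$bank, mode = mode,
                      doses = inv$A, stringsAsFactors = FALSE)
  alloc <- alloc[order(alloc$breed, alloc$bank), , drop = FALSE]
  rownames(alloc) <- NULL
  breakdown <- price_allocation(instance, alloc, costing_mode, fixed_cost_rule)
  structure(list(name = "S0", breakdown = breakdown, allocation = alloc,
                 summary = allocation_summary(instance, alloc),
                 total = breakdown$total, status = "optimal",
                 solution = NULL, relative_cost_vs_S0 = 0),
            class = "gb_scenario_result")
}

allocation_summary <- function(instance, alloc) {
  ids <- instance$banks$id
  sp <- instance$species$species
  m <- matrix(0, length(ids), length(sp), dimnames = list(ids, sp))
  if (nrow(alloc) > 0) {
    agg <- tapply(alloc$doses, list(alloc$bank, alloc$species), sum)
    m[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  }
  m
}

#' Run a named scenario
#'
#' `SUC` solves the least-cost recollection with unlimited capacity; `SC50`
#' the same with the instance's tank capacities enforced; `single:<bank>`
#' forces every breed's storage into one bank (unlimited capacity). The
#' result carries the cost relative to the baseline, computed as
#' `100 * (C_scenario - C_S0) / C_S0`.
#'
#' @param instance a [gb_instance()].
#' @param spec a scenario name or [scenario_spec()].
#' @param s0 optionally a precomputed [run_s0()] result (recomputed if NULL).
#' @inheritParams run_s0
#' @param ... passed to [model_config()] (e.g. `node_limit`).
#' @return a `gb_scenario_result`; its `solution` field holds the full
#'   [solve_model()] output for optimized scenarios.
#' @export
run_scenario <- function(instance, spec, s0 = NULL,
                         costing_mode = c("campaign", "per_dose"),
                         fixed_cost_rule = c("always", "active_only"), ...) {
  costing_mode <- match.arg(costing_mode)
  fixed_cost_rule <- match.arg(fixed_cost_rule)
  if (is.character(spec)) spec <- scenario_spec(spec)
  if (spec$name == "S0") {
    res <- run_s0(instance, costing_mode, fixed_cost_rule)
    return(res)
  }
  if (is.null(s0)) s0 <- run_s0(instance, costing_mode, fixed_cost_rule)
  cfg <- model_config(
    objective = "min_cost", demand_rule = "recollect_current",
    capacity_on = (spec$name == "SC50"),
    forced_bank = spec$bank, costing_mode = costing_mode,
    fixed_cost_rule = fixed_cost_rule, ...)
  sol <- solve_model(build_model(instance, cfg))
  rel <- if (sol$status == "infeasible") NA_real_
         else 100 * (sol$objective - s0$total) / s0$total
  structure(list(name = spec$name, breakdown = sol$breakdown,
                 allocation = sol$allocation,
                 summary = allocation_summary(instance, sol$allocation),
                 total = sol$objective, status = sol$status, solution = sol,
                 relative_cost_vs_S0 = rel),
            class = "gb_scenario_result")
}

#' @export
print.gb_scenario_result <- function(x, ...) {
  cat("<gb_scenario_result> ", x$name, ": total ",
      format(round(x$total, 2), big.mark = ","), " EUR",
      if (x$name != "S0") sprintf(" (%+.1f%% vs S0)", x$relative_cost_vs_S0),
      " [", x$status, "]\n", sep = "")
  invisible(x)
}

#' Compare scenarios on one instance
#'
#' Runs the requested scenarios (sharing one baseline) and tabulates their
#' total costs and percent difference versus `S0`. Rows follow the canonical
#' order `S0, SUC, SC50, single:<bank>...`; the per-bank stored-dose
#' occupancy of every scenario is attached as attribute `"occupancy"`.
#'
#' @param instance a [gb_instance()].
#' @param specs character vector of scenario names; default all 14.
#' @inheritParams run_s0
#' @param ... passed to [run_scenario()].
#' @return data frame with columns `scenario, status, total_cost, pct_vs_S0`.
#' @export
compare_scenarios <- function(instance, specs = scenario_names(instance),
                              costing_mode = c("campaign", "per_dose"), ...) {
  costing_mode <- match.arg(costing_mode)
  canon <- scenario_names(instance)
  specs <- canon[canon %in% specs]
  s0 <- run_s0(instance, costing_mode)
  occ <- matrix(0, length(instance$banks$id), length(specs),
                dimnames = list(instance$banks$id, specs))
  rows <- lapply(specs, function(nm) {
    res <- if (nm == "S0") s0
           else run_scenario(instance, nm, s0 = s0, costing_mode = costing_mode, ...)
    occ[, nm] <<- rowSums(res$summary)
    data.frame(scenario = nm, status = res$status, total_cost = res$total,
               pct_vs_S0 = res$relative_cost_vs_S0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "occupancy") <- occ
  out
}
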