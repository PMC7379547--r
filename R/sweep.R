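#' Budget sweep configuration
#'
#' Defines the grid of budgets over which diversity (the number of
#' conservable breeds) is maximized: `B_i = B0 + i * (BMax - B0) / n` for
#' `i = 1..n`. Defaults mirror the bundled network's budget range (600 to
#' 118,800 EUR over 100 points). Only variable spend — collection campaigns,
#' travel and per-dose storage — counts against the budget; the banks' fixed
#' maintenance costs vastly exceed this budget range and are excluded (see
#' the methods vignette).
#'
#' @param b0 initial budget (EUR), must satisfy `0 <= b0 < bmax`.
#' @param bmax maximum budget (EUR).
#' @param n number of budget points.
#' @param species optional species subset; the sweep then runs on the
#'   species-restricted sub-inventory.
#' @param capacity_on enforce tank capacities during the sweep (off by
#'   default: the diversity curves assume unlimited tanks).
#' @param costing_mode `"campaign"` or `"per_dose"`.
#' @return list of class `gb_sweep_config`.
#' @export
sweep_config <- function(b0 = 600, bmax = 118800, n = 100L, species = NULL,
                         capacity_on = FALSE,
                         costing_mode = c("campaign", "per_dose")) {
  stopifnot(b0 >= 0, b0 < bmax, n >= 1)
  structure(list(b0 = b0, bmax = bmax, n = as.integer(n), species = species,
                 capacity_on = capacity_on,
                 costing_mode = match.arg(costing_mode)),
            class = "gb_sweep_config")
}

#' Budget grid of a sweep
#'
#' @param config a [sweep_config()].
#' @return numeric vector `B_i = b0 + i * (bmax - b0) / n`, `i = 1..n`; the
#'   last point is exactly `bmax`.
#' @export
budget_grid <- function(config) {
  config$b0 + seq_len(config$n) * (config$bmax - config$b0) / config$n
}

#' Run a diversity-cost sweep
#'
#' For each budget point solves the diversity-maximization model
#' (free semicontinuous dose levels, budget enforced, breed-count measure)
#' and records the optimum `D_i` and the variable spend it uses. Raw optima
#' are reported without monotone repair — monotonicity of `D(B)` is a
#' property the test suite asserts, not one the sweep enforces.
#'
#' @param instance a [gb_instance()].
#' @param config a [sweep_config()].
#' @return data frame of class `gb_sweep_result`: columns
#'   `i, budget, diversity, cost_used, feasible`.
#' @export
run_sweep <- function(instance, config = sweep_config()) {
  if (!is.null(config$species)) {
    keep <- instance$inventory$species %in% config$species
    instance$inventory <- instance$inventory[keep, , drop = FALSE]
    if (nrow(instance$inventory) == 0L)
      stop("species filter leaves no breeds", call. = FALSE)
  }
  grid <- budget_grid(config)
  base_cfg <- model_config(objective = "max_diversity",
                           demand_rule = "free_semicontinuous",
                           budget_on = TRUE, TB = grid[1],
                           capacity_on = config$capacity_on,
                           costing_mode = config$costing_mode)
  model <- build_model(instance, base_cfg)
  rows <- lapply(seq_along(grid), function(i) {
    model$config$TB <- grid[i]
    sol <- solve_model(model)
    data.frame(i = i, budget = grid[i],
               diversity = if (sol$status == "infeasible") NA_integer_
                           else sol$diversity,
               cost_used = if (sol$status == "infeasible") NA_real_
                           else sol$budget_spend,
               feasible = sol$status != "infeasible")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gb_sweep_result", class(out))
  out
}

#' Marginal cost per conserved breed along a sweep
#'
#' For consecutive sweep rows with a diversity gain emits the incremental
#' cost per breed, `dB / dD`; rows where diversity decreases (possible only
#' through solver tolerance) are flagged and excluded. The minimum and
#' maximum marginal cost over the curve and the average cost per breed at
#' the final (saturation) point are attached as attributes.
#'
#' @param sweep_result a [run_sweep()] result (at least 2 points).
#' @return data frame `from_i, to_i, delta_budget, delta_diversity,
#'   marginal_cost`, with attributes `min_marginal`, `max_marginal` and
#'   `avg_cost_at_saturation`.
#' @export
marginal_costs <- function(sweep_result) {
  s <- sweep_result[sweep_result$feasible, , drop = FALSE]
  if (nrow(s) < 2L) stop("sweep must contain at least 2 feasible points",
                         call. = FALSE)
  dD <- diff(s$diversity)
  dB <- diff(s$budget)
  keep <- dD > 0
  out <- data.frame(from_i = s$i[-nrow(s)][keep], to_i = s$i[-1][keep],
                    delta_budget = dB[keep], delta_diversity = dD[keep],
                    marginal_cost = dB[keep] / dD[keep])
  rownames(out) <- NULL
  attr(out, "min_marginal") <- if (nrow(out) > 0) min(out$marginal_cost) else NA_real_
  attr(out, "max_marginal") <- if (nrow(out) > 0) max(out$marginal_cost) else NA_real_
  last <- s[nrow(s), ]
  attr(out, "avg_cost_at_saturation") <-
    if (last$diversity > 0) last$cost_used / last$diversity else NA_real_
  out
}
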