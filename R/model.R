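#' Model configuration
#'
#' Options controlling how the planning model is built and solved.
#'
#' @param objective `"min_cost"` (minimize total network cost for a fixed
#'   recollection demand) or `"max_diversity"` (maximize the number of
#'   conserved breeds under a budget, with free semicontinuous dose levels).
#' @param demand_rule `"recollect_current"`: every breed's collected total
#'   must equal its current network-wide holdings (per-breed dose bounds are
#'   not additionally imposed — the quantities are predetermined);
#'   `"free_semicontinuous"`: each breed's total is either 0 or in
#'   `[mu, M]` for its species.
#' @param capacity_on enforce per-bank cryotank capacities.
#' @param budget_on enforce the total budget `TB`; budget accounting covers
#'   variable spend only (collection campaigns, travel and per-dose storage;
#'   fixed maintenance costs are excluded — see the methods vignette).
#' @param TB budget in EUR; `NULL` uses the instance's `TB`.
#' @param forced_bank optional bank id: all storage is forced to this bank
#'   (single-bank centralization scenarios).
#' @param costing_mode `"campaign"` or `"per_dose"`, see [collection_cost()].
#' @param diversity_measure `"breed_count"` (number of conserved breeds,
#'   default) or `"total_doses"` (the literal dose-sum alternative).
#' @param fixed_cost_rule `"always"` or `"active_only"`, see
#'   [price_allocation()]. With `"active_only"` the optimizer still minimizes
#'   variable cost; fixed costs are then priced on the banks actually used.
#' @param clamp_demand if `TRUE`, recollection demand is capped at the
#'   species maximum `M` per breed (off by default: current holdings are
#'   recollected in full).
#' @param mip_gap relative optimality tolerance.
#' @param node_limit branch-and-bound node budget for capacitated
#'   fixed-charge solves; if exhausted the best feasible solution is returned
#'   with its proven gap.
#' @return list of class `gb_model_config`.
#' @export
model_config <- function(objective = c("min_cost", "max_diversity"),
                         demand_rule = c("recollect_current", "free_semicontinuous"),
                         capacity_on = FALSE, budget_on = FALSE, TB = NULL,
                         forced_bank = NULL,
                         costing_mode = c("campaign", "per_dose"),
                         diversity_measure = c("breed_count", "total_doses"),
                         fixed_cost_rule = c("always", "active_only"),
                         clamp_demand = FALSE,
                         mip_gap = 1e-6, node_limit = 400L) {
  structure(list(
    objective = match.arg(objective), demand_rule = match.arg(demand_rule),
    capacity_on = capacity_on, budget_on = budget_on, TB = TB,
    forced_bank = forced_bank, costing_mode = match.arg(costing_mode),
    diversity_measure = match.arg(diversity_measure),
    fixed_cost_rule = match.arg(fixed_cost_rule),
    clamp_demand = clamp_demand, mip_gap = mip_gap,
    node_limit = as.integer(node_limit)), class = "gb_model_config")
}

# Precompute per-species unit-cost and campaign-charge tables.
#   U_<mode>[[s]][g, j]: cost of one dose collected by bank g in region j
#     (storage mc_g * T + travel per dose; plus donor cost per dose when
#     costing per_dose)
#   FC_<mode>[[s]][g]: campaign charge of bank g for species s (0 per_dose)
prep_cost_tables <- function(instance, costing_mode) {
  b <- instance$banks
  ids <- b$id
  ng <- length(ids)
  D <- instance$distances[ids, ids, drop = FALSE]
  per_trip <- b$tc / b$k
  tpd_farm <- per_trip * sweep(D, 2, b$d, "+")    # (d_j + D[g,j]) rowwise g
  tpd_point <- per_trip * D
  store <- instance$T * b$mc
  sp <- instance$species$species
  U_farm <- U_point <- FC_farm <- FC_point <- list()
  for (s in sp) {
    r <- species_row(instance, s)$r
    ci <- match(paste(ids, s), paste(instance$costs$bank, instance$costs$species))
    cf <- instance$costs$cf[ci]; cc <- instance$costs$cc[ci]
    if (costing_mode == "campaign") {
      U_farm[[s]] <- store + tpd_farm
      U_point[[s]] <- store + tpd_point
      FC_farm[[s]] <- r * cf
      FC_point[[s]] <- r * cc
    } else {
      U_farm[[s]] <- store + tpd_farm + r * cf
      U_point[[s]] <- store + tpd_point + r * cc
      FC_farm[[s]] <- rep(0, ng)
      FC_point[[s]] <- rep(0, ng)
    }
  }
  list(ids = ids, ng = ng, U_farm = U_farm, U_point = U_point,
       FC_farm = FC_farm, FC_point = FC_point)
}

# Cheapest (bank, region, mode) triple for one breed at a given dose level,
# scanning candidates in lexicographic (bank, region, mode) order so ties
# resolve to the first bank/region and farm before point.
best_triple <- function(tab, species, avail, banks_idx, level) {
  na <- length(avail); nbk <- length(banks_idx)
  fm <- sweep(tab$U_farm[[species]][banks_idx, avail, drop = FALSE] * level,
              1, tab$FC_farm[[species]][banks_idx], "+")
  pm <- sweep(tab$U_point[[species]][banks_idx, avail, drop = FALSE] * level,
              1, tab$FC_point[[species]][banks_idx], "+")
  arr <- array(0, c(2L, na, nbk))
  arr[1L, , ] <- t(fm); arr[2L, , ] <- t(pm)
  i <- which.min(arr)
  m <- (i - 1L) %% 2L + 1L
  j <- ((i - 1L) %/% 2L) %% na + 1L
  g <- (i - 1L) %/% (2L * na) + 1L
  list(bank = banks_idx[g], region = avail[j],
       mode = c("farm", "point")[m], cost = arr[i])
}

#' Build the planning model
#'
#' Assembles the model for an instance under a [model_config()]: the breed
#' demand/bound table, availability sets, precomputed unit-cost and
#' campaign-charge tables, and the symbolic size of the full matrix-form
#' formulation (see [count_model_size()]). Solve it with [solve_model()].
#'
#' @param instance a [gb_instance()].
#' @param config a [model_config()].
#' @return object of class `gb_model`.
#' @export
build_model <- function(instance, config = model_config()) {
  stopifnot(inherits(config, "gb_model_config"))
  if (!is.null(config$forced_bank) &&
      !config$forced_bank %in% instance$banks$id)
    stop("forced_bank ", config$forced_bank, " does not exist", call. = FALSE)
  if (is.null(config$TB)) config$TB <- instance$TB

  inv <- instance$inventory
  ids <- instance$banks$id
  breeds <- sort(unique(inv$breed))
  spv <- inv$species[match(breeds, inv$breed)]
  si <- match(spv, instance$species$species)
  M <- instance$species$M[si]
  mu <- instance$species$mu_factor[si] * M
  dem <- as.numeric(tapply(inv$A, inv$breed, sum)[breeds])
  if (config$clamp_demand) dem <- pmin(dem, M)
  avail <- lapply(breeds, function(bb) {
    sort(match(unique(inv$bank[inv$breed == bb & inv$e == 1]), ids))
  })
  if (any(vapply(avail, length, 1L) == 0L))
    stop("infeasible: a breed has no available collection region", call. = FALSE)

  structure(list(
    instance = instance, config = config,
    breeds = data.frame(breed = breeds, species = spv, demand = dem,
                        mu = mu, M = M, stringsAsFactors = FALSE),
    avail = avail,
    tab = prep_cost_tables(instance, config$costing_mode)),
    class = "gb_model")
}

#' @export
print.gb_model <- function(x, ...) {
  n <- count_model_size(x)
  cat("<gb_model> ", x$config$objective, "/", x$config$demand_rule, ": ",
      nrow(x$breeds), " breeds x ", x$tab$ng, " banks (",
      format(n[["n_variables"]], big.mark = ","), " variables, ",
      format(n[["n_constraints"]], big.mark = ","), " constraints)\n", sep = "")
  invisible(x)
}

#' Size of the matrix-form formulation
#'
#' Counts the decision variables and constraint rows of the fully
#' instantiated matrix-form model, excluding simple variable bounds.
#' Variables: the collection variables `SF` and `SP` (breed x bank x region
#' each), the stored-dose variables `SB` (breed x bank), the per-breed
#' conservation indicators `y`, and the five per-bank cost variables
#' (`MC, CC, TC, VC, C`). Rows: the `SB` definition (breed x bank), the
#' per-(breed, bank) indicator link, the per-breed semicontinuous pair, the
#' per-breed demand balance (recollection models), the five per-bank cost
#' definitions, and — when enforced — the per-bank capacity rows and the
#' budget row. Availability restrictions are applied through variable bounds
#' and are therefore not counted. The counts are structural: they depend only
#' on the numbers of breeds and banks and the active constraint families,
#' never on cost values.
#'
#' @param model a [gb_model()].
#' @return named integer vector `c(n_variables, n_constraints)`.
#' @export
count_model_size <- function(model) {
  nb <- nrow(model$breeds)
  ng <- model$tab$ng
  n_var <- 2L * nb * ng * ng + nb * ng + nb + 5L * ng
  n_con <- nb * ng +            # SB definition
    nb * ng +                   # indicator link per (breed, bank)
    2L * nb +                   # semicontinuous lower/upper pair
    (if (model$config$demand_rule == "recollect_current") nb else 0L) +
    5L * ng +                   # cost decomposition rows
    (if (model$config$capacity_on) ng else 0L) +
    (if (model$config$budget_on) 1L else 0L)
  c(n_variables = n_var, n_constraints = n_con)
}

# exact cost of storing x doses of breed row `bi` at bank `g` (cheapest
# region/mode), plus the chosen triple
exact_pair <- function(model, bi, g, x) {
  best_triple(model$tab, model$breeds$species[bi], model$avail[[bi]], g, x)
}

# vectorized over banks: cheapest exact cost per bank of shipping `dem`
# doses of breed `bi` (emat) and the smallest campaign charge per bank (fmin)
best_per_bank <- function(model, bi, dem) {
  tab <- model$tab
  s <- model$breeds$species[bi]
  avail <- model$avail[[bi]]
  Uf <- tab$U_farm[[s]][, avail, drop = FALSE]
  Up <- tab$U_point[[s]][, avail, drop = FALSE]
  uf <- do.call(pmin, asplit(Uf, 2))
  up <- do.call(pmin, asplit(Up, 2))
  ef <- tab$FC_farm[[s]] + dem * uf
  ep <- tab$FC_point[[s]] + dem * up
  list(emat = pmin(ef, ep), fmin = pmin(tab$FC_farm[[s]], tab$FC_point[[s]]))
}

#' Solve the planning model
#'
#' Exact solver exploiting the model's structure. Uncapacitated cost
#' minimization decomposes per breed (splitting a breed's fixed demand across
#' banks can never reduce cost when unit costs are linear and campaign
#' charges accrue per activation), so each breed is assigned its cheapest
#' (bank, region, mode) triple. With capacities the problem is a fixed-charge
#' transportation problem: a transportation linear program (campaign charges
#' amortized per dose) provides lower bounds inside a branch-and-bound on
#' campaign activations; per-dose costing needs no charges and the
#' transportation optimum is returned directly. Diversity maximization under
#' a budget selects breeds at their species minimum dose level in increasing
#' order of minimal conservation cost, which is optimal for the breed-count
#' measure without capacities.
#'
#' @param model a [gb_model()].
#' @return object of class `gb_solution`: `status` (`"optimal"`,
#'   `"feasible"` or `"infeasible"`), `objective` (EUR for cost minimization,
#'   breeds or doses for diversity), `achieved_gap`, `allocation` (data frame
#'   `breed, species, bank, region, mode, doses`), `y` (named 0/1 vector),
#'   `diversity`, and `breakdown` (the solution independently re-priced by
#'   [price_allocation()]).
#' @export
solve_model <- function(model) {
  stopifnot(inherits(model, "gb_model"))
  cfg <- model$config
  if (cfg$objective == "min_cost") {
    if (cfg$demand_rule != "recollect_current")
      stop("min_cost is supported with demand_rule = 'recollect_current'",
           call. = FALSE)
    solve_min_cost(model)
  } else {
    if (cfg$demand_rule != "free_semicontinuous")
      stop("max_diversity is supported with demand_rule = 'free_semicontinuous'",
           call. = FALSE)
    solve_max_diversity(model)
  }
}

finish_solution <- function(model, alloc, status, objective, gap, diversity) {
  cfg <- model$config
  y <- stats::setNames(rep(0L, nrow(model$breeds)), model$breeds$breed)
  if (nrow(alloc) > 0) {
    tot <- tapply(alloc$doses, alloc$breed, sum)
    y[names(tot)[tot > 0]] <- 1L
    alloc <- alloc[order(alloc$breed, match(alloc$bank, model$tab$ids)), ,
                   drop = FALSE]
    rownames(alloc) <- NULL
  }
  breakdown <- price_allocation(model$instance, alloc,
                                costing_mode = cfg$costing_mode,
                                fixed_cost_rule = cfg$fixed_cost_rule)
  structure(list(status = status, objective = objective, achieved_gap = gap,
                 allocation = alloc, y = y, diversity = diversity,
                 breakdown = breakdown, config = cfg),
            class = "gb_solution")
}

#' @export
print.gb_solution <- function(x, ...) {
  cat("<gb_solution> status: ", x$status,
      " | objective: ", format(round(x$objective, 2), big.mark = ","),
      " | breeds conserved: ", x$diversity,
      if (x$achieved_gap > 0) paste0(" | gap: ", signif(x$achieved_gap, 3)) else "",
      "\n", sep = "")
  invisible(x)
}

fixed_total <- function(model) model$instance$T * sum(model$instance$banks$F)

solve_min_cost <- function(model) {
  cfg <- model$config
  br <- model$breeds
  tab <- model$tab
  ng <- tab$ng
  act <- which(br$demand > 0)
  banks_idx <- if (is.null(cfg$forced_bank)) seq_len(ng)
               else match(cfg$forced_bank, tab$ids)

  if (!cfg$capacity_on) {
    rows <- vector("list", length(act))
    varcost <- 0
    for (ii in seq_along(act)) {
      bi <- act[ii]
      bt <- best_triple(tab, br$species[bi], model$avail[[bi]], banks_idx,
                        br$demand[bi])
      rows[[ii]] <- data.frame(breed = br$breed[bi], species = br$species[bi],
                               bank = tab$ids[bt$bank],
                               region = tab$ids[bt$region], mode = bt$mode,
                               doses = br$demand[bi], stringsAsFactors = FALSE)
      varcost <- varcost + bt$cost
    }
    alloc <- if (length(rows) > 0) do.call(rbind, rows) else empty_allocation()
    return(min_cost_wrapup(model, alloc, varcost, gap = 0, status = "optimal"))
  }

  # capacitated: fixed-charge transportation with branch-and-bound
  dem <- br$demand[act]
  cap <- model$instance$banks$cp
  if (sum(dem) > sum(cap[banks_idx]) + 1e-6)
    return(finish_solution(model, empty_allocation(), "infeasible",
                           NA_real_, NA_real_, 0L))

  nb <- length(act)
  emat <- fmat <- matrix(Inf, nb, ng)
  for (ii in seq_len(nb)) {
    bp <- best_per_bank(model, act[ii], dem[ii])
    emat[ii, banks_idx] <- bp$emat[banks_idx]
    fmat[ii, banks_idx] <- bp$fmin[banks_idx]
  }
  cmat <- emat / dem                            # amortized LP cost per dose

  if (cfg$costing_mode == "per_dose") {
    # no fixed charges: the transportation LP is the exact model
    res <- transport_lp(cmat, dem, cap)
    if (res$status != "optimal")
      return(finish_solution(model, empty_allocation(), "infeasible",
                             NA_real_, NA_real_, 0L))
    alloc <- flow_to_alloc(model, act, res$flow)
    return(min_cost_wrapup(model, alloc, res$objective, gap = 0,
                           status = "optimal"))
  }

  bb <- branch_and_bound_fc(model, act, dem, cap, emat, fmat)
  if (is.null(bb$flow))
    return(finish_solution(model, empty_allocation(), "infeasible",
                           NA_real_, NA_real_, 0L))
  alloc <- flow_to_alloc(model, act, bb$flow)
  min_cost_wrapup(model, alloc, bb$value, gap = bb$gap, status = bb$status)
}

# turn a breed x bank flow matrix into allocation rows, choosing the cheapest
# (region, mode) for each positive cell at its shipped volume
flow_to_alloc <- function(model, act, flow, eps = 1e-6) {
  tab <- model$tab
  br <- model$breeds
  rows <- list()
  for (ii in seq_len(nrow(flow))) {
    for (g in which(flow[ii, ] > eps)) {
      bi <- act[ii]
      bt <- exact_pair(model, bi, g, flow[ii, g])
      rows[[length(rows) + 1L]] <-
        data.frame(breed = br$breed[bi], species = br$species[bi],
                   bank = tab$ids[g], region = tab$ids[bt$region],
                   mode = bt$mode, doses = flow[ii, g],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) > 0) do.call(rbind, rows) else empty_allocation()
}

min_cost_wrapup <- function(model, alloc, varcost, gap, status) {
  cfg <- model$config
  if (cfg$fixed_cost_rule == "always") {
    objective <- varcost + fixed_total(model)
  } else {
    active <- unique(alloc$bank[alloc$doses > 0])
    objective <- varcost + model$instance$T *
      sum(model$instance$banks$F[model$instance$banks$id %in% active])
  }
  if (cfg$budget_on && !is.na(cfg$TB) && varcost > cfg$TB * (1 + 1e-9))
    return(finish_solution(model, alloc, "infeasible", objective, gap,
                           sum(tapply(alloc$doses, alloc$breed, sum) > 0)))
  div <- if (nrow(alloc) > 0)
    sum(tapply(alloc$doses, alloc$breed, sum) > 0) else 0L
  finish_solution(model, alloc, status, objective, gap, as.integer(div))
}

# Branch-and-bound for the capacitated fixed-charge (campaign) model.
#
# LP relaxation: a transportation problem whose free-arc cost amortizes the
# campaign charge over the breed's full demand, c = (FC + U*dem)/dem — a
# valid underestimate of FC + U*x for x <= dem, tight at x = dem. Branching
# fixes a campaign activation z[b,g]: "closed" removes the arc, "open"
# charges min FC as a constant and prices the arc at
# ((FC + U*dem) - min FC)/dem, again tight at full demand. Every node's LP
# flow is repaired into a feasible integral assignment so incumbents improve
# immediately; exhaustion of the node budget returns the incumbent with its
# proven gap.
branch_and_bound_fc <- function(model, act, dem, cap, emat, fmat) {
  nb <- length(act); ng <- ncol(emat)
  eps <- 1e-7
  node_limit <- model$config$node_limit
  rel_gap <- model$config$mip_gap
  cmat <- emat / dem
  copen <- (emat - fmat) / dem

  exact_value <- function(flow) {
    v <- 0
    for (ii in seq_len(nb)) {
      used <- which(flow[ii, ] > eps)
      for (g in used) {
        v <- v + if (flow[ii, g] >= dem[ii] - eps) emat[ii, g]
        else exact_pair(model, act[ii], g, flow[ii, g])$cost
      }
    }
    v
  }

  # repair an LP flow into a feasible assignment: unsplit breeds keep their
  # bank; split breeds are consolidated into a used bank with headroom when
  # possible, otherwise left split (still feasible, priced exactly)
  repair <- function(flow) {
    x <- flow
    splitters <- which(rowSums(x > eps) > 1L)
    if (length(splitters) > 0L) {
      resid <- cap - colSums(x)
      for (ii in splitters) {
        used <- which(x[ii, ] > eps)
        room <- resid + x[ii, ]
        cand <- used[room[used] >= dem[ii] - eps & is.finite(emat[ii, used])]
        if (length(cand) == 0L) next
        g <- cand[which.min(emat[ii, cand])]
        resid <- resid + x[ii, ]
        x[ii, ] <- 0
        x[ii, g] <- dem[ii]
        resid <- resid - x[ii, ]
      }
    }
    list(flow = x, value = exact_value(x))
  }

  lp_of <- function(open, closed, init = NULL) {
    lpcost <- cmat
    lpcost[closed] <- Inf
    lpcost[open] <- copen[open]
    res <- transport_lp(lpcost, dem, cap, init = init)
    if (res$status != "optimal") return(NULL)
    list(flow = res$flow, bound = res$objective + sum(fmat[open]))
  }

  root <- lp_of(matrix(FALSE, nb, ng), matrix(FALSE, nb, ng))
  if (is.null(root)) return(list(flow = NULL))
  incumbent <- repair(root$flow)

  nodes <- list(list(open = matrix(FALSE, nb, ng),
                     closed = matrix(FALSE, nb, ng), lp = root))
  explored <- 0L
  proven_lb <- -Inf
  terminal_lbs <- numeric(0)
  while (length(nodes) > 0 && explored < node_limit) {
    bounds <- vapply(nodes, function(n) n$lp$bound, 0)
    k <- which.min(bounds)
    node <- nodes[[k]]
    nodes[[k]] <- NULL
    explored <- explored + 1L
    if (node$lp$bound >= incumbent$value * (1 - rel_gap) - 1e-9) {
      proven_lb <- node$lp$bound  # best-first: nothing cheaper remains
      nodes <- list()
      break
    }
    splits <- rowSums(node$lp$flow > pmax(eps, 1e-9 * dem))
    if (all(splits <= 1L)) {
      val <- exact_value(node$lp$flow)
      if (val < incumbent$value)
        incumbent <- list(flow = node$lp$flow, value = val)
      next
    }
    # branch on a used, not-yet-opened arc of a split breed; a node whose
    # split arcs are all committed open cannot be partitioned further and
    # becomes a terminal leaf (its bound still counts towards the gap)
    ii <- 0L; g <- 0L
    for (b in order(splits, decreasing = TRUE)) {
      if (splits[b] <= 1L) break
      arcs <- which(node$lp$flow[b, ] > eps & !node$open[b, ])
      if (length(arcs) > 0L) {
        ii <- b; g <- arcs[which.max(node$lp$flow[b, arcs])]
        break
      }
    }
    if (ii == 0L) {
      val <- exact_value(node$lp$flow)
      if (val < incumbent$value)
        incumbent <- list(flow = node$lp$flow, value = val)
      terminal_lbs <- c(terminal_lbs, node$lp$bound)
      next
    }
    for (branch in c("closed", "open")) {
      open <- node$open; closed <- node$closed
      init <- node$lp$flow
      if (branch == "closed") {
        closed[ii, g] <- TRUE
        init[ii, g] <- 0                        # re-route just this arc
      } else {
        open[ii, g] <- TRUE
        init[ii, ] <- 0                         # row cost changed: re-route row
      }
      lp <- lp_of(open, closed, init = init)
      if (is.null(lp)) next
      rep_sol <- repair(lp$flow)
      if (rep_sol$value < incumbent$value) incumbent <- rep_sol
      if (lp$bound < incumbent$value * (1 - rel_gap))
        nodes[[length(nodes) + 1L]] <- list(open = open, closed = closed, lp = lp)
    }
  }

  open_lbs <- if (length(nodes) > 0)
    vapply(nodes, function(n) n$lp$bound, 0) else numeric(0)
  lb <- min(c(open_lbs, terminal_lbs,
              if (is.finite(proven_lb)) proven_lb else incumbent$value))
  gap <- max(0, (incumbent$value - lb) / max(1, incumbent$value))
  list(flow = incumbent$flow, value = incumbent$value, gap = gap,
       status = if (gap <= rel_gap + 1e-12) "optimal" else "feasible")
}

solve_max_diversity <- function(model) {
  cfg <- model$config
  br <- model$breeds
  tab <- model$tab
  ng <- tab$ng
  banks_idx <- if (is.null(cfg$forced_bank)) seq_len(ng)
               else match(cfg$forced_bank, tab$ids)
  TB <- if (cfg$budget_on) cfg$TB else NA_real_
  nb <- nrow(br)

  best <- vector("list", nb)
  w <- numeric(nb)
  for (bi in seq_len(nb)) {
    best[[bi]] <- best_triple(tab, br$species[bi], model$avail[[bi]],
                              banks_idx, br$mu[bi])
    w[bi] <- best[[bi]]$cost
  }

  if (cfg$diversity_measure == "total_doses")
    return(solve_max_doses(model, banks_idx, TB))

  ord <- order(w, br$breed)
  take <- logical(nb)
  if (!cfg$capacity_on) {
    if (is.na(TB)) {
      take[ord] <- TRUE
    } else {
      sel <- ord[cumsum(w[ord]) <= TB * (1 + 1e-12)]
      take[sel] <- TRUE
    }
  }

  if (cfg$capacity_on) {
    resid <- model$instance$banks$cp
    spend <- 0
    for (bi in ord) {
      cand <- banks_idx[order(vapply(banks_idx, function(g)
        exact_pair(model, bi, g, br$mu[bi])$cost, 0))]
      for (g in cand) {
        if (resid[g] < br$mu[bi]) next
        bt <- exact_pair(model, bi, g, br$mu[bi])
        if (!is.na(TB) && spend + bt$cost > TB * (1 + 1e-12)) break
        best[[bi]] <- bt
        resid[g] <- resid[g] - br$mu[bi]
        spend <- spend + bt$cost
        take[bi] <- TRUE
        break
      }
    }
  }

  rows <- lapply(which(take), function(bi) {
    bt <- best[[bi]]
    data.frame(breed = br$breed[bi], species = br$species[bi],
               bank = tab$ids[bt$bank], region = tab$ids[bt$region],
               mode = bt$mode, doses = br$mu[bi], stringsAsFactors = FALSE)
  })
  alloc <- if (length(rows) > 0) do.call(rbind, rows) else empty_allocation()
  D <- sum(take)
  # upper bound from the uncapacitated relaxation (which the greedy solves
  # exactly when no capacity is enforced)
  ub <- if (is.na(TB)) nb else length(which(cumsum(w[ord]) <= TB * (1 + 1e-12)))
  gap <- max(0, (ub - D) / max(1, ub))
  status <- if (gap <= model$config$mip_gap) "optimal" else "feasible"
  sol <- finish_solution(model, alloc, status, as.numeric(D), gap, as.integer(D))
  sol$budget_spend <- sum(vapply(which(take), function(bi) best[[bi]]$cost, 0))
  sol
}

# literal dose-sum diversity: fixed-charge knapsack, solved by a greedy fill
# in increasing amortized cost per dose with an LP-relaxation upper bound;
# optimality is only claimed when the bound is attained
solve_max_doses <- function(model, banks_idx, TB) {
  br <- model$breeds
  tab <- model$tab
  nb <- nrow(br)
  E <- numeric(nb); u <- numeric(nb); trip <- vector("list", nb)
  for (bi in seq_len(nb)) {
    bt <- best_triple(tab, br$species[bi], model$avail[[bi]], banks_idx, br$mu[bi])
    trip[[bi]] <- bt
    E[bi] <- bt$cost
    s <- br$species[bi]
    u[bi] <- if (bt$mode == "farm") tab$U_farm[[s]][bt$bank, bt$region]
             else tab$U_point[[s]][bt$bank, bt$region]
  }
  full <- E + u * (br$M - br$mu)
  rho <- full / br$M
  ord <- order(rho, br$breed)
  doses <- numeric(nb)
  remB <- if (is.na(TB)) Inf else TB
  for (bi in ord) {
    if (remB >= full[bi]) {
      doses[bi] <- br$M[bi]; remB <- remB - full[bi]
    } else if (remB >= E[bi]) {
      extra <- if (u[bi] > 0) (remB - E[bi]) / u[bi] else br$M[bi] - br$mu[bi]
      lvl <- min(br$M[bi], br$mu[bi] + extra)
      doses[bi] <- lvl; remB <- remB - (E[bi] + u[bi] * (lvl - br$mu[bi]))
    }
  }
  ub <- {  # LP bound: fill fully by ascending amortized cost, last fractional
    bspent <- 0; dtot <- 0
    for (bi in ord) {
      if (is.infinite(remB)) { dtot <- sum(br$M); break }
      if (bspent + full[bi] <= TB) { bspent <- bspent + full[bi]; dtot <- dtot + br$M[bi] }
      else { dtot <- dtot + br$M[bi] * max(0, (TB - bspent) / full[bi]); break }
    }
    dtot
  }
  rows <- lapply(which(doses > 0), function(bi) {
    bt <- trip[[bi]]
    data.frame(breed = br$breed[bi], species = br$species[bi],
               bank = tab$ids[bt$bank], region = tab$ids[bt$region],
               mode = bt$mode, doses = doses[bi], stringsAsFactors = FALSE)
  })
  alloc <- if (length(rows) > 0) do.call(rbind, rows) else empty_allocation()
  val <- sum(doses)
  gap <- max(0, (ub - val) / max(1, ub))
  status <- if (gap <= model$config$mip_gap) "optimal" else "feasible"
  finish_solution(model, alloc, status, val, gap, as.integer(sum(doses > 0)))
}

#' Exhaustive minimum-cost oracle for tiny instances
#'
#' Enumerates, per breed, every assignment of its full recollection demand to
#' a single (collecting bank, available source region, mode) triple, prices
#' every combination with the cost engine ([collection_cost()],
#' [travel_cost()], [maintenance_cost()]), rejects combinations violating
#' bank capacities when requested, and returns the global minimum. Under
#' linear per-dose costs optimal solutions concentrate each breed's demand on
#' one triple, and under campaign costing splitting only adds charges, so the
#' single-triple enumeration is exhaustive whenever capacities permit
#' unsplit assignments. Ties resolve to the lexicographically first
#' combination (bank, then region, then farm before point). Intended as an
#' independent verification oracle for [solve_model()]; refuses instances
#' beyond 4 banks, 5 breeds or 200,000 combinations.
#'
#' @param instance a [gb_instance()].
#' @param costing_mode `"campaign"` or `"per_dose"`.
#' @param capacity_on enforce tank capacities.
#' @param fixed_cost_rule see [price_allocation()].
#' @return a list with `objective`, `allocation` and `breakdown`.
#' @export
brute_force_min_cost <- function(instance,
                                 costing_mode = c("campaign", "per_dose"),
                                 capacity_on = FALSE,
                                 fixed_cost_rule = c("always", "active_only")) {
  costing_mode <- match.arg(costing_mode)
  fixed_cost_rule <- match.arg(fixed_cost_rule)
  ids <- instance$banks$id
  inv <- instance$inventory
  breeds <- sort(unique(inv$breed))
  if (length(ids) > 4L || length(breeds) > 5L)
    stop("oracle size bound exceeded: at most 4 banks and 5 breeds",
         call. = FALSE)

  cand <- list()   # per breed: data frame of (bank, region, mode, cost)
  dem <- numeric(length(breeds))
  spv <- character(length(breeds))
  for (i in seq_along(breeds)) {
    bb <- breeds[i]
    spv[i] <- inv$species[match(bb, inv$breed)]
    dem[i] <- sum(inv$A[inv$breed == bb])
    regions <- intersect(ids, unique(inv$bank[inv$breed == bb & inv$e == 1]))
    rows <- expand.grid(mode = c("farm", "point"), region = regions,
                        bank = ids, stringsAsFactors = FALSE)[, 3:1]
    rows$cost <- vapply(seq_len(nrow(rows)), function(k) {
      collection_cost(instance, spv[i], rows$bank[k], rows$mode[k], dem[i],
                      costing_mode) +
        travel_cost(instance, rows$bank[k], rows$region[k], rows$mode[k], dem[i]) +
        maintenance_cost(rows$bank[k], dem[i], instance$T, instance) -
        maintenance_cost(rows$bank[k], 0, instance$T, instance)  # mc part only
    }, 0)
    cand[[i]] <- rows
  }

  n_comb <- prod(vapply(cand, nrow, 1L))
  if (n_comb > 200000)
    stop("oracle size bound exceeded: more than 200,000 combinations",
         call. = FALSE)

  # combination grid ordered so that earlier breeds vary slowest: the first
  # strict minimum is then the lexicographically first optimal combination
  grid <- do.call(expand.grid, rev(lapply(cand, function(z) seq_len(nrow(z)))))
  grid <- grid[, rev(seq_along(cand)), drop = FALSE]

  total <- rep(instance$T * sum(instance$banks$F), nrow(grid))
  loads <- matrix(0, nrow(grid), length(ids))
  for (i in seq_along(breeds)) {
    total <- total + cand[[i]]$cost[grid[[i]]]
    bidx <- match(cand[[i]]$bank, ids)[grid[[i]]]
    loads[cbind(seq_len(nrow(grid)), bidx)] <-
      loads[cbind(seq_len(nrow(grid)), bidx)] + dem[i]
  }
  feas <- if (capacity_on)
    rowSums(sweep(loads, 2, instance$banks$cp, ">") & loads > 0) == 0
  else rep(TRUE, nrow(grid))
  if (!any(feas)) stop("oracle: no feasible combination", call. = FALSE)
  total[!feas] <- Inf
  kbest <- which.min(total)

  alloc <- do.call(rbind, lapply(seq_along(breeds), function(i) {
    row <- cand[[i]][grid[[i]][kbest], ]
    data.frame(breed = breeds[i], species = spv[i], bank = row$bank,
               region = row$region, mode = row$mode, doses = dem[i],
               stringsAsFactors = FALSE)
  }))
  breakdown <- price_allocation(instance, alloc, costing_mode, fixed_cost_rule)
  list(objective = breakdown$total, allocation = alloc, breakdown = breakdown)
}
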