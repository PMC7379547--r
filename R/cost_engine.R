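#' @title Cost engine
#' @description
#' Deterministic pricing of any fixed allocation, independent of the
#' optimizer. Total cost per bank decomposes as
#' `C = MC + VC`, `VC = CC + TC`, with
#' maintenance `MC = T * (F + mc * stored doses)`, collection-campaign costs
#' `CC` and travel costs `TC`. The engine is used both to price the baseline
#' scenario and to independently re-price optimizer solutions (the two must
#' agree to within numerical tolerance, which the test suite asserts).
#' @name cost_engine
NULL

#' Annual maintenance cost of a bank
#'
#' `T * (F + mc * stored_doses)`: the fixed cost `F` is charged even when the
#' bank stores nothing (the cost model has no closure/activation decision; see
#' the `fixed_cost_rule` option of [price_allocation()] for the alternative).
#'
#' @param bank a one-row bank data frame (fields `F`, `mc`) or a bank id
#'   together with `instance`.
#' @param stored_doses total doses stored at the bank.
#' @param T storage horizon in years.
#' @param instance optional [gb_instance()] used to resolve a bank id.
#' @return cost in EUR.
#' @export
maintenance_cost <- function(bank, stored_doses, T = 1, instance = NULL) {
  if (is.character(bank)) bank <- bank_row(instance, bank)
  if (stored_doses < 0) stop("stored_doses must be nonnegative", call. = FALSE)
  if (T < 0) stop("T must be nonnegative", call. = FALSE)
  T * (bank$F + bank$mc * stored_doses)
}

#' Collection (campaign) cost of a breed at a bank
#'
#' In the default `"campaign"` costing a collection charges the donor-animal
#' cost once per campaign: `r * cf` at farm zones or `r * cc` at a collection
#' centre, independent of the number of doses frozen (zero doses cost
#' nothing). The `"per_dose"` mode instead charges `r * cf * doses`
#' (resp. `cc`), i.e. the donor cost scales with every dose; it is retained
#' for fidelity because the two readings of the cost identity differ by
#' orders of magnitude and only the campaign reading is compatible with
#' realistic per-breed budgets (see the methods vignette).
#'
#' @param instance a [gb_instance()].
#' @param species species of the collected breed (selects `r` and the cost row).
#' @param bank collecting bank id.
#' @param mode `"farm"` or `"point"`.
#' @param doses doses collected (only its positivity matters in campaign mode).
#' @param costing_mode `"campaign"` (default) or `"per_dose"`.
#' @return cost in EUR.
#' @export
collection_cost <- function(instance, species, bank,
                            mode = c("farm", "point"), doses,
                            costing_mode = c("campaign", "per_dose")) {
  mode <- match.arg(mode)
  costing_mode <- match.arg(costing_mode)
  if (doses < 0) stop("doses must be nonnegative", call. = FALSE)
  if (doses == 0) return(0)
  r <- species_row(instance, species)$r
  i <- which(instance$costs$bank == bank & instance$costs$species == species)
  if (length(i) != 1L)
    stop("unknown (bank, species) pair: ", bank, "/", species, call. = FALSE)
  unit <- if (mode == "farm") instance$costs$cf[i] else instance$costs$cc[i]
  if (costing_mode == "campaign") r * unit else r * unit * doses
}

#' Travel cost of a collection journey set
#'
#' Trips are fractional (`doses / k`), matching a linear travel-cost model:
#' `(doses / k) * tc * (d_j + D[bank, region])` for farm collection in region
#' `j` and `(doses / k) * tc * D[bank, region]` for collection-centre pickup
#' (the centre sits at the region's bank, so within-region distance is zero).
#' `d_j` is the round-trip farm-zone distance of the *source* region.
#'
#' @inheritParams collection_cost
#' @param bank collecting bank id.
#' @param region source region (a bank id; regions coincide with banks).
#' @return cost in EUR.
#' @export
travel_cost <- function(instance, bank, region, mode = c("farm", "point"),
                        doses) {
  mode <- match.arg(mode)
  if (doses < 0) stop("doses must be nonnegative", call. = FALSE)
  b <- bank_row(instance, bank)
  j <- bank_row(instance, region)
  D <- instance$distances[bank, region]
  dist <- if (mode == "farm") j$d + D else D
  (doses / b$k) * b$tc * dist
}

#' An empty allocation
#'
#' @return zero-row allocation data frame with columns
#'   `breed, species, bank, region, mode, doses`.
#' @export
empty_allocation <- function() {
  data.frame(breed = character(0), species = character(0),
             bank = character(0), region = character(0),
             mode = character(0), doses = numeric(0),
             stringsAsFactors = FALSE)
}

#' Price a fixed allocation
#'
#' Assembles the full cost breakdown of an allocation: per bank the
#' maintenance (`MC`), collection (`CC`), travel (`TC`), variable
#' (`VC = CC + TC`) and total (`C = MC + VC`) costs, plus the network total.
#' Campaign charges are incurred once per distinct
#' `(breed, bank, region, mode)` with positive doses.
#'
#' @param instance a [gb_instance()].
#' @param allocation data frame with columns
#'   `breed, species, bank, region, mode, doses`; `bank` is the collecting
#'   (and storing) bank, `region` the source region, `mode` `"farm"` or
#'   `"point"`.
#' @param costing_mode `"campaign"` (default) or `"per_dose"`, see
#'   [collection_cost()].
#' @param fixed_cost_rule `"always"` charges every bank's fixed cost `F`
#'   (default); `"active_only"` charges `F` only for banks storing a positive
#'   number of doses.
#' @return object of class `gb_cost_breakdown`: a list with `per_bank` (data
#'   frame `bank, MC, CC, TC, VC, C`) and `total`.
#' @export
price_allocation <- function(instance, allocation,
                             costing_mode = c("campaign", "per_dose"),
                             fixed_cost_rule = c("always", "active_only")) {
  costing_mode <- match.arg(costing_mode)
  fixed_cost_rule <- match.arg(fixed_cost_rule)
  a <- allocation
  if (nrow(a) > 0) {
    if (any(a$doses < 0)) stop("allocation doses must be nonnegative", call. = FALSE)
    if (!all(a$bank %in% instance$banks$id) ||
        !all(a$region %in% instance$banks$id))
      stop("allocation references unknown bank/region", call. = FALSE)
    if (!all(a$mode %in% c("farm", "point")))
      stop("allocation mode must be 'farm' or 'point'", call. = FALSE)
    a <- a[a$doses > 0, , drop = FALSE]
  }
  ids <- instance$banks$id
  T <- instance$T
  MC <- CC <- TC <- stats::setNames(numeric(length(ids)), ids)

  stored <- if (nrow(a) > 0) tapply(a$doses, a$bank, sum) else NULL
  for (g in ids) {
    sd <- if (!is.null(stored) && g %in% names(stored)) stored[[g]] else 0
    Fg <- if (fixed_cost_rule == "always" || sd > 0) instance$banks$F[match(g, ids)] else 0
    MC[g] <- T * (Fg + instance$banks$mc[match(g, ids)] * sd)
  }

  if (nrow(a) > 0) {
    rr <- instance$species$r[match(a$species, instance$species$species)]
    ci <- match(paste(a$bank, a$species), paste(instance$costs$bank, instance$costs$species))
    if (anyNA(ci)) stop("allocation references unknown (bank, species) pair", call. = FALSE)
    unit <- ifelse(a$mode == "farm", instance$costs$cf[ci], instance$costs$cc[ci])
    if (costing_mode == "campaign") {
      # one charge per distinct (breed, bank, region, mode) with doses > 0
      key <- paste(a$breed, a$bank, a$region, a$mode)
      first <- !duplicated(key)
      cc_terms <- tapply((rr * unit)[first], a$bank[first], sum)
    } else {
      cc_terms <- tapply(rr * unit * a$doses, a$bank, sum)
    }
    CC[names(cc_terms)] <- as.numeric(cc_terms)

    bi <- match(a$bank, ids)
    Dv <- instance$distances[cbind(a$bank, a$region)]
    dj <- instance$banks$d[match(a$region, ids)]
    dist <- ifelse(a$mode == "farm", dj + Dv, Dv)
    tc_terms <- tapply((a$doses / instance$banks$k[bi]) *
                         instance$banks$tc[bi] * dist, a$bank, sum)
    TC[names(tc_terms)] <- as.numeric(tc_terms)
  }

  VC <- CC + TC
  C <- MC + VC
  structure(list(
    per_bank = data.frame(bank = ids, MC = as.numeric(MC), CC = as.numeric(CC),
                          TC = as.numeric(TC), VC = as.numeric(VC),
                          C = as.numeric(C), stringsAsFactors = FALSE),
    total = sum(C)), class = "gb_cost_breakdown")
}

#' @export
print.gb_cost_breakdown <- function(x, ...) {
  cat("<gb_cost_breakdown> total:", format(round(x$total, 2), big.mark = ","),
      "EUR\n")
  pb <- x$per_bank
  pb[, -1] <- round(pb[, -1], 2)
  print(pb, row.names = FALSE)
  invisible(x)
}
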