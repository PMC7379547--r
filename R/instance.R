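#' @title Gene-bank network instances
#'
#' @description
#' A `gb_instance` bundles everything the planning model needs to know about a
#' cryoconservation network: the gene banks with their economic and logistic
#' parameters, per-bank and per-species collection costs, the inter-bank
#' distance matrix, species-level collection limits, and the breed-level
#' inventory of currently stored semen doses. All monetary values are stored in
#' EUR (never thousands), distances in km, and stocks in doses.
#'
#' @details
#' The components are plain data frames (and a named distance matrix):
#'
#' * `banks`: one row per bank with `id`, `location`, `F` (fixed annual
#'   maintenance cost, EUR/year), `mc` (storage cost, EUR/dose/year), `cp`
#'   (cryotank capacity, doses), `current_doses`, `d` (round-trip distance to
#'   the farm zones of its own region, km), `tc` (travel cost, EUR/km) and `k`
#'   (doses collected per journey).
#' * `costs`: one row per (bank, species) with `cf` (collection cost at farm
#'   zones, EUR/animal) and `cc` (collection cost at a collection centre,
#'   EUR/animal).
#' * `distances`: symmetric matrix of inter-bank distances with zero diagonal,
#'   row/column names equal to the bank ids.
#' * `species`: one row per species with `M` (maximum doses collected per
#'   breed), `mu_factor` (the minimum collection is `mu_factor * M`) and `r`
#'   (donor animals required per collection campaign).
#' * `inventory`: one row per (breed, bank) with `A` (doses currently stored)
#'   and `e` (1 if the breed is available for collection in that bank's
#'   region). A breed stored in a bank is assumed collectable there, so
#'   `A > 0` implies `e = 1`.
#'
#' Because every bank is identified with its regional vicinity, bank ids double
#' as region ids throughout the package.
#'
#' @param banks,costs,distances,species,inventory see Details.
#' @param T storage horizon in years (default 1).
#' @param TB total budget in EUR; `NA` means unbounded.
#' @return An object of class `gb_instance`.
#' @export
gb_instance <- function(banks, costs, distances, species, inventory,
                        T = 1, TB = NA_real_) {
  distances <- as.matrix(distances)
  storage.mode(distances) <- "double"
  x <- structure(
    list(banks = as.data.frame(banks), costs = as.data.frame(costs),
         distances = distances, species = as.data.frame(species),
         inventory = as.data.frame(inventory),
         T = as.numeric(T), TB = as.numeric(TB)),
    class = "gb_instance")
  findings <- validate_instance(x)
  if (length(findings) > 0L)
    stop("invalid instance:\n  ", paste(findings, collapse = "\n  "),
         call. = FALSE)
  x
}

#' @export
print.gb_instance <- function(x, ...) {
  cat("<gb_instance> ", nrow(x$banks), " banks, ",
      nrow(x$species), " species, ",
      length(unique(x$inventory$breed)), " breeds (",
      nrow(x$inventory), " inventory records)\n", sep = "")
  cat("  stored doses: ", format(sum(x$inventory$A), big.mark = ","),
      " | horizon T = ", x$T, " year(s) | budget TB = ",
      if (is.na(x$TB)) "unbounded" else format(x$TB, big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Validate a gene-bank instance
#'
#' Checks every structural invariant of a [gb_instance()] and returns the
#' violations as a character vector of findings (empty when the instance is
#' valid). Each finding names the offending entity and the violated rule;
#' nothing is thrown, so the function can be used to audit hand-edited CSV
#' inputs.
#'
#' @param instance a `gb_instance` (or a bare list with the same components).
#' @return character vector of findings; `character(0)` if all invariants hold.
#' @export
validate_instance <- function(instance) {
  f <- character(0)
  add <- function(msg) f <<- c(f, msg)
  b <- instance$banks
  need <- c("id", "F", "mc", "cp", "current_doses", "d", "tc", "k")
  miss <- setdiff(need, names(b))
  if (length(miss) > 0L)
    return(paste0("banks: missing column(s) ", paste(miss, collapse = ", ")))
  if (anyDuplicated(b$id)) add("banks: duplicated bank id")
  for (col in c("F", "mc", "cp", "current_doses", "d", "tc")) {
    bad <- which(b[[col]] < 0)
    for (i in bad) add(sprintf("bank %s: %s must be nonnegative", b$id[i], col))
  }
  for (i in which(b$k <= 0))
    add(sprintf("bank %s: k (doses per trip) must be positive", b$id[i]))

  s <- instance$species
  for (i in seq_len(nrow(s))) {
    if (s$M[i] <= 0) add(sprintf("species %s: M must be positive", s$species[i]))
    if (s$mu_factor[i] <= 0 || s$mu_factor[i] > 1)
      add(sprintf("species %s: mu_factor must be in (0, 1]", s$species[i]))
    if (s$r[i] <= 0) add(sprintf("species %s: r must be positive", s$species[i]))
  }

  cc <- instance$costs
  key <- paste(cc$bank, cc$species)
  want <- as.vector(outer(b$id, s$species, paste))
  for (w in setdiff(want, key)) add(sprintf("costs: missing (bank, species) pair %s", w))
  for (i in which(cc$cf < 0)) add(sprintf("costs %s/%s: cf must be nonnegative", cc$bank[i], cc$species[i]))
  for (i in which(cc$cc < 0)) add(sprintf("costs %s/%s: cc must be nonnegative", cc$bank[i], cc$species[i]))

  D <- instance$distances
  if (!identical(rownames(D), colnames(D)) ||
      !setequal(rownames(D), b$id)) {
    add("distances: row/column names must both equal the bank ids")
  } else {
    D <- D[b$id, b$id, drop = FALSE]
    if (any(diag(D) != 0)) add("distances: diagonal must be zero")
    asym <- which(abs(D - t(D)) > 1e-9, arr.ind = TRUE)
    if (nrow(asym) > 0L) {
      i <- asym[1, 1]; j <- asym[1, 2]
      add(sprintf("distances: D[%s,%s]=%g but D[%s,%s]=%g (not symmetric)",
                  rownames(D)[i], colnames(D)[j], D[i, j],
                  rownames(D)[j], colnames(D)[i], D[j, i]))
    }
    if (any(D < 0)) add("distances: entries must be nonnegative")
  }

  inv <- instance$inventory
  if (nrow(inv) > 0L) {
    for (i in which(!inv$bank %in% b$id))
      add(sprintf("inventory row %d (breed %s): unknown bank %s", i, inv$breed[i], inv$bank[i]))
    for (i in which(!inv$species %in% s$species))
      add(sprintf("inventory row %d (breed %s): unknown species %s", i, inv$breed[i], inv$species[i]))
    for (i in which(inv$A < 0))
      add(sprintf("inventory row %d (breed %s): A must be nonnegative", i, inv$breed[i]))
    for (i in which(!inv$e %in% c(0, 1)))
      add(sprintf("inventory row %d (breed %s): e must be 0 or 1", i, inv$breed[i]))
    for (i in which(inv$A > 0 & inv$e == 0))
      add(sprintf("inventory row %d (breed %s at %s): stored doses imply availability (A > 0 requires e = 1)",
                  i, inv$breed[i], inv$bank[i]))
    ok <- tapply(inv$e, inv$breed, function(z) any(z == 1))
    for (nm in names(ok)[!ok])
      add(sprintf("breed %s: no record with e = 1 (not collectable anywhere)", nm))
    sp_per_breed <- tapply(inv$species, inv$breed, function(z) length(unique(z)))
    for (nm in names(sp_per_breed)[sp_per_breed > 1])
      add(sprintf("breed %s: inconsistent species across records", nm))
  }

  if (!is.numeric(instance$T) || is.na(instance$T) || instance$T <= 0)
    add("config: storage horizon T must be positive")
  if (!is.na(instance$TB) && instance$TB < 0)
    add("config: budget TB must be nonnegative (or NA for unbounded)")
  f
}

# internal lookups -----------------------------------------------------------

bank_row <- function(instance, id) {
  i <- match(id, instance$banks$id)
  if (is.na(i)) stop("unknown bank: ", id, call. = FALSE)
  instance$banks[i, , drop = FALSE]
}

species_row <- function(instance, sp) {
  i <- match(sp, instance$species$species)
  if (is.na(i)) stop("unknown species: ", sp, call. = FALSE)
  instance$species[i, , drop = FALSE]
}

#' Read a gene-bank instance from a directory of CSV files
#'
#' Expects `banks.csv`, `collection_costs.csv`, `distances.csv`, `species.csv`
#' and `inventory.csv` (comma-separated, UTF-8, header row, `.` decimal mark)
#' plus an optional `config.csv` with `key,value` rows for `T_years` and
#' `TB_eur` (an empty `TB_eur` means the budget is unbounded). Column layouts
#' are documented in [gb_instance()]; monetary columns are EUR.
#'
#' @param path directory containing the CSV files.
#' @return a validated [gb_instance()].
#' @seealso [write_instance()] for the inverse operation, [example_instance()]
#'   for the bundled 11-bank European network.
#' @export
load_instance <- function(path) {
  file_of <- function(name) {
    fp <- file.path(path, name)
    if (!file.exists(fp))
      stop("instance format error: missing file ", name, " in ", path, call. = FALSE)
    fp
  }
  rd <- function(name) utils::read.csv(file_of(name), stringsAsFactors = FALSE)

  need_cols <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0L)
      stop("instance format error: ", name, " lacks column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    df
  }

  braw <- need_cols(rd("banks.csv"),
                    c("id", "F_eur", "mc_eur_per_dose", "cp_doses",
                      "current_doses", "d_km", "tc_eur_per_km",
                      "k_doses_per_trip"), "banks.csv")
  banks <- data.frame(
    id = as.character(braw$id),
    location = if ("location" %in% names(braw)) as.character(braw$location) else "",
    F = as.numeric(braw$F_eur), mc = as.numeric(braw$mc_eur_per_dose),
    cp = as.numeric(braw$cp_doses), current_doses = as.numeric(braw$current_doses),
    d = as.numeric(braw$d_km), tc = as.numeric(braw$tc_eur_per_km),
    k = as.numeric(braw$k_doses_per_trip), stringsAsFactors = FALSE)

  craw <- need_cols(rd("collection_costs.csv"),
                    c("bank", "species", "cf_eur_per_animal", "cc_eur_per_animal"),
                    "collection_costs.csv")
  costs <- data.frame(bank = as.character(craw$bank),
                      species = as.character(craw$species),
                      cf = as.numeric(craw$cf_eur_per_animal),
                      cc = as.numeric(craw$cc_eur_per_animal),
                      stringsAsFactors = FALSE)

  draw <- utils::read.csv(file_of("distances.csv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(draw)[1] != "id")
    stop("instance format error: distances.csv must have an 'id' first column",
         call. = FALSE)
  distances <- as.matrix(draw[, -1, drop = FALSE])
  rownames(distances) <- as.character(draw$id)
  storage.mode(distances) <- "double"

  sraw <- need_cols(rd("species.csv"),
                    c("species", "M_doses", "mu_factor", "r_animals"), "species.csv")
  species <- data.frame(species = as.character(sraw$species),
                        M = as.numeric(sraw$M_doses),
                        mu_factor = as.numeric(sraw$mu_factor),
                        r = as.numeric(sraw$r_animals), stringsAsFactors = FALSE)

  iraw <- need_cols(rd("inventory.csv"),
                    c("breed", "species", "bank", "A_doses", "e_available"),
                    "inventory.csv")
  inventory <- data.frame(breed = as.character(iraw$breed),
                          species = as.character(iraw$species),
                          bank = as.character(iraw$bank),
                          A = as.numeric(iraw$A_doses),
                          e = as.integer(iraw$e_available),
                          stringsAsFactors = FALSE)

  T <- 1; TB <- NA_real_
  cfg_path <- file.path(path, "config.csv")
  if (file.exists(cfg_path)) {
    cfg <- utils::read.csv(cfg_path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character"))
    kv <- stats::setNames(cfg$value, cfg$key)
    if ("T_years" %in% names(kv) && nzchar(kv[["T_years"]]))
      T <- as.numeric(kv[["T_years"]])
    if ("TB_eur" %in% names(kv) && nzchar(kv[["TB_eur"]]))
      TB <- as.numeric(kv[["TB_eur"]])
  }

  gb_instance(banks, costs, distances, species, inventory, T = T, TB = TB)
}

#' Write a gene-bank instance to a directory of CSV files
#'
#' Inverse of [load_instance()]: writing then reloading reproduces the
#' instance field-for-field, including floating-point cost values (written
#' with full precision) and an unbounded budget (serialized as an empty
#' `TB_eur` value).
#'
#' @param instance a [gb_instance()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_instance <- function(instance, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  b <- instance$banks
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  utils::write.csv(data.frame(
    id = b$id, location = b$location, F_eur = num(b$F),
    mc_eur_per_dose = num(b$mc), cp_doses = num(b$cp),
    current_doses = num(b$current_doses), d_km = num(b$d),
    tc_eur_per_km = num(b$tc), k_doses_per_trip = num(b$k)),
    file.path(path, "banks.csv"), row.names = FALSE, quote = 2)
  cc <- instance$costs
  utils::write.csv(data.frame(
    bank = cc$bank, species = cc$species,
    cf_eur_per_animal = num(cc$cf), cc_eur_per_animal = num(cc$cc)),
    file.path(path, "collection_costs.csv"), row.names = FALSE, quote = FALSE)
  D <- instance$distances
  Dchr <- matrix(num(D), nrow(D), ncol(D), dimnames = dimnames(D))
  dd <- data.frame(id = rownames(D), Dchr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(dd, file.path(path, "distances.csv"),
                   row.names = FALSE, quote = FALSE)
  s <- instance$species
  utils::write.csv(data.frame(
    species = s$species, M_doses = num(s$M), mu_factor = num(s$mu_factor),
    r_animals = num(s$r)),
    file.path(path, "species.csv"), row.names = FALSE, quote = FALSE)
  inv <- instance$inventory
  utils::write.csv(data.frame(
    breed = inv$breed, species = inv$species, bank = inv$bank,
    A_doses = num(inv$A), e_available = inv$e),
    file.path(path, "inventory.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(
    key = c("T_years", "TB_eur"),
    value = c(num(instance$T), if (is.na(instance$TB)) "" else num(instance$TB))),
    file.path(path, "config.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled 11-bank European network
#'
#' Returns the packaged instance: eleven European gene banks with their
#' surveyed maintenance, storage, collection and travel cost parameters, tank
#' capacities, inter-bank distances, and the six-species collection limits.
#' The breed-level inventory accompanying it is synthetic: the real survey
#' matrix is not public, so the bundled `inventory.csv` was produced by
#' [generate_inventory()] (seed 1) and is statistically calibrated to the
#' network's per-bank dose totals and species dose shares. Pass a `seed` to
#' regenerate the inventory instead of using the bundled file.
#'
#' @param seed optional integer; when given, the inventory is regenerated with
#'   [default_generator_config()] at this seed rather than read from disk.
#' @return a validated [gb_instance()] with 11 banks and 6 species.
#' @export
example_instance <- function(seed = NULL) {
  path <- system.file("extdata", "eu_network", package = "cryoplan",
                      mustWork = TRUE)
  inst <- load_instance(path)
  if (!is.null(seed)) {
    cfg <- default_generator_config()
    cfg$seed <- as.integer(seed)
    inst$inventory <- generate_inventory(cfg)
    findings <- validate_instance(inst)
    if (length(findings) > 0L)
      stop("generated inventory failed validation: ", findings[1], call. = FALSE)
  }
  inst
}
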