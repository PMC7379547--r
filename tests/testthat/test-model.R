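test_that("model size counts match hand enumeration and are structural", {
  mini <- gb_instance(
    banks = data.frame(id = "G1", location = "", F = 100, mc = 0.5, cp = 1000,
                       current_doses = 10, d = 50, tc = 2.5, k = 400),
    costs = data.frame(bank = "G1", species = "cattle", cf = 100, cc = 50),
    distances = matrix(0, 1, 1, dimnames = list("G1", "G1")),
    species = data.frame(species = "cattle", M = 585, mu_factor = 0.8, r = 25),
    inventory = data.frame(breed = "X1", species = "cattle", bank = "G1",
                           A = 10, e = 1L))
  m <- build_model(mini, model_config(objective = "max_diversity",
                                      demand_rule = "free_semicontinuous"))
  n <- count_model_size(m)
  # by hand: SF 1 + SP 1 + SB 1 + y 1 + five cost variables
  expect_equal(unname(n["n_variables"]), 2 + 1 + 1 + 5)
  # SB definition 1 + indicator link 1 + semicontinuous pair 2 + cost rows 5
  expect_equal(unname(n["n_constraints"]), 1 + 1 + 2 + 5)

  mr <- build_model(mini, model_config())   # recollection adds a demand row
  expect_equal(unname(count_model_size(mr)["n_constraints"]), 10)
  mc <- build_model(mini, model_config(capacity_on = TRUE, budget_on = TRUE,
                                       TB = 1e6))
  expect_equal(unname(count_model_size(mc)["n_constraints"]), 10 + 1 + 1)

  # counts depend only on structure, never on cost values
  mini2 <- mini
  mini2$costs$cf <- 9 * mini2$costs$cf
  mini2$banks$F <- 0
  expect_equal(count_model_size(build_model(mini2, model_config())),
               count_model_size(mr))
})

test_that("the full network model has the expected variable and row families", {
  inst <- fixture_instance()
  m <- build_model(inst, model_config())
  n <- count_model_size(m)
  nb <- 489; ng <- 11
  expect_equal(unname(n["n_variables"]),
               2 * nb * ng * ng + nb * ng + nb + 5 * ng)
  expect_equal(unname(n["n_constraints"]),
               nb * ng + nb * ng + 2 * nb + nb + 5 * ng)
  # order of magnitude of the published formulation
  expect_true(n["n_variables"] > 1.1e5 && n["n_variables"] < 1.4e5)
})

test_that("forced-bank models keep storage at that bank only", {
  inst <- tiny_instance(101, n_banks = 3, n_breeds = 3)
  cfg <- model_config(forced_bank = "G2")
  sol <- solve_model(build_model(inst, cfg))
  expect_true(all(sol$allocation$bank == "G2"))
  expect_error(build_model(inst, model_config(forced_bank = "nope")),
               "does not exist")
})

test_that("an obviously dominant bank attracts all collection", {
  ids <- c("G1", "G2")
  banks <- data.frame(id = ids, location = "", F = c(100, 100),
                      mc = c(0.1, 0.1), cp = 1e6, current_doses = 0,
                      d = c(50, 50), tc = 2.5, k = 400)
  D <- matrix(c(0, 10, 10, 0), 2, dimnames = list(ids, ids))
  costs <- data.frame(bank = rep(ids, each = 1), species = "cattle",
                      cf = c(10, 1000), cc = c(10, 1000))
  species <- data.frame(species = "cattle", M = 585, mu_factor = 0.8, r = 25)
  inv <- data.frame(breed = c("X1", "X2"), species = "cattle",
                    bank = c("G1", "G2"), A = c(100, 100), e = 1L)
  inst <- gb_instance(banks, costs, D, species, inv)
  sol <- solve_model(build_model(inst, model_config()))
  expect_true(all(sol$allocation$bank == "G1"))
})

test_that("exact ties resolve to the lexicographically first bank", {
  ids <- c("G1", "G2")
  banks <- data.frame(id = ids, location = "", F = 100, mc = 0.2, cp = 1e6,
                      current_doses = 0, d = 50, tc = 2.5, k = 400)
  D <- matrix(0, 2, 2, dimnames = list(ids, ids))   # co-located banks
  costs <- data.frame(bank = ids, species = "cattle", cf = 80, cc = 40)
  species <- data.frame(species = "cattle", M = 585, mu_factor = 0.8, r = 25)
  inv <- data.frame(breed = c("X1", "X1"), species = "cattle",
                    bank = ids, A = c(50, 50), e = 1L)
  inst <- gb_instance(banks, costs, D, species, inv)
  sol <- solve_model(build_model(inst, model_config()))
  expect_equal(unique(sol$allocation$bank), "G1")
  bf <- brute_force_min_cost(inst)
  expect_equal(unique(bf$allocation$bank), "G1")
  expect_equal(sol$objective, bf$objective, tolerance = 1e-9)
})

test_that("solver matches the exhaustive oracle on seeded tiny instances", {
  for (seed in 1:20) {
    inst <- tiny_instance(seed)
    mode <- if (seed %% 2 == 0) "campaign" else "per_dose"
    bf <- brute_force_min_cost(inst, costing_mode = mode)
    sol <- solve_model(build_model(inst, model_config(costing_mode = mode)))
    expect_equal(sol$objective, bf$objective, tolerance = 1e-6,
                 label = paste("seed", seed, mode))
    expect_equal(sol$status, "optimal")
  }
})

test_that("capacitated solves never beat the oracle and agree when unsplit", {
  for (seed in 21:28) {
    inst <- tiny_instance(seed, cap_factor = 0.7)
    bf <- tryCatch(brute_force_min_cost(inst, capacity_on = TRUE),
                   error = function(e) NULL)   # oracle may find no unsplit combo
    sol <- solve_model(build_model(inst, model_config(capacity_on = TRUE)))
    if (sol$status == "infeasible") next
    loads <- tapply(sol$allocation$doses, sol$allocation$bank, sum)
    cp <- stats::setNames(inst$banks$cp, inst$banks$id)
    expect_true(all(loads <= cp[names(loads)] + 1e-6))
    if (!is.null(bf)) {
      # the solver may legally do better by splitting a breed across banks
      expect_lte(sol$objective, bf$objective * (1 + 1e-9))
      splits <- tapply(sol$allocation$bank, sol$allocation$breed,
                       function(z) length(unique(z)))
      if (all(splits == 1))
        expect_equal(sol$objective, bf$objective, tolerance = 1e-6)
    }
  }
})

test_that("relaxing capacity or freeing the bank never worsens the optimum", {
  for (seed in c(31, 32, 33)) {
    inst <- tiny_instance(seed, n_banks = 3, n_breeds = 4, cap_factor = 0.8)
    free <- solve_model(build_model(inst, model_config()))
    capped <- solve_model(build_model(inst, model_config(capacity_on = TRUE)))
    expect_gte(capped$objective + 1e-9, free$objective)
    for (k in inst$banks$id) {
      forced <- solve_model(build_model(inst, model_config(forced_bank = k)))
      expect_gte(forced$objective + 1e-9, free$objective)
    }
  }
})

test_that("recollection conserves every breed's demand exactly", {
  inst <- tiny_instance(55, n_banks = 3, n_breeds = 4)
  sol <- solve_model(build_model(inst, model_config()))
  dem <- tapply(inst$inventory$A, inst$inventory$breed, sum)
  got <- breed_totals(sol$allocation)
  expect_equal(got[names(dem)], dem, tolerance = 1e-9)
})

test_that("re-pricing a solution with the cost engine matches its objective", {
  inst <- tiny_instance(77, n_banks = 3, n_breeds = 4)
  for (cfg in list(model_config(),
                   model_config(costing_mode = "per_dose"),
                   model_config(capacity_on = TRUE))) {
    sol <- solve_model(build_model(inst, cfg))
    expect_equal(sol$breakdown$total, sol$objective,
                 tolerance = 1e-6)
  }
})

test_that("free semicontinuous solutions respect {0} union [mu, M]", {
  inst <- fixture_instance()
  cfg <- model_config(objective = "max_diversity",
                      demand_rule = "free_semicontinuous",
                      budget_on = TRUE, TB = 50000)
  sol <- solve_model(build_model(inst, cfg))
  tot <- breed_totals(sol$allocation)
  m <- build_model(inst, cfg)
  br <- m$breeds
  for (nm in names(tot)) {
    i <- match(nm, br$breed)
    expect_true(tot[nm] >= br$mu[i] - 1e-9 && tot[nm] <= br$M[i] + 1e-9)
  }
  # indicator consistency: y = 1 exactly for conserved breeds
  expect_equal(sum(sol$y), length(tot))
  expect_equal(sol$diversity, length(tot))
})

test_that("diversity is nondecreasing in the budget", {
  inst <- tiny_instance(91, n_banks = 3, n_breeds = 4)
  divs <- vapply(c(0, 2000, 5000, 20000, 1e6), function(B) {
    cfg <- model_config(objective = "max_diversity",
                        demand_rule = "free_semicontinuous",
                        budget_on = TRUE, TB = B)
    solve_model(build_model(inst, cfg))$diversity
  }, 0L)
  expect_false(is.unsorted(divs))
  # saturation: a huge budget conserves every collectable breed
  expect_equal(divs[5], length(unique(inst$inventory$breed)))
})

test_that("the literal dose-sum diversity measure is available and bounded", {
  inst <- tiny_instance(95, n_banks = 2, n_breeds = 3)
  cfg <- model_config(objective = "max_diversity",
                      demand_rule = "free_semicontinuous",
                      budget_on = TRUE, TB = 30000,
                      diversity_measure = "total_doses")
  sol <- solve_model(build_model(inst, cfg))
  m <- build_model(inst, cfg)
  expect_lte(sol$objective, sum(m$breeds$M) + 1e-9)
  tot <- breed_totals(sol$allocation)
  br <- m$breeds
  for (nm in names(tot)) {
    i <- match(nm, br$breed)
    expect_true(tot[nm] >= br$mu[i] - 1e-9 && tot[nm] <= br$M[i] + 1e-9)
  }
})

test_that("oracle refuses instances beyond its size bound", {
  expect_error(brute_force_min_cost(fixture_instance()), "at most 4 banks")
})

test_that("budget-infeasible recollection is reported infeasible", {
  inst <- tiny_instance(60, n_banks = 2, n_breeds = 2)
  sol <- solve_model(build_model(inst, model_config(budget_on = TRUE, TB = 1)))
  expect_equal(sol$status, "infeasible")
})
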