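# Expected values below are direct arithmetic on the bundled bank tables:
# maintenance T*(F + mc*doses), campaign r*cf (or r*cc), travel
# (doses/k)*tc*(d_j + D) with fractional trips.

test_that("maintenance cost is T * (F + mc * doses)", {
  inst <- fixture_instance()
  expect_equal(maintenance_cost("B1", 303888, 1, inst), 155466.56)
  expect_equal(maintenance_cost("B5", 2062, 1, inst), 46000.56)
  # a bank storing nothing still pays its fixed cost
  for (g in inst$banks$id)
    expect_equal(maintenance_cost(g, 0, 1, inst),
                 inst$banks$F[inst$banks$id == g])
  expect_equal(maintenance_cost("B1", 100, 3, inst), 3 * (119000 + 0.12 * 100))
  expect_error(maintenance_cost("B1", -1, 1, inst), "nonnegative")
})

test_that("campaign collection charges donors once; per-dose scales with doses", {
  inst <- fixture_instance()
  expect_equal(collection_cost(inst, "cattle", "B2", "farm", 400, "campaign"),
               25 * 50)
  expect_equal(collection_cost(inst, "poultry", "B5", "point", 123, "campaign"),
               25 * 1)
  # campaign charge is independent of the dose count
  expect_equal(collection_cost(inst, "cattle", "B2", "farm", 1, "campaign"),
               collection_cost(inst, "cattle", "B2", "farm", 9999, "campaign"))
  expect_equal(collection_cost(inst, "cattle", "B2", "farm", 400, "per_dose"),
               25 * 50 * 400)
  expect_equal(collection_cost(inst, "cattle", "B2", "farm", 0, "campaign"), 0)
  expect_equal(collection_cost(inst, "cattle", "B2", "farm", 0, "per_dose"), 0)
  expect_error(collection_cost(inst, "cattle", "B99", "farm", 1), "unknown")
})

test_that("travel cost uses fractional trips and the source region's distances", {
  inst <- fixture_instance()
  expect_equal(travel_cost(inst, "B2", "B11", "point", 400),
               (400 / 400) * 2.5 * 39.7)
  expect_equal(travel_cost(inst, "B1", "B1", "farm", 400), 1 * 2.5 * 200)
  # own-region collection point sits at distance zero
  for (g in inst$banks$id)
    expect_equal(travel_cost(inst, g, g, "point", 500), 0)
  # fractional trips: no rounding up
  expect_equal(travel_cost(inst, "B1", "B1", "farm", 100),
               (100 / 400) * 2.5 * 200)
  # farm mode adds the source region's own farm-zone distance
  expect_equal(travel_cost(inst, "B2", "B11", "farm", 400),
               1 * 2.5 * (200 + 39.7))
})

test_that("pricing an empty allocation yields the fixed-cost floor", {
  inst <- fixture_instance()
  bd <- price_allocation(inst, empty_allocation())
  expect_equal(bd$total, 1267000)
  expect_equal(bd$per_bank$VC, rep(0, 11))
  bd0 <- price_allocation(inst, empty_allocation(),
                          fixed_cost_rule = "active_only")
  expect_equal(bd0$total, 0)
})

test_that("a single-record allocation decomposes componentwise", {
  inst <- fixture_instance()
  alloc <- data.frame(breed = "X1", species = "cattle", bank = "B2",
                      region = "B2", mode = "farm", doses = 400)
  bd <- price_allocation(inst, alloc)
  pb <- bd$per_bank
  expect_equal(pb$MC[pb$bank == "B2"], 41000 + 0.56 * 400)
  expect_equal(pb$CC[pb$bank == "B2"], 1250)
  expect_equal(pb$TC[pb$bank == "B2"], (400 / 400) * 2.5 * 300)
  # identities hold exactly
  expect_equal(pb$VC, pb$CC + pb$TC)
  expect_equal(pb$C, pb$MC + pb$VC)
  expect_equal(bd$total, sum(pb$C))
})

test_that("collection costs are linear in the fee tables, travel is not affected", {
  inst <- fixture_instance()
  set.seed(3)
  alloc <- data.frame(
    breed = c("X1", "X2", "X3"), species = c("cattle", "sheep", "pig"),
    bank = c("B1", "B2", "B7"), region = c("B3", "B2", "B7"),
    mode = c("farm", "point", "farm"), doses = c(200, 300, 150))
  bd1 <- price_allocation(inst, alloc)
  inst2 <- inst
  inst2$costs$cf <- 2 * inst2$costs$cf
  inst2$costs$cc <- 2 * inst2$costs$cc
  bd2 <- price_allocation(inst2, alloc)
  expect_equal(bd2$per_bank$CC, 2 * bd1$per_bank$CC)
  expect_equal(bd2$per_bank$TC, bd1$per_bank$TC)
  expect_equal(bd2$per_bank$MC, bd1$per_bank$MC)
})

test_that("campaign charges accrue once per breed-bank-region-mode with doses", {
  inst <- fixture_instance()
  two_trips <- data.frame(breed = "X1", species = "cattle", bank = "B1",
                          region = "B1", mode = "farm", doses = c(100, 300))
  one_trip <- data.frame(breed = "X1", species = "cattle", bank = "B1",
                         region = "B1", mode = "farm", doses = 400)
  bd2 <- price_allocation(inst, two_trips)
  bd1 <- price_allocation(inst, one_trip)
  expect_equal(bd2$total, bd1$total)   # same campaign, same doses
  # but a second distinct campaign (other mode) is charged
  mixed <- data.frame(breed = "X1", species = "cattle", bank = "B1",
                      region = "B1", mode = c("farm", "point"),
                      doses = c(200, 200))
  bdm <- price_allocation(inst, mixed)
  expect_gt(bdm$per_bank$CC[bdm$per_bank$bank == "B1"],
            bd1$per_bank$CC[bd1$per_bank$bank == "B1"])
})

test_that("pricing is additive over disjoint allocations", {
  inst <- fixture_instance()
  a1 <- data.frame(breed = "X1", species = "cattle", bank = "B1",
                   region = "B2", mode = "farm", doses = 250)
  a2 <- data.frame(breed = "X2", species = "sheep", bank = "B6",
                   region = "B6", mode = "point", doses = 120)
  sep <- price_allocation(inst, a1)$total + price_allocation(inst, a2)$total -
    price_allocation(inst, empty_allocation())$total
  expect_equal(price_allocation(inst, rbind(a1, a2))$total, sep)
})
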