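test_that("the bundled network loads with the published structure", {
  inst <- fixture_instance()
  expect_s3_class(inst, "gb_instance")
  expect_equal(nrow(inst$banks), 11)
  expect_equal(nrow(inst$species), 6)
  expect_length(validate_instance(inst), 0)
  # tank capacity is twice the current holdings for every bank
  expect_equal(inst$banks$cp, 2 * inst$banks$current_doses)
  # distance matrix is symmetric with zero diagonal
  expect_equal(inst$distances, t(inst$distances))
  expect_true(all(diag(inst$distances) == 0))
  # monetary unit is EUR, not thousands
  expect_equal(inst$banks$F[inst$banks$id == "B1"], 119000)
  expect_equal(sum(inst$banks$F), 1267000)
})

test_that("write followed by load is the identity on all fields", {
  inst <- fixture_instance()
  td <- withr::local_tempdir()
  write_instance(inst, td)
  back <- load_instance(td)
  expect_equal(back$banks, inst$banks)
  expect_equal(back$costs, inst$costs)
  expect_equal(back$distances, inst$distances)
  expect_equal(back$species, inst$species)
  expect_equal(back$inventory, inst$inventory)
  expect_equal(back$T, inst$T)
  # unbounded budget survives the round trip as an empty sentinel
  expect_true(is.na(back$TB))

  inst$TB <- 118800
  write_instance(inst, td)
  expect_equal(load_instance(td)$TB, 118800)
})

test_that("a minimal one-bank one-breed directory loads", {
  td <- withr::local_tempdir()
  mini <- gb_instance(
    banks = data.frame(id = "G1", location = "", F = 100, mc = 0.5, cp = 1000,
                       current_doses = 10, d = 50, tc = 2.5, k = 400),
    costs = data.frame(bank = "G1", species = "cattle", cf = 100, cc = 50),
    distances = matrix(0, 1, 1, dimnames = list("G1", "G1")),
    species = data.frame(species = "cattle", M = 585, mu_factor = 0.8, r = 25),
    inventory = data.frame(breed = "X1", species = "cattle", bank = "G1",
                           A = 10, e = 1L))
  write_instance(mini, td)
  back <- load_instance(td)
  expect_equal(nrow(back$inventory), 1)
  expect_equal(back$inventory$e, 1L)
})

test_that("asymmetric distances are rejected with a symmetry finding", {
  inst <- fixture_instance()
  inst$distances["B2", "B11"] <- 40.0   # true value 39.7
  findings <- validate_instance(inst)
  expect_true(any(grepl("not symmetric", findings)))

  td <- withr::local_tempdir()
  write_instance(inst, td)
  expect_error(load_instance(td), "not symmetric")
})

test_that("validation names the entity and the violated rule", {
  inst <- fixture_instance()
  expect_length(validate_instance(inst), 0)

  bad <- inst
  bad$banks$cp[3] <- -5
  f <- validate_instance(bad)
  expect_length(f, 1)
  expect_match(f, "bank B3.*cp.*nonnegative")

  bad <- inst
  bad$inventory$e[1] <- 0L   # stored doses but flagged unavailable
  f <- validate_instance(bad)
  expect_true(any(grepl("A > 0 requires e = 1", f)))

  bad <- inst
  bad$T <- 0
  expect_true(any(grepl("T must be positive", validate_instance(bad))))
})

test_that("missing files and columns raise format errors naming the file", {
  td <- withr::local_tempdir()
  write_instance(fixture_instance(), td)
  file.remove(file.path(td, "species.csv"))
  expect_error(load_instance(td), "species.csv")

  td2 <- withr::local_tempdir()
  write_instance(fixture_instance(), td2)
  b <- utils::read.csv(file.path(td2, "banks.csv"))
  b$cp_doses <- NULL
  utils::write.csv(b, file.path(td2, "banks.csv"), row.names = FALSE)
  expect_error(load_instance(td2), "banks.csv.*cp_doses")
})
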