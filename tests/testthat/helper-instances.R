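# Small instance builders used across the tests. Everything is generated in
# code; `tiny_instance()` draws a random feasible network of 2-4 banks and a
# handful of breeds, the scale at which the exhaustive oracle is usable.

fixture_instance <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "eu_network", package = "cryoplan",
                          mustWork = TRUE)
      cache <<- load_instance(path)
    }
    cache
  }
})

tiny_instance <- function(seed, n_banks = NULL, n_breeds = NULL,
                          cap_factor = NULL) {
  set.seed(seed)
  if (is.null(n_banks)) n_banks <- sample(2:3, 1)
  if (is.null(n_breeds)) n_breeds <- sample(2:4, 1)
  ids <- paste0("G", seq_len(n_banks))
  D <- matrix(0, n_banks, n_banks, dimnames = list(ids, ids))
  for (i in seq_len(n_banks)) for (j in seq_len(n_banks)) {
    if (j > i) D[i, j] <- D[j, i] <- round(runif(1, 5, 400), 1)
  }
  banks <- data.frame(
    id = ids, location = "", F = round(runif(n_banks, 500, 5000)),
    mc = round(runif(n_banks, 0.05, 2), 2), cp = 1e7,
    current_doses = 0, d = round(runif(n_banks, 20, 300)),
    tc = 2.5, k = 400, stringsAsFactors = FALSE)
  sp_use <- sample(c("cattle", "sheep", "pig"), 2)
  species <- data.frame(species = sp_use,
                        M = c(585, 198)[seq_along(sp_use)],
                        mu_factor = 0.8, r = 25, stringsAsFactors = FALSE)
  costs <- expand.grid(bank = ids, species = sp_use,
                       stringsAsFactors = FALSE)
  costs$cf <- round(runif(nrow(costs), 10, 300))
  costs$cc <- round(runif(nrow(costs), 5, 200))
  rows <- list()
  for (b in seq_len(n_breeds)) {
    sp <- sample(sp_use, 1)
    home <- sample(ids, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      breed = sprintf("X%02d", b), species = sp, bank = home,
      A = round(runif(1, 20, 900)), e = 1L, stringsAsFactors = FALSE)
    # sometimes also available (but not stored) in a second region
    if (runif(1) < 0.4 && n_banks > 1) {
      other <- sample(setdiff(ids, home), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        breed = sprintf("X%02d", b), species = sp, bank = other,
        A = 0, e = 1L, stringsAsFactors = FALSE)
    }
  }
  inv <- do.call(rbind, rows)
  if (!is.null(cap_factor)) {
    tot <- sum(inv$A)
    banks$cp <- round(runif(n_banks, 0.6, 1.2) * tot * cap_factor)
    # ensure overall feasibility
    if (sum(banks$cp) < tot * 1.1) banks$cp <- banks$cp + ceiling(tot / n_banks)
  }
  gb_instance(banks, costs, D, species, inv)
}

breed_totals <- function(alloc) {
  if (nrow(alloc) == 0) return(numeric(0))
  tapply(alloc$doses, alloc$breed, sum)
}
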