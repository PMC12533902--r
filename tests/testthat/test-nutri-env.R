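toy_db <- function() {
  structure(list(
    food_item("meal1", c(sodium_mg = 400, satfat_g = 2.5, fiber_g = 6,
                         calories_kcal = 400, cholesterol_mg = 50), 4),
    food_item("salad", c(sodium_mg = 150, satfat_g = 1, fiber_g = 12,
                         calories_kcal = 250, cholesterol_mg = 5), 3,
              tags = c("vegetarian", "vegan")),
    food_item("burger", c(sodium_mg = 1000, satfat_g = 9, fiber_g = 1,
                          calories_kcal = 750, cholesterol_mg = 170), 6,
              tags = "fried"),
    food_item("salty", c(sodium_mg = 2700, satfat_g = 1, fiber_g = 0,
                         calories_kcal = 150, cholesterol_mg = 10), 2),
    food_item("free", c(sodium_mg = 0, satfat_g = 0, fiber_g = 0.5,
                        calories_kcal = 30, cholesterol_mg = 0), 0)),
    class = "food_db")
}

test_that("reset yields the zero state and rejects bad horizons", {
  prof <- gen_patient_profile("healthy", seed = 1)
  st <- nutri_reset(prof, toy_db(), 5)
  expect_equal(unname(st$cumulative), rep(0, 5))
  expect_equal(st$t, 0L)
  expect_length(st$history, 0L)
  expect_error(nutri_reset(prof, toy_db(), 0),
               class = "cardiopipe_invalid_argument")
  expect_identical(nutri_reset(prof, toy_db(), 5, seed = 3),
                   nutri_reset(prof, toy_db(), 5, seed = 3))
})

test_that("the feasibility mask enforces bounds, exclusions and tags", {
  prof <- gen_patient_profile("healthy", seed = 1)
  db <- toy_db()
  st <- nutri_reset(prof, db, 5)
  # hand enumeration at c = 0: salty (2700mg) exceeds the 2800mg sodium cap?
  # no: 2700 <= 2800, so all five are feasible for the healthy profile
  expect_equal(feasible_actions(st), 1:5)
  # push sodium to the cap: only items with sodium <= 100 stay feasible
  st$cumulative["sodium_mg"] <- prof$upper[["sodium_mg"]] - 100
  expect_equal(feasible_actions(st), c(5L))
  # exclusion removes an item regardless of nutrients
  prof2 <- prof; prof2$exclusions <- "free"
  st2 <- nutri_reset(prof2, db, 5)
  expect_false(5L %in% feasible_actions(st2))
  # forbidden tag removes the fried item for dyslipidemia
  dys <- gen_patient_profile("dyslipidemia", seed = 1)
  st3 <- nutri_reset(dys, db, 5)
  expect_false(3L %in% feasible_actions(st3))
})

test_that("adherence and risk terms match their closed forms and a loop oracle", {
  expect_equal(adherence_term(c(5, 5), c(5, 5), c(1, 1)), 0)
  expect_equal(adherence_term(7, 3, 2), -4)      # |c-g| = T + 2 -> -(2^2)
  expect_equal(risk_term(c(1, 2), c(5, 5), c(2, 2)), 0)
  expect_equal(risk_term(8, 5, 2), -18)          # exceed by 3, w = 2
  set.seed(20)
  for (i in 1:10) {
    d <- sample(2:6, 1)
    c_ <- runif(d, 0, 10); g <- runif(d, 0, 10); tol <- runif(d, 0, 2)
    gm <- runif(d, 0, 10); w <- runif(d, 0, 3)
    adh_loop <- 0; rsk_loop <- 0
    for (j in seq_len(d)) {
      adh_loop <- adh_loop - max(0, abs(c_[j] - g[j]) - tol[j])^2 / d
      rsk_loop <- rsk_loop - w[j] * max(0, c_[j] - gm[j])^2
    }
    expect_equal(adherence_term(c_, g, tol), adh_loop, tolerance = 1e-12)
    expect_equal(risk_term(c_, gm, w), rsk_loop, tolerance = 1e-12)
  }
})

test_that("soft terms: preference, repetition, cost", {
  prof <- gen_patient_profile("dyslipidemia", seed = 1)
  db <- toy_db()
  st <- nutri_reset(prof, db, 5)
  w <- reward_weights(rho = 0.5, lambda_viol = 1, kappa_cost = 0.05)
  s1 <- soft_terms(db[[1]], st, w)
  expect_equal(s1$preference, 1)
  expect_equal(s1$diversity, 0)
  expect_equal(s1$cost, -0.05 * 4)
  expect_equal(soft_terms(db[[3]], st, w)$preference, -1)   # fried forbidden
  st$history <- c("meal1", "meal1")
  expect_equal(soft_terms(db[[1]], st, w)$diversity, -2 * 0.5)
  expect_equal(soft_terms(db[[5]], st, w)$cost, 0)
})

test_that("step assembles the reward exactly from its components", {
  prof <- gen_patient_profile("healthy", seed = 1)
  st <- nutri_reset(prof, toy_db(), 5)
  zero <- reward_weights(0, 0, 0, 0, 0, lambda_viol = 1, rho = 1, kappa_cost = 1)
  out0 <- nutri_step(st, 1, zero)
  expect_equal(out0$reward, 0)
  w <- reward_weights()
  set.seed(21)
  state <- st
  while (!state$done) {
    feas <- feasible_actions(state)
    a <- feas[sample.int(length(feas), 1)]
    out <- nutri_step(state, a, w)
    recombined <- w$alpha * out$components$adherence +
      w$beta * out$components$risk + w$gamma_pref * out$components$preference +
      w$delta_div * out$components$diversity + w$eta_cost * out$components$cost
    expect_equal(out$reward, recombined, tolerance = 1e-12)
    state <- out$next_state
  }
  expect_equal(state$t, 5L)
})

test_that("cumulative intake is conserved, monotone and capped by the mask", {
  prof <- gen_patient_profile("healthy", seed = 1)
  db <- toy_db()
  set.seed(22)
  for (ep in 1:50) {
    state <- nutri_reset(prof, db, 5)
    chosen <- c()
    while (!state$done) {
      feas <- feasible_actions(state)
      if (!length(feas)) break
      a <- feas[sample.int(length(feas), 1)]
      prev <- state$cumulative
      out <- nutri_step(state, a)
      expect_true(all(out$next_state$cumulative >= prev))
      expect_true(all(out$next_state$cumulative <= prof$upper + 1e-9))
      chosen <- c(chosen, a)
      state <- out$next_state
    }
    manual <- Reduce(`+`, lapply(db[chosen], function(it) it$nutrients))
    expect_equal(state$cumulative, manual, tolerance = 1e-12)
  }
})

test_that("an infeasible action is a contract violation; empty mask terminates", {
  prof <- gen_patient_profile("healthy", seed = 1)
  db <- toy_db()
  st <- nutri_reset(prof, db, 5)
  st$cumulative["sodium_mg"] <- prof$upper[["sodium_mg"]] - 100
  expect_error(nutri_step(st, 4), class = "cardiopipe_contract_violation")
  # a db whose single item nearly fills the sodium budget forces termination
  big <- structure(list(
    food_item("dense", c(sodium_mg = 1500, satfat_g = 1, fiber_g = 1,
                         calories_kcal = 300, cholesterol_mg = 10), 1)),
    class = "food_db")
  state <- nutri_reset(prof, big, 5)
  out <- nutri_step(state, 1)
  expect_true(out$done)
  expect_true(out$next_state$infeasible)
})

test_that("literal (non-prorated) adherence compares against full-day targets", {
  prof <- gen_patient_profile("healthy", seed = 1)
  db <- toy_db()
  st <- nutri_reset(prof, db, 5, prorate_adherence = FALSE)
  out <- nutri_step(st, 5)   # tiny item, far below full-day targets
  g <- prof$targets
  cn <- db[[5]]$nutrients / g
  expect_equal(out$components$adherence,
               adherence_term(cn, rep(1, 5), prof$tol / g),
               tolerance = 1e-12)
  expect_lt(out$components$adherence, -0.1)
})
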