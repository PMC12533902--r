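test_that("GAE limits: reward-to-go at lambda 1, single TD error at lambda 0", {
  r <- c(1, 2, 3)
  v0 <- rep(0, 4)
  g1 <- gae(r, v0, gamma = 0.9, lam = 1)
  expect_equal(g1$advantages,
               c(1 + 0.9 * 2 + 0.81 * 3, 2 + 0.9 * 3, 3))
  set.seed(40)
  v <- rnorm(4)
  g0 <- gae(r, v, gamma = 0.9, lam = 0)
  expect_equal(g0$advantages, r + 0.9 * v[2:4] - v[1:3])
  expect_equal(g0$returns, g0$advantages + v[1:3])
  expect_error(gae(r, v[1:3]), class = "cardiopipe_invalid_argument")
})

test_that("GAE equals the double-loop summation on random sequences", {
  set.seed(41)
  for (rep in 1:10) {
    Tn <- sample(2:50, 1)
    r <- rnorm(Tn); v <- rnorm(Tn + 1)
    gamma <- runif(1, 0.8, 1); lam <- runif(1)
    expect_equal(gae(r, v, gamma, lam)$advantages,
                 oracle_gae(r, v, gamma, lam), tolerance = 1e-12)
  }
})

make_batch <- function(policy, n = 16, seed = 42) {
  set.seed(seed)
  S <- matrix(rnorm(n * policy$state_dim), n)
  mask <- matrix(TRUE, n, policy$n_actions)
  mask[1, 2] <- FALSE                      # one infeasible entry
  fw <- policy_forward(policy, S, mask)
  acts <- apply(exp(fw$logp), 1, function(p) sample.int(length(p), 1, prob = p))
  list(S = S, mask = mask, actions = acts,
       old_logp = fw$logp[cbind(seq_len(n), acts)],
       advantages = rnorm(n), returns = rnorm(n), values = fw$value)
}

test_that("at ratio one the surrogate equals the mean advantage, clip inactive", {
  pol <- ppo_policy_new(5, 4, c(8, 8), seed = 1)
  b <- make_batch(pol)
  res <- ppo_loss(b, pol, ppo_config())
  expect_equal(res$surrogate, mean(b$advantages), tolerance = 1e-10)
  expect_equal(res$clip_fraction, 0)
  res0 <- ppo_loss(b, pol, ppo_config(clip_eps = 0))
  expect_equal(res0$surrogate, mean(b$advantages), tolerance = 1e-10)
  bz <- b; bz$advantages <- rep(0, length(b$advantages))
  resz <- ppo_loss(bz, pol, ppo_config())
  expect_equal(resz$surrogate, 0)
  expect_equal(resz$objective,
               ppo_config()$c_entropy * resz$entropy -
                 ppo_config()$c_value * resz$value_error)
})

test_that("the clipped surrogate never exceeds its sanity envelope", {
  pol <- ppo_policy_new(5, 4, c(8, 8), seed = 2)
  pol2 <- ppo_policy_new(5, 4, c(8, 8), seed = 3)   # a different policy
  b <- make_batch(pol)
  cfg <- ppo_config(clip_eps = 0.2)
  fw <- policy_forward(pol2, b$S, b$mask)
  ratio <- exp(fw$logp[cbind(seq_along(b$actions), b$actions)] - b$old_logp)
  A <- b$advantages
  clipped <- pmin(ratio * A, pmin(pmax(ratio, 0.8), 1.2) * A)
  expect_true(all(clipped <= ratio * A + abs(A) * cfg$clip_eps + 1e-12))
})

test_that("policy gradients agree with finite differences", {
  pol <- ppo_policy_new(4, 3, c(6), seed = 5)
  b <- make_batch(pol, n = 8, seed = 6)
  # perturb the policy so ratios differ from 1 and clipping engages
  pol2 <- pol
  set.seed(7)
  pol2$pi$params$W <- pol2$pi$params$W + matrix(rnorm(length(pol2$pi$params$W), 0, 0.3),
                                               nrow(pol2$pi$params$W))
  cfg <- ppo_config(clip_eps = 0.1)
  grads <- ppo_grads(b, pol2, cfg)
  obj_at <- function(p) ppo_loss(b, p, cfg)$objective
  eps <- 1e-6
  paths <- list(list(c("pi"), "W"), list(c("v"), "W"),
                list(c("trunk", 1L), "W"), list(c("trunk", 1L), "b"))
  gpaths <- list(grads$pi$W, grads$v$W, grads$trunk[[1]]$W, grads$trunk[[1]]$b)
  for (pi_ in seq_along(paths)) {
    path <- paths[[pi_]]
    pv <- if (length(path[[1]]) == 1) pol2[[path[[1]]]]$params[[path[[2]]]]
          else pol2$trunk[[path[[1]][2]]]$params[[path[[2]]]]
    for (i in sample(length(pv), min(4, length(pv)))) {
      bump <- function(h) {
        p <- pol2
        if (length(path[[1]]) == 1) p[[path[[1]]]]$params[[path[[2]]]][i] <- pv[i] + h
        else p$trunk[[path[[1]][2]]]$params[[path[[2]]]][i] <- pv[i] + h
        p
      }
      num <- (obj_at(bump(eps)) - obj_at(bump(-eps))) / (2 * eps)
      # ppo_grads returns descent gradients of the negated objective
      expect_equal(-gpaths[[pi_]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("zero learning rate leaves the policy untouched", {
  db <- gen_food_db(8, seed = 3)
  prof <- gen_patient_profile("healthy", seed = 3)
  res <- train_ppo(prof, db, 3, ppo_config(updates = 2, rollout = 32, lr = 0,
                                           seed = 4))
  fresh <- ppo_policy_new(res$policy$state_dim, res$policy$n_actions,
                          ppo_config()$hidden, 4)
  expect_identical(res$policy$pi$params, fresh$pi$params)
  expect_identical(res$policy$trunk[[1]]$params, fresh$trunk[[1]]$params)
})

test_that("training on a dominant-arm toy environment finds the dominant arm", {
  # two items with identical nutrition; one carries the required tag and is
  # cheap, the other misses it (soft lambda_viol penalty, still feasible)
  # and costs more, so the first strictly dominates every step
  nt <- c(sodium_mg = 300, satfat_g = 2, fiber_g = 6,
          calories_kcal = 380, cholesterol_mg = 40)
  db <- structure(list(food_item("good", nt, 1, tags = "vegetarian"),
                       food_item("bad", nt, 8)),
                  class = "food_db")
  prof <- gen_patient_profile("healthy", seed = 5)
  prof$prefs$required <- "vegetarian"
  res <- train_ppo(prof, db, 3,
                   ppo_config(updates = 30, rollout = 96, seed = 6))
  expect_equal(res$n_bound_violations, 0L)
  st <- nutri_reset(prof, db, 3)
  fw <- policy_forward(res$policy, matrix(nutri_state_features(st), 1),
                       matrix(feasibility_mask(st), 1))
  expect_gt(exp(fw$logp[1, 1]), 0.9)
  # and it beats the uniform-random baseline
  rollout_reward <- function(pick) {
    state <- nutri_reset(prof, db, 3); tot <- 0
    while (!state$done) {
      feas <- feasible_actions(state)
      a <- pick(state, feas)
      out <- nutri_step(state, a)
      tot <- tot + out$reward; state <- out$next_state
    }
    tot
  }
  set.seed(7)
  rnd <- mean(replicate(50, rollout_reward(function(s, f) sample(f, 1))))
  pol <- mean(replicate(5, rollout_reward(function(s, f) {
    fw <- policy_forward(res$policy, matrix(nutri_state_features(s), 1),
                         matrix(feasibility_mask(s), 1))
    f[which.max(fw$logp[1, f])]
  })))
  expect_gt(pol, rnd)
})

test_that("greedy recommendation respects the mask and conserves totals", {
  db <- gen_food_db(12, seed = 8)
  prof <- gen_patient_profile("hypertension", seed = 8)
  prof$exclusions <- db[[2]]$id
  res <- train_ppo(prof, db, 4, ppo_config(updates = 3, rollout = 48, seed = 9))
  plan <- recommend(res$policy, prof, db, 4)
  expect_lte(length(plan$items), 4L)
  expect_false(prof$exclusions %in% plan$items)
  manual <- Reduce(`+`, lapply(plan$items, function(id)
    db[[which(vapply(db, function(x) x$id, "") == id)]]$nutrients))
  expect_equal(plan$totals, manual, tolerance = 1e-12)
  expect_true(all(plan$totals <= prof$upper + 1e-9))
})

test_that("an environment with no feasible first action fails loudly", {
  prof <- gen_patient_profile("healthy", seed = 1)
  prof$exclusions <- "only"
  db <- structure(list(food_item("only", c(sodium_mg = 1, satfat_g = 0,
                                           fiber_g = 0, calories_kcal = 1,
                                           cholesterol_mg = 0), 1)),
                  class = "food_db")
  expect_error(train_ppo(prof, db, 3, ppo_config(updates = 1, rollout = 8)),
               class = "cardiopipe_infeasible_env")
})

test_that("trend summary detects monotone versus flat curves", {
  expect_equal(trend_fraction(1:100, 10), 1)
  expect_equal(trend_fraction(100:1, 10), 0)
  expect_true(is.na(trend_fraction(1:5, 10)))
})
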