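# Proximal policy optimization on the nutrition environment: clipped
# surrogate objective with entropy and value regularization, generalized
# advantage estimation, and feasibility masking realized as -Inf logits so
# infeasible actions have exactly zero sampling probability.

#' PPO configuration
#'
#' Standard PPO hyperparameters; every value is exposed because none is
#' dictated by the method itself.
#'
#' @param clip_eps clipping radius of the probability ratio, in (0, 1).
#' @param c_entropy entropy bonus coefficient.
#' @param c_value value-error coefficient.
#' @param gamma discount factor in (0, 1].
#' @param lambda GAE decay in [0, 1].
#' @param lr Adam step size.
#' @param epochs_per_update passes over each rollout.
#' @param minibatch minibatch size.
#' @param rollout environment steps collected per update.
#' @param updates number of policy updates.
#' @param hidden trunk layer widths.
#' @param normalize_adv standardize advantages per update (default TRUE).
#' @param seed RNG seed.
#' @return An object of class `ppo_config`.
#' @export
ppo_config <- function(clip_eps = 0.2, c_entropy = 0.01, c_value = 0.5,
                       gamma = 0.99, lambda = 0.95, lr = 3e-4,
                       epochs_per_update = 4L, minibatch = 64L,
                       rollout = 256L, updates = 200L,
                       hidden = c(64L, 64L), normalize_adv = TRUE, seed = 1L) {
  if (clip_eps < 0 || clip_eps >= 1) stop_invalid("clip_eps must be in [0, 1)")
  if (gamma <= 0 || gamma > 1) stop_invalid("gamma must be in (0, 1]")
  if (lambda < 0 || lambda > 1) stop_invalid("lambda must be in [0, 1]")
  structure(list(clip_eps = clip_eps, c_entropy = c_entropy, c_value = c_value,
                 gamma = gamma, lambda = lambda, lr = lr,
                 epochs_per_update = check_count(epochs_per_update, "epochs_per_update"),
                 minibatch = check_count(minibatch, "minibatch"),
                 rollout = check_count(rollout, "rollout"),
                 updates = check_count(updates, "updates", 0L),
                 hidden = hidden, normalize_adv = isTRUE(normalize_adv),
                 seed = seed),
            class = "ppo_config")
}

#' Generalized advantage estimation
#'
#' `A_t = sum_l (gamma*lambda)^l delta_{t+l}` with TD errors
#' `delta_t = r_t + gamma V(s_{t+1}) - V(s_t)`, computed by the standard
#' backward recursion; returns also `R_t = A_t + V(s_t)`.
#'
#' @param rewards reward sequence (length `T`).
#' @param values value estimates with bootstrap (length `T + 1`; the last
#'   entry is `V(s_T)`, 0 for a terminal state).
#' @param gamma discount factor.
#' @param lam GAE decay.
#' @return List with `advantages` and `returns`, each length `T`.
#' @export
gae <- function(rewards, values, gamma = 0.99, lam = 0.95) {
  Tn <- length(rewards)
  if (length(values) != Tn + 1L)
    stop_invalid("values must have one more entry than rewards (bootstrap)")
  adv <- numeric(Tn)
  acc <- 0
  for (t in rev(seq_len(Tn))) {
    delta <- rewards[t] + gamma * values[t + 1L] - values[t]
    acc <- delta + gamma * lam * acc
    adv[t] <- acc
  }
  list(advantages = adv, returns = adv + values[seq_len(Tn)])
}

# ---- actor-critic network -------------------------------------------------

# Shared tanh trunk with separate linear policy and value heads.
ppo_policy_new <- function(state_dim, n_actions, hidden, seed) {
  with_seed(seed, {
    trunk <- list()
    din <- state_dim
    for (h in hidden) {
      trunk <- c(trunk, list(nn_dense(din, h, init = "glorot"), nn_tanh()))
      din <- h
    }
    structure(list(trunk = trunk,
                   pi = nn_dense(din, n_actions, init = "glorot"),
                   v = nn_dense(din, 1L, init = "glorot"),
                   state_dim = state_dim, n_actions = n_actions),
              class = "ppo_policy")
  })
}

#' @export
print.ppo_policy <- function(x, ...) {
  np <- sum(vapply(c(x$trunk, list(x$pi, x$v)), layer_n_params, numeric(1)))
  cat(sprintf("<ppo_policy> %d-dim state, %d actions, %d parameters\n",
              x$state_dim, x$n_actions, np))
  invisible(x)
}

# Forward: masked log-probabilities and values. mask: logical matrix
# (N, n_actions); infeasible entries get -Inf logits.
policy_forward <- function(policy, S, mask, with_cache = FALSE) {
  rt <- chain_forward(policy$trunk, S, training = FALSE)
  rp <- layer_forward(policy$pi, rt$out)
  rv <- layer_forward(policy$v, rt$out)
  logits <- rp$out
  logits[!mask] <- -Inf
  zmax <- apply(logits, 1, max)
  ez <- exp(logits - zmax)
  sez <- rowSums(ez)
  logp <- logits - zmax - log(sez)
  res <- list(logp = logp, value = as.numeric(rv$out))
  if (with_cache)
    res$cache <- list(trunk = rt$caches, pi = rp$cache, v = rv$cache,
                      prob = ez / sez, mask = mask)
  res
}

# Backward through the shared trunk given logit and value gradients.
policy_backward <- function(policy, cache, glogits, gvalue) {
  bp <- layer_backward(policy$pi, cache$pi, glogits)
  bv <- layer_backward(policy$v, cache$v, matrix(gvalue, ncol = 1L))
  bt <- chain_backward(policy$trunk, cache$trunk, bp$gin + bv$gin)
  list(trunk = bt$grads, pi = bp$grads, v = bv$grads)
}

policy_update <- function(policy, grads, lr, t) {
  policy$trunk <- chain_update(policy$trunk, grads$trunk, lr, t)
  policy$pi <- adam_layer(policy$pi, grads$pi, lr, t)
  policy$v <- adam_layer(policy$v, grads$v, lr, t)
  policy
}

# State featurization: profile scalars (age/100, BMI/40, risk), fractional
# intake c_t/u per nutrient, episode progress t/horizon, and a per-item
# binary indicator of whether the item already occurs in the history.
nutri_state_features <- function(state) {
  prof <- state$profile
  picked <- as.numeric(vapply(state$food_db,
                              function(it) it$id %in% state$history, logical(1)))
  c(prof$age / 100, prof$bmi / 40, prof$risk,
    as.numeric(state$cumulative / prof$upper),
    state$t / state$horizon, picked)
}

feasibility_mask <- function(state) {
  m <- rep(FALSE, length(state$food_db))
  m[feasible_actions(state)] <- TRUE
  m
}

#' PPO objective on a minibatch
#'
#' Evaluates the clipped surrogate
#' `mean(min(r A, clip(r, 1-eps, 1+eps) A))` with probability ratios
#' against the stored behavior log-probabilities, plus the entropy bonus
#' (over feasible actions only) and the value mean-squared-error term.
#'
#' @param batch list with matrix `S`, logical matrix `mask`, integer
#'   `actions` (1-based), `old_logp`, `advantages`, `returns`.
#' @param policy a `ppo_policy`.
#' @param config a [ppo_config()].
#' @return List: `objective` (to maximize), `surrogate`, `entropy`,
#'   `value_error`, `clip_fraction`.
#' @export
ppo_loss <- function(batch, policy, config = ppo_config()) {
  fw <- policy_forward(policy, batch$S, batch$mask)
  n <- nrow(batch$S)
  idx <- cbind(seq_len(n), batch$actions)
  ratio <- exp(fw$logp[idx] - batch$old_logp)
  A <- batch$advantages
  unclipped <- ratio * A
  clipped <- pmin(pmax(ratio, 1 - config$clip_eps), 1 + config$clip_eps) * A
  surrogate <- mean(pmin(unclipped, clipped))
  p <- exp(fw$logp)
  ent_terms <- ifelse(is.finite(fw$logp) & p > 0, -p * fw$logp, 0)
  entropy <- mean(rowSums(ent_terms))
  verr <- mean((fw$value - batch$returns)^2)
  list(objective = surrogate + config$c_entropy * entropy - config$c_value * verr,
       surrogate = surrogate, entropy = entropy, value_error = verr,
       clip_fraction = mean(clipped < unclipped))
}

# Objective gradient for one minibatch (ascent direction returned as
# descent gradients on the negated objective).
ppo_grads <- function(batch, policy, config) {
  fw <- policy_forward(policy, batch$S, batch$mask, with_cache = TRUE)
  n <- nrow(batch$S)
  idx <- cbind(seq_len(n), batch$actions)
  logp_a <- fw$logp[idx]
  ratio <- exp(logp_a - batch$old_logp)
  A <- batch$advantages
  lo <- 1 - config$clip_eps; hi <- 1 + config$clip_eps
  unclipped <- ratio * A
  clipped <- pmin(pmax(ratio, lo), hi) * A
  take_unclipped <- unclipped <= clipped   # min(); ties -> unclipped branch
  # d surrogate / d logp_a = ratio * A when the unclipped branch is active
  # (or the clip is inactive), else 0
  active <- take_unclipped | (ratio > lo & ratio < hi)
  dlogp_a <- ifelse(active, ratio * A, 0) / n
  p <- fw$cache$prob
  # d logp_a / d logits = onehot - p ; entropy gradient over feasible cols
  glogits <- -p * dlogp_a  # start with -p * dlogp_a for all columns
  glogits[idx] <- glogits[idx] + dlogp_a
  logp_safe <- ifelse(is.finite(fw$logp), fw$logp, 0)
  ent_row <- rowSums(ifelse(is.finite(fw$logp), -p * fw$logp, 0))
  # d entropy / d logits_k = -p_k (logp_k + ent_row) (masked cols have p=0)
  gent <- -p * (logp_safe + ent_row)
  glogits <- glogits + config$c_entropy * gent / n
  gvalue <- -config$c_value * 2 * (fw$value - batch$returns) / n
  # negate for descent (Adam minimizes)
  policy_backward(policy, fw$cache, -glogits, -gvalue)
}

#' Train a PPO policy on the nutrition environment
#'
#' Collects `rollout` masked environment steps per update (episodes reset
#' automatically), computes GAE advantages per episode segment, and runs
#' `epochs_per_update` passes of minibatch Adam on the clipped objective.
#' Action sampling uses the feasibility mask, so infeasible actions have
#' zero probability throughout; cumulative upper-bound violations are
#' asserted never to occur and counted in the returned curve.
#'
#' @param profile a [patient_profile].
#' @param food_db a food database.
#' @param horizon episode length.
#' @param config a [ppo_config()].
#' @param weights a [reward_weights()].
#' @return An object of class `ppo_result`: `policy`, `curve` (one row per
#'   update: mean episode reward, mean per-step components, diagnostics),
#'   and `n_bound_violations` (always 0 under masking).
#' @export
train_ppo <- function(profile, food_db, horizon = 5L, config = ppo_config(),
                      weights = reward_weights()) {
  s0 <- nutri_reset(profile, food_db, horizon)
  if (!length(feasible_actions(s0)))
    stop(errorCondition("environment has no feasible first action",
                        class = c("cardiopipe_infeasible_env", "error")))
  n_act <- length(food_db)
  sd0 <- length(nutri_state_features(s0))
  policy <- ppo_policy_new(sd0, n_act, config$hidden, config$seed)
  curve <- data.frame()
  violations <- 0L
  step_t <- 0L
  with_seed(derive_seed(config$seed, "ppo"), {
    state <- nutri_reset(profile, food_db, horizon)
    for (up in seq_len(config$updates)) {
      # ---- rollout ----
      S <- matrix(0, config$rollout, sd0)
      Msk <- matrix(FALSE, config$rollout, n_act)
      acts <- integer(config$rollout)
      logps <- numeric(config$rollout)
      rews <- numeric(config$rollout)
      vals <- numeric(config$rollout)
      dones <- logical(config$rollout)
      comp_sums <- c(adherence = 0, risk = 0, preference = 0,
                     diversity = 0, cost = 0)
      ep_rewards <- c(); ep_acc <- 0
      final_adh <- c()
      for (k in seq_len(config$rollout)) {
        feats <- nutri_state_features(state)
        mask <- feasibility_mask(state)
        fw <- policy_forward(policy, matrix(feats, 1L), matrix(mask, 1L))
        pr <- exp(fw$logp[1L, ])
        a <- sample.int(n_act, 1L, prob = pr)
        out <- nutri_step(state, a, weights)
        if (any(out$next_state$cumulative > profile$upper + 1e-9))
          violations <- violations + 1L
        S[k, ] <- feats; Msk[k, ] <- mask
        acts[k] <- a; logps[k] <- fw$logp[1L, a]
        rews[k] <- out$reward; vals[k] <- fw$value
        dones[k] <- out$done
        comp_sums <- comp_sums + unlist(out$components)
        ep_acc <- ep_acc + out$reward
        if (out$done) {
          ep_rewards <- c(ep_rewards, ep_acc); ep_acc <- 0
          final_adh <- c(final_adh, out$components$adherence)
          state <- nutri_reset(profile, food_db, horizon)
        } else state <- out$next_state
      }
      # ---- advantages per episode segment ----
      adv <- numeric(config$rollout); ret <- numeric(config$rollout)
      seg_start <- 1L
      for (k in seq_len(config$rollout)) {
        if (dones[k] || k == config$rollout) {
          seg <- seg_start:k
          boot <- if (dones[k]) 0 else {
            policy_forward(policy,
                           matrix(nutri_state_features(state), 1L),
                           matrix(feasibility_mask(state), 1L))$value
          }
          g <- gae(rews[seg], c(vals[seg], boot), config$gamma, config$lambda)
          adv[seg] <- g$advantages; ret[seg] <- g$returns
          seg_start <- k + 1L
        }
      }
      if (config$normalize_adv && stats::sd(adv) > 0)
        adv <- (adv - mean(adv)) / stats::sd(adv)
      # ---- minibatch updates ----
      diag_obj <- NA_real_
      for (pe in seq_len(config$epochs_per_update)) {
        ord <- sample.int(config$rollout)
        for (mb in split(ord, ceiling(seq_along(ord) / config$minibatch))) {
          batch <- list(S = S[mb, , drop = FALSE],
                        mask = Msk[mb, , drop = FALSE],
                        actions = acts[mb], old_logp = logps[mb],
                        advantages = adv[mb], returns = ret[mb])
          if (config$lr > 0) {
            grads <- ppo_grads(batch, policy, config)
            step_t <- step_t + 1L
            policy <- policy_update(policy, grads, config$lr, step_t)
          }
        }
      }
      dg <- ppo_loss(list(S = S, mask = Msk, actions = acts, old_logp = logps,
                          advantages = adv, returns = ret), policy, config)
      curve <- rbind(curve, data.frame(
        update = up,
        mean_episode_reward = if (length(ep_rewards)) mean(ep_rewards) else NA_real_,
        mean_final_adherence = if (length(final_adh)) mean(final_adh) else NA_real_,
        adherence = comp_sums[["adherence"]] / config$rollout,
        risk = comp_sums[["risk"]] / config$rollout,
        preference = comp_sums[["preference"]] / config$rollout,
        diversity = comp_sums[["diversity"]] / config$rollout,
        cost = comp_sums[["cost"]] / config$rollout,
        entropy = dg$entropy, value_error = dg$value_error,
        clip_fraction = dg$clip_fraction))
    }
  })
  structure(list(policy = policy, curve = curve,
                 n_bound_violations = violations, config = config,
                 weights = weights),
            class = "ppo_result")
}

#' @export
print.ppo_result <- function(x, ...) {
  cat(sprintf("<ppo_result> %d updates, final mean episode reward %.3f, %d bound violations\n",
              nrow(x$curve), utils::tail(x$curve$mean_episode_reward, 1),
              x$n_bound_violations))
  invisible(x)
}

#' Greedy meal-plan recommendation
#'
#' Decodes a plan by repeatedly taking the feasible action with maximal
#' policy probability. Reports the chosen items, nutrient totals, the
#' per-step reward components, and any shortfall against the guideline
#' lower bounds.
#'
#' @param policy a `ppo_policy` (e.g. `train_ppo(...)$policy`).
#' @param profile a [patient_profile].
#' @param food_db the food database.
#' @param horizon maximal plan length.
#' @param weights a [reward_weights()].
#' @return List (`meal_plan`): `items` (ids in order), `totals`,
#'   `shortfall` (vs lower bounds), `reward`, `components`, `infeasible`.
#' @export
recommend <- function(policy, profile, food_db, horizon = 5L,
                      weights = reward_weights()) {
  state <- nutri_reset(profile, food_db, horizon)
  items <- character(0)
  total_reward <- 0
  comps <- c(adherence = 0, risk = 0, preference = 0, diversity = 0, cost = 0)
  while (!state$done && state$t < horizon) {
    mask <- feasibility_mask(state)
    if (!any(mask)) { state$infeasible <- TRUE; break }
    fw <- policy_forward(policy, matrix(nutri_state_features(state), 1L),
                         matrix(mask, 1L))
    a <- which.max(fw$logp[1L, ])
    out <- nutri_step(state, a, weights)
    items <- c(items, state$food_db[[a]]$id)
    total_reward <- total_reward + out$reward
    comps <- comps + unlist(out$components)
    state <- out$next_state
  }
  structure(list(items = items, totals = state$cumulative,
                 shortfall = pmax(0, profile$lower - state$cumulative),
                 reward = total_reward, components = comps,
                 infeasible = isTRUE(state$infeasible)),
            class = "meal_plan")
}

#' @export
print.meal_plan <- function(x, ...) {
  cat("<meal_plan>", paste(x$items, collapse = " -> "), "\n")
  cat("totals:\n"); print(round(x$totals, 1))
  if (any(x$shortfall > 0)) { cat("shortfall vs lower bounds:\n")
    print(round(x$shortfall[x$shortfall > 0], 1)) }
  cat(sprintf("total reward %.3f%s\n", x$reward,
              if (x$infeasible) " [terminated infeasible]" else ""))
  invisible(x)
}

#' Fraction of nondecreasing adjacent-window comparisons of a curve
#'
#' Splits a series into consecutive windows of `window` points, averages
#' each, and reports the fraction of adjacent window pairs whose mean does
#' not decrease — a simple monotone-trend summary for learning curves.
#'
#' @param values numeric series (NAs dropped).
#' @param window window width in points.
#' @return Fraction in `[0, 1]`.
#' @export
trend_fraction <- function(values, window = 10L) {
  v <- values[!is.na(values)]
  nw <- length(v) %/% window
  if (nw < 2L) return(NA_real_)
  wm <- vapply(seq_len(nw), function(i)
    mean(v[((i - 1L) * window + 1L):(i * window)]), numeric(1))
  mean(diff(wm) >= 0)
}
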