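# Guideline-constrained nutrition MDP: state, feasibility masking, and the
# five-component reward (adherence, risk, preference, diversity, cost).
#
# Inside the environment all nutrient quantities are expressed on the
# guideline-normalized scale (divided by the profile's target vector g), so
# the five reward components are commensurate regardless of the nutrients'
# physical units; the standalone term functions below stay in whatever units
# they are given.

#' Reward weights for the nutrition environment
#'
#' Mixing weights of the five reward components plus the three inner
#' coefficients: the preference-violation penalty, the repetition penalty,
#' and the cost coefficient. All nonnegative.
#'
#' @param alpha adherence weight. @param beta risk weight.
#' @param gamma_pref preference weight. @param delta_div diversity weight.
#' @param eta_cost cost weight.
#' @param lambda_viol penalty when preferences are violated.
#' @param rho per-repetition penalty.
#' @param kappa_cost cost coefficient (per currency unit).
#' @return An object of class `reward_weights`.
#' @export
reward_weights <- function(alpha = 1, beta = 1, gamma_pref = 0.5,
                           delta_div = 0.3, eta_cost = 0.1,
                           lambda_viol = 1, rho = 0.5, kappa_cost = 0.05) {
  w <- list(alpha = alpha, beta = beta, gamma_pref = gamma_pref,
            delta_div = delta_div, eta_cost = eta_cost,
            lambda_viol = lambda_viol, rho = rho, kappa_cost = kappa_cost)
  if (any(unlist(w) < 0)) stop_invalid("all reward weights must be >= 0")
  structure(w, class = "reward_weights")
}

#' Guideline-adherence penalty
#'
#' `-(1/d) * sum_i max(0, |c_i - g_i| - T_i)^2`: zero while every nutrient
#' is within its tolerance band around the target, quadratic beyond it.
#'
#' @param c cumulative nutrient vector.
#' @param g guideline targets.
#' @param tol per-nutrient tolerances.
#' @return Nonpositive scalar.
#' @export
adherence_term <- function(c, g, tol) {
  -mean(pmax(0, abs(c - g) - tol)^2)
}

#' Risk-weighted hard-maximum penalty
#'
#' `-sum_i w_i * max(0, c_i - gmax_i)^2`: penalizes exceeding the
#' disease-specific hard maxima, weighted per nutrient.
#'
#' @param c cumulative nutrient vector.
#' @param gmax per-nutrient hard maxima.
#' @param w_risk nonnegative per-nutrient weights.
#' @return Nonpositive scalar.
#' @export
risk_term <- function(c, gmax, w_risk) {
  -sum(w_risk * pmax(0, c - gmax)^2)
}

# prefs satisfied: the item carries all required tags and none forbidden
prefs_satisfied <- function(item, prefs) {
  all(prefs$required %in% item$tags) && !any(prefs$forbidden %in% item$tags)
}

#' Preference, diversity and cost reward components
#'
#' Preference is `+1` when the action satisfies the profile's tag
#' preferences and `-lambda_viol` otherwise; diversity is `-rho` times the
#' number of prior picks of the same item within the episode; cost is
#' `-kappa_cost` times the item's cost.
#'
#' @param action a [food_item].
#' @param state a `nutri_state` (for the history and profile).
#' @param weights a [reward_weights()].
#' @return Named list: `preference`, `diversity`, `cost`.
#' @export
soft_terms <- function(action, state, weights = reward_weights()) {
  rep_count <- sum(state$history == action$id)
  list(preference = if (prefs_satisfied(action, state$profile$prefs)) 1
                    else -weights$lambda_viol,
       diversity = -weights$rho * rep_count,
       cost = -weights$kappa_cost * action$cost)
}

#' Initialize a nutrition episode
#'
#' Zero cumulative intake, empty history, step counter 0. The state bundles
#' the profile, the food database and the horizon so stepping needs no
#' external context.
#'
#' @param profile a [patient_profile].
#' @param food_db a [gen_food_db()] list.
#' @param horizon number of meal slots per episode (> 0).
#' @param prorate_adherence compare cumulative intake against targets
#'   prorated by `(t+1)/horizon` (default) rather than full-day targets at
#'   every step.
#' @param seed kept for interface symmetry; the reset itself is
#'   deterministic.
#' @return An object of class `nutri_state`.
#' @export
nutri_reset <- function(profile, food_db, horizon = 5L,
                        prorate_adherence = TRUE, seed = 1L) {
  stopifnot(inherits(profile, "patient_profile"))
  horizon <- check_count(horizon, "horizon")
  structure(list(profile = profile, food_db = food_db, horizon = horizon,
                 cumulative = stats::setNames(numeric(length(NUTRIENTS)), NUTRIENTS),
                 t = 0L, history = character(0),
                 prorate = isTRUE(prorate_adherence),
                 done = FALSE, infeasible = FALSE),
            class = "nutri_state")
}

#' @export
print.nutri_state <- function(x, ...) {
  cat(sprintf("<nutri_state> t=%d/%d, %d items chosen%s\n", x$t, x$horizon,
              length(x$history), if (x$done) " [done]" else ""))
  invisible(x)
}

#' Feasible actions under the hard constraints
#'
#' An item is feasible when adding its nutrient vector keeps the cumulative
#' intake at or below the profile's upper bounds, the item is not excluded,
#' and it carries no forbidden tag. (The guideline lower bounds are
#' enforced terminally, not per step, since no single early serving can meet
#' a daily minimum.)
#'
#' @param state a `nutri_state`.
#' @param food_db optional override of the state's database.
#' @return Integer indices into the database (possibly empty).
#' @export
feasible_actions <- function(state, food_db = state$food_db) {
  u <- state$profile$upper
  ex <- state$profile$exclusions
  forb <- state$profile$prefs$forbidden
  which(vapply(food_db, function(item) {
    all(state$cumulative + item$nutrients <= u) &&
      !(item$id %in% ex) && !any(forb %in% item$tags)
  }, logical(1)))
}

#' Take one environment step
#'
#' Adds the chosen item's nutrients to the cumulative intake and assembles
#' the reward `alpha*adherence + beta*risk + gamma*preference +
#' delta*diversity + eta*cost`, all terms computed on the
#' guideline-normalized scale (nutrients divided by the target vector).
#' Adherence compares intake to targets prorated by episode progress when
#' the state was created with `prorate_adherence = TRUE` (full-day
#' tolerances either way). The episode ends at the horizon or when no
#' feasible action remains (flagged `infeasible`, not an error); at episode
#' end the guideline lower-bound shortfall penalty
#' `-(1/d) sum max(0, l_i - c_i)^2` (normalized scale) is added to the
#' adherence component.
#'
#' Calling with an infeasible action is a contract violation and errors:
#' masking is the caller's obligation.
#'
#' @param state a `nutri_state`.
#' @param action integer index into the food database.
#' @param weights a [reward_weights()].
#' @return List (`step_outcome`): `next_state`, `reward`, `components`
#'   (the five raw components), `done`.
#' @export
nutri_step <- function(state, action, weights = reward_weights()) {
  stopifnot(inherits(state, "nutri_state"))
  if (state$done) stop_invalid("episode already finished")
  feas <- feasible_actions(state)
  if (!(action %in% feas))
    stop(errorCondition(paste0("action ", action, " violates the feasibility",
                               " mask; masking is the caller's obligation"),
                        class = c("cardiopipe_contract_violation", "error")))
  item <- state$food_db[[action]]
  prof <- state$profile
  g <- prof$targets
  cn <- (state$cumulative + item$nutrients) / g
  t_new <- state$t + 1L
  frac <- if (state$prorate) t_new / state$horizon else 1
  adh <- adherence_term(cn, frac * rep(1, length(g)), prof$tol / g)
  rsk <- risk_term(cn, prof$gmax / g, prof$risk_weights)
  soft <- soft_terms(item, state, weights)
  next_state <- state
  next_state$cumulative <- state$cumulative + item$nutrients
  next_state$t <- t_new
  next_state$history <- c(state$history, item$id)
  done <- t_new >= state$horizon
  if (!done && !length(feasible_actions(next_state))) {
    done <- TRUE
    next_state$infeasible <- TRUE
  }
  if (done) {
    adh <- adh + -mean(pmax(0, prof$lower / g - cn)^2)
    next_state$done <- TRUE
  }
  components <- list(adherence = adh, risk = rsk,
                     preference = soft$preference,
                     diversity = soft$diversity, cost = soft$cost)
  reward <- weights$alpha * adh + weights$beta * rsk +
    weights$gamma_pref * soft$preference +
    weights$delta_div * soft$diversity + weights$eta_cost * soft$cost
  structure(list(next_state = next_state, reward = reward,
                 components = components, done = done),
            class = "step_outcome")
}
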