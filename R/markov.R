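# Two-arm discounted Markov cohort simulator. Stands in for the external
# published cost-effectiveness models when exercising the pricing
# pipeline: each arm propagates a cohort through a time-homogeneous
# state-transition matrix, accumulating discounted QALYs and costs, with
# the device price charged once at time zero in the new-treatment arm.

#' Specification of a synthetic two-arm Markov cohort model
#'
#' Defines a discrete-time cohort model shared by two arms that differ
#' only in their transition matrices: arm A (new treatment, charged the
#' device price once at cycle 0) and arm B (comparator). Rewards are
#' counted at cycle start — state membership before that cycle's
#' transition — and discounted at an annual rate compounded per cycle.
#' State utilities are per cycle-year in \[0, 1\]; cycle costs are EUR per
#' state per cycle. Absorbing states get utility and cost 0 unless
#' `allow_absorbing_rewards = TRUE`.
#'
#' @param states character vector of state labels.
#' @param trans_A,trans_B row-stochastic square transition matrices
#'   (rows sum to 1 within 1e-12, entries >= 0), one per arm.
#' @param init initial state-occupancy probability vector (sums to 1).
#' @param n_cycles positive integer number of cycles.
#' @param cycle_length_months cycle length in months (default 12).
#' @param utility per-state utility weight per cycle-year.
#' @param cost_per_cycle per-state EUR cost per cycle (shared by both arms;
#'   arm totals differ through occupancy).
#' @param device_price_A EUR price of the device, charged undiscounted at
#'   cycle 0 in arm A only.
#' @param discount_annual annual discount rate, >= 0 (default 0).
#' @param absorbing logical vector flagging absorbing states; defaults to
#'   states whose self-transition is 1 in both arms.
#' @param allow_absorbing_rewards keep nonzero utility/cost on absorbing
#'   states instead of zeroing them.
#' @return an object of class `markov_spec`.
#' @export
#' @examples
#' spec <- markov_spec(
#'   states = c("alive", "dead"),
#'   trans_A = matrix(c(0.95, 0.05, 0, 1), 2, byrow = TRUE),
#'   trans_B = matrix(c(0.90, 0.10, 0, 1), 2, byrow = TRUE),
#'   init = c(1, 0), n_cycles = 10, utility = c(0.8, 0),
#'   cost_per_cycle = c(1200, 0), device_price_A = 9000,
#'   discount_annual = 0.03)
markov_spec <- function(states, trans_A, trans_B, init, n_cycles,
                        cycle_length_months = 12,
                        utility = rep(1, length(states)),
                        cost_per_cycle = rep(0, length(states)),
                        device_price_A = 0,
                        discount_annual = 0,
                        absorbing = NULL,
                        allow_absorbing_rewards = FALSE) {
  k <- length(states)
  check_matrix <- function(m, arm) {
    if (!is.matrix(m) || nrow(m) != k || ncol(m) != k)
      stop_validation(sprintf("transition matrix for arm %s must be %dx%d", arm, k, k))
    if (any(m < 0))
      stop_validation(sprintf("negative transition probabilities in arm %s", arm))
    if (any(abs(rowSums(m) - 1) > 1e-12))
      stop_validation(sprintf("transition rows must sum to 1 in arm %s", arm))
    unname(m)
  }
  trans_A <- check_matrix(trans_A, "A")
  trans_B <- check_matrix(trans_B, "B")
  if (length(init) != k || any(init < 0) || abs(sum(init) - 1) > 1e-12)
    stop_validation("init must be a probability vector over the states")
  if (n_cycles < 1 || n_cycles != round(n_cycles))
    stop_validation("n_cycles must be a positive integer")
  if (cycle_length_months <= 0) stop_validation("cycle_length_months must be positive")
  if (any(utility < 0) || any(utility > 1))
    stop_validation("utilities must lie in [0, 1] per cycle-year")
  if (discount_annual < 0) stop_validation("discount_annual must be >= 0")
  if (is.null(absorbing))
    absorbing <- diag(trans_A) == 1 & diag(trans_B) == 1
  if (!allow_absorbing_rewards) {
    utility[absorbing] <- 0
    cost_per_cycle[absorbing] <- 0
  }
  structure(list(states = states, absorbing = absorbing,
                 trans_A = trans_A, trans_B = trans_B, init = unname(init),
                 n_cycles = as.integer(n_cycles),
                 cycle_length_months = cycle_length_months,
                 utility = unname(utility), cost_per_cycle = unname(cost_per_cycle),
                 device_price_A = device_price_A,
                 discount_annual = discount_annual),
            class = "markov_spec")
}

#' Simulate one arm of a Markov cohort model
#'
#' Propagates the cohort `n_cycles` steps. Per-cycle QALY reward is
#' occupancy-at-cycle-start times `utility * cycle_length_years`; costs
#' likewise with the per-cycle state costs; both discounted by
#' `(1 + r)^(-t * cycle_length_years)` with `t` the cycle index. No
#' half-cycle correction is applied unless `half_cycle = TRUE` (which
#' averages start- and end-of-cycle occupancy). In arm A the device price
#' is added undiscounted at time zero.
#'
#' @param spec a [markov_spec()].
#' @param arm `"A"` (new treatment) or `"B"` (comparator).
#' @param half_cycle apply a half-cycle correction to rewards.
#' @return a list of class `arm_outcome` with `discounted_qalys`,
#'   `discounted_cost` (EUR) and `occupancy`, the
#'   `(n_cycles + 1) x n_states` state-probability trace.
#' @export
simulate_arm <- function(spec, arm = c("A", "B"), half_cycle = FALSE) {
  if (!inherits(spec, "markov_spec")) stop_validation("spec must be a markov_spec")
  arm <- match.arg(arm)
  P <- if (arm == "A") spec$trans_A else spec$trans_B
  k <- length(spec$states)
  cly <- spec$cycle_length_months / 12
  occ <- matrix(NA_real_, nrow = spec$n_cycles + 1L, ncol = k,
                dimnames = list(NULL, spec$states))
  occ[1, ] <- spec$init
  for (t in seq_len(spec$n_cycles)) occ[t + 1, ] <- occ[t, ] %*% P
  weights <- if (half_cycle) {
    (occ[seq_len(spec$n_cycles), , drop = FALSE] +
       occ[seq_len(spec$n_cycles) + 1L, , drop = FALSE]) / 2
  } else {
    occ[seq_len(spec$n_cycles), , drop = FALSE]
  }
  disc <- (1 + spec$discount_annual)^(-(seq_len(spec$n_cycles) - 1L) * cly)
  qalys <- sum(disc * (weights %*% (spec$utility * cly)))
  cost <- sum(disc * (weights %*% spec$cost_per_cycle))
  if (arm == "A") cost <- cost + spec$device_price_A
  structure(list(discounted_qalys = qalys,
                 discounted_cost = money(cost, "EUR"),
                 occupancy = occ, arm = arm),
            class = "arm_outcome")
}

#' Assemble CEA inputs from a simulated two-arm model
#'
#' Simulates both arms and packages the results as the pricing
#' parameters: `gain` is the discounted QALY difference, `othercosts_A`
#' the arm-A discounted cost net of the device price, `cost_B` the arm-B
#' discounted cost. Also returns the implied ICER of the model at its own
#' device price — feeding that ICER back into [value_based_price()]
#' recovers the device price exactly, the simulator's parameter-recovery
#' identity. A zero gain leaves the ICER undefined (`NA` with a warning)
#' while still returning the inputs.
#'
#' @param spec a [markov_spec()].
#' @param half_cycle passed to [simulate_arm()].
#' @return a list with `inputs` ([cea_inputs()] in EUR), `implied_icer`
#'   (EUR/QALY or `NA`), and the two `arm_outcome`s.
#' @export
make_cea_inputs <- function(spec, half_cycle = FALSE) {
  a <- simulate_arm(spec, "A", half_cycle)
  b <- simulate_arm(spec, "B", half_cycle)
  gain <- a$discounted_qalys - b$discounted_qalys
  inputs <- cea_inputs(
    gain = gain,
    cost_B = b$discounted_cost,
    othercosts_A = a$discounted_cost - money(spec$device_price_A, "EUR"),
    outcome_kind = "QALY",
    time_horizon_months = spec$n_cycles * spec$cycle_length_months,
    source = "synthetic Markov cohort model",
    source_kind = "CEA_registry")
  implied_icer <- if (gain == 0) {
    warn_vbp("zero QALY gain: implied ICER undefined", "undefined_icer")
    NA_real_
  } else {
    icer(a$discounted_cost, b$discounted_cost,
         a$discounted_qalys, b$discounted_qalys)
  }
  list(inputs = inputs, implied_icer = implied_icer, arm_A = a, arm_B = b)
}

# Two-state (alive/dead) spec with constant per-cycle death probability.
two_state_spec <- function(p_death_A, p_death_B, n_cycles,
                           cycle_length_months = 12, utility_alive = 1,
                           cost_alive = 0, device_price_A = 0,
                           discount_annual = 0) {
  markov_spec(states = c("alive", "dead"),
              trans_A = matrix(c(1 - p_death_A, p_death_A, 0, 1), 2, byrow = TRUE),
              trans_B = matrix(c(1 - p_death_B, p_death_B, 0, 1), 2, byrow = TRUE),
              init = c(1, 0), n_cycles = n_cycles,
              cycle_length_months = cycle_length_months,
              absorbing = c(FALSE, TRUE), # alive stays rewarded even if deathless
              utility = c(utility_alive, 0),
              cost_per_cycle = c(cost_alive, 0),
              device_price_A = device_price_A,
              discount_annual = discount_annual)
}

# Discounted sum of alive-state occupancy over n cycles for constant
# per-cycle death probability p (geometric series, used for calibration).
discounted_alive_sum <- function(p, n, discount_annual, cly) {
  d <- (1 + discount_annual)^(-cly)
  x <- (1 - p) * d
  if (abs(x - 1) < 1e-14) n else (1 - x^n) / (1 - x)
}

#' Generate a synthetic device portfolio
#'
#' Emulates the statistical structure of a real HTA device portfolio: only
#' a fraction of devices (default 21%) carry usable cost-effectiveness
#' parameters, and real market prices scatter log-normally around the
#' value-based price at the 60,000 EUR/QALY threshold. Each eligible
#' device's parameters come from a randomised two-state Markov cohort
#' model (20 annual cycles, 3% annual discount): QALY gains are
#' log-normal around 0.1 (the arm-A transition probability is calibrated
#' by root-finding to hit each drawn gain), and comparator discounted
#' costs are log-normal around 10,000 EUR. Ineligible devices get a price
#' only. Fully reproducible given `seed`.
#'
#' @param n number of devices.
#' @param eligible_fraction fraction with CEA data; the eligible count is
#'   `round(n * eligible_fraction)` half-up.
#' @param price_noise_sd standard deviation of the log-scale price noise
#'   (0 makes every real price equal its value-based price).
#' @param seed integer seed; identical seeds give identical portfolios.
#' @return a portfolio `data.frame` in the [read_portfolio()] schema.
#' @export
#' @examples
#' p <- generate_portfolio(24, seed = 7)
#' screen_portfolio(p)$summary
generate_portfolio <- function(n, eligible_fraction = 0.21,
                               price_noise_sd = 0.5, seed = 1) {
  if (n < 1 || n != round(n)) stop_domain("n must be a positive integer")
  if (eligible_fraction < 0 || eligible_fraction > 1)
    stop_domain("eligible_fraction must lie in [0, 1]")
  if (price_noise_sd < 0) stop_domain("price_noise_sd must be >= 0")
  set.seed(seed)
  n_eligible <- round_half_up(n * eligible_fraction)
  eligible_idx <- if (n_eligible > 0) sort(sample.int(n, n_eligible)) else integer(0)

  n_cycles <- 20L; discount <- 0.03; cly <- 1
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("SYN%02d", i)
    if (i %in% eligible_idx) {
      p_B <- runif(1, 0.08, 0.25)
      u <- runif(1, 0.6, 0.9)
      gain_target <- rlnorm(1, meanlog = log(0.1), sdlog = 0.5)
      q_of <- function(p) u * cly * discounted_alive_sum(p, n_cycles, discount, cly)
      gain_max <- q_of(1e-9) - q_of(p_B)
      gain_target <- min(gain_target, 0.99 * gain_max)
      p_A <- uniroot(function(p) q_of(p) - q_of(p_B) - gain_target,
                     c(1e-9, p_B), tol = 1e-12)$root
      cost_B_target <- rlnorm(1, meanlog = log(1e4), sdlog = 0.5)
      cost_cycle <- cost_B_target / discounted_alive_sum(p_B, n_cycles, discount, cly)
      device_price <- rlnorm(1, meanlog = log(1e4), sdlog = 0.7)
      spec <- two_state_spec(p_A, p_B, n_cycles, cycle_length_months = 12,
                             utility_alive = u, cost_alive = cost_cycle,
                             device_price_A = device_price,
                             discount_annual = discount)
      made <- suppressWarnings(make_cea_inputs(spec))
      inp <- made$inputs
      vbp60 <- suppressWarnings(value_based_price(60000, inp))
      real <- if (vbp60 > 0) vbp60 * exp(rnorm(1, 0, price_noise_sd)) else device_price
      rows[[i]] <- data.frame(
        device_id = id, name = paste("Synthetic device", i),
        description = "synthetic Markov-derived device",
        comparator = "standard of care",
        real_price = real, real_price_currency = "EUR", has_cea = TRUE,
        gain = inp$gain, outcome_kind = "QALY",
        surv1y_a = NA_real_, surv1y_b = NA_real_,
        cost_b = inp$cost_B$amount, cost_b_currency = "EUR",
        othercosts_a = inp$othercosts_A$amount, othercosts_a_currency = "EUR",
        time_horizon_months = as.character(n_cycles * 12L),
        source = sprintf("synthetic Markov model (seed %d)", seed),
        source_kind = "CEA_registry", reported_vbp_eur = NA_real_,
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        device_id = id, name = paste("Synthetic device", i),
        description = "synthetic placeholder without CEA data",
        comparator = "", real_price = rlnorm(1, meanlog = log(1.5e4), sdlog = 0.7),
        real_price_currency = "EUR", has_cea = FALSE,
        gain = NA_real_, outcome_kind = NA_character_,
        surv1y_a = NA_real_, surv1y_b = NA_real_,
        cost_b = NA_real_, cost_b_currency = NA_character_,
        othercosts_a = NA_real_, othercosts_a_currency = NA_character_,
        time_horizon_months = NA_character_, source = "",
        source_kind = NA_character_, reported_vbp_eur = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
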