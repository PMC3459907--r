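#' Exponential running rate of a decision sequence
#'
#' Low-pass filter \eqn{r_t = (1-\alpha) r_{t-1} + \alpha d_t} with
#' \eqn{r_0} the random-choice prior.
#'
#' @param decisions 0/1 (or numeric) sequence.
#' @param alpha Smoothing rate in (0, 1].
#' @param init Initial rate (default 0.5, random choice before learning).
#' @return Numeric vector of the same length as `decisions`.
#' @export
running_rate <- function(decisions, alpha = 0.02, init = 0.5) {
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must be in (0, 1]")
  stats::filter(alpha * decisions, 1 - alpha, method = "recursive",
                init = init)[seq_along(decisions)]
}

#' Binned rate changes, re-smoothed
#'
#' Bins a rate time course into bins of `bin_width`, takes the mean of each
#' bin, differences succeeding bins, and low-pass filters the differences
#' once more with an exponential running mean.
#'
#' @param rates Numeric rate sequence.
#' @param bin_width Bin width in trials (>= 1).
#' @param alpha2 Smoothing rate of the second filter.
#' @return Numeric vector of length `floor(length(rates)/bin_width) - 1`.
#' @export
rate_change_series <- function(rates, bin_width, alpha2 = 0.2) {
  if (bin_width < 1) stop_invalid("bin_width must be >= 1")
  n_bins <- floor(length(rates) / bin_width)
  if (n_bins < 2) stop_invalid("series too short: need at least 2 full bins")
  idx <- rep(seq_len(n_bins), each = bin_width)
  means <- tapply(rates[seq_along(idx)], idx, mean)
  d <- diff(as.numeric(means))
  as.numeric(stats::filter(alpha2 * d, 1 - alpha2, method = "recursive",
                           init = d[1]))
}

#' Empirical strategy estimate for one state
#'
#' Fraction of draw (action = 1) decisions among the last `window` visits
#' to `state`.
#'
#' @param history Data frame with columns `state` and `action`.
#' @param state State key.
#' @param window Number of most recent visits to use.
#' @return A list with `p` (the fraction; `NA` if the state was never
#'   visited), `n_used`, and `partial` (TRUE if fewer than `window` visits
#'   were available).
#' @export
estimate_strategy <- function(history, state, window = 50) {
  if (window < 1) stop_invalid("window must be >= 1")
  a <- history$action[history$state == state]
  if (!length(a)) return(list(p = NA_real_, n_used = 0L, partial = TRUE))
  used <- tail(a, window)
  list(p = mean(used), n_used = length(used),
       partial = length(used) < window)
}

parse_learner_spec <- function(spec, role, game, seed, cost_i = 0.3, ...) {
  if (inherits(spec, "learner")) return(spec)
  if (is.numeric(spec)) {
    return(if (game == "blackjack") learner_fixed(threshold = spec)
           else learner_fixed(p = spec))
  }
  if (is.list(spec)) {
    type <- spec$type
    args <- spec[setdiff(names(spec), "type")]
  } else {
    type <- as.character(spec)
    args <- list()
    if (grepl("^fixed:", type)) {
      val <- as.numeric(sub("^fixed:", "", type))
      return(parse_learner_spec(val, role, game, seed))
    }
  }
  states <- if (game == "blackjack") {
    as.character(if (role == "a") 11:18 else 13:19)
  } else "inspector"
  cfg <- inspector_config(cost_i)
  own_payoffs <- if (game == "inspector") {
    if (role == "a") cfg$employee else cfg$employer
  } else matrix(c(0, 1, -1, 0), 2)  # blackjack payoff cells are +-1
  switch(type,
    prl = do.call(learner_prl, utils::modifyList(
      list(states = states, seed = derive_seed(seed, paste0("prl", role))),
      args)),
    pcov = do.call(learner_pcov, utils::modifyList(
      list(states = states, seed = derive_seed(seed, paste0("pcov", role))),
      args)),
    td = do.call(learner_td, args),
    re1 = do.call(learner_re,
                  utils::modifyList(list(payoffs = own_payoffs,
                                         type = "re1"), args)),
    re3 = do.call(learner_re,
                  utils::modifyList(list(payoffs = own_payoffs,
                                         type = "re3"), args)),
    stop_invalid("unknown learner spec: ", type))
}

#' Run a learner-vs-learner match
#'
#' Orchestrates repeated play of one of the two games between two learners
#' (or fixed strategies), records a per-trial trajectory with low-pass
#' filtered decision rates, and summarizes block averages against the
#' analytic Nash benchmarks. Deterministic given `master_seed`.
#'
#' In the inspector game player A is the employee (action 1 = shirk) and
#' player B the employer (action 1 = inspect); the inspection cost can be
#' stepped across blocks. In blackjack player A is the gambler and player B
#' the croupier (action 1 = draw); each trial is one game and the reward of
#' the gambler is minus the bank payoff.
#'
#' @param game `"inspector"` or `"blackjack"`.
#' @param player_a,player_b Learner objects, or specs: `"prl"`, `"pcov"`,
#'   `"td"`, `"re1"`, `"re3"`, `"fixed:<value>"`, a number (fixed mixing
#'   probability / stopping value), or a list `list(type = ..., ...)` with
#'   constructor arguments.
#' @param n_trials Number of trials (ignored for the inspector game when
#'   `cost_schedule` is given).
#' @param cost_schedule Inspector cost protocol: a data frame with columns
#'   `n_trials` and `cost`, emulating the stepped-cost blocks; default one
#'   block at `cost_i`.
#' @param cost_i Inspection cost of the default single block.
#' @param master_seed Integer; every source of randomness in the run is
#'   derived from it.
#' @param smoothing_alpha Rate of the running-rate filter.
#' @param cards Card distribution for blackjack.
#' @param output_dir If non-`NULL`, writes `trajectory.csv`,
#'   `summary.json` and final weight/propensity snapshots there.
#' @return A list of class `match_result` with `trajectory` (data frame),
#'   `history_a`/`history_b` (per-decision state/action logs) and
#'   `summary`.
#' @export
run_match <- function(game = c("inspector", "blackjack"),
                      player_a, player_b, n_trials = 1000,
                      cost_schedule = NULL, cost_i = 0.3,
                      master_seed = 1, smoothing_alpha = 0.02,
                      cards = card_distribution(), output_dir = NULL) {
  game <- match.arg(game)
  if (game == "inspector" && is.null(cost_schedule))
    cost_schedule <- data.frame(n_trials = n_trials, cost = cost_i)
  first_cost <- if (game == "inspector") cost_schedule$cost[1] else cost_i
  la <- parse_learner_spec(player_a, "a", game, master_seed, first_cost)
  lb <- parse_learner_spec(player_b, "b", game, master_seed, first_cost)
  res <- with_seed(derive_seed(master_seed, "match"), {
    if (game == "inspector") {
      run_inspector_match(la, lb, cost_schedule, smoothing_alpha)
    } else {
      run_blackjack_match(la, lb, n_trials, cards, smoothing_alpha)
    }
  })
  res$game <- game
  class(res) <- "match_result"
  if (!is.null(output_dir)) write_match_artifacts(res, la, lb, output_dir)
  res
}

run_inspector_match <- function(la, lb, schedule, alpha) {
  n_total <- sum(schedule$n_trials)
  action_a <- action_b <- integer(n_total)
  reward_a <- reward_b <- numeric(n_total)
  cost <- rep(schedule$cost, schedule$n_trials)
  block <- rep(seq_len(nrow(schedule)), schedule$n_trials)
  for (t in seq_len(n_total)) {
    cfg <- inspector_config(cost[t])
    a <- act(la, "inspector")   # 1 = shirk
    b <- act(lb, "inspector")   # 1 = inspect
    r <- inspector_step(a, b, cfg)
    give_reward(la, r[["r_employee"]])
    give_reward(lb, r[["r_employer"]])
    action_a[t] <- a; action_b[t] <- b
    reward_a[t] <- r[["r_employee"]]; reward_b[t] <- r[["r_employer"]]
  }
  traj <- data.frame(
    trial = seq_len(n_total), block = block, cost = cost,
    action_a = action_a, action_b = action_b,
    reward_a = reward_a, reward_b = reward_b,
    rate_a = as.numeric(running_rate(action_a, alpha)),
    rate_b = as.numeric(running_rate(action_b, alpha)))
  blocks <- lapply(split(traj, traj$block), function(df) {
    i <- df$cost[1]
    list(cost = i, n_trials = nrow(df),
         shirk_rate = mean(df$action_a), inspect_rate = mean(df$action_b),
         mean_reward_a = mean(df$reward_a),
         mean_reward_b = mean(df$reward_b),
         nash_shirk = i, nash_inspect = 0.5,
         dist_shirk_from_nash = abs(mean(df$action_a) - i),
         dist_inspect_from_nash = abs(mean(df$action_b) - 0.5))
  })
  list(trajectory = traj,
       history_a = data.frame(state = "inspector", action = action_a),
       history_b = data.frame(state = "inspector", action = action_b),
       summary = list(blocks = blocks))
}

run_blackjack_match <- function(la, lb, n_trials, cards, alpha) {
  hand_g <- hand_c <- integer(n_trials)
  reward_bank <- numeric(n_trials)
  hist_a <- list(); hist_b <- list()
  for (t in seq_len(n_trials)) {
    ep <- play_blackjack_episode(
      function(h) act(la, as.character(h)),
      function(h) act(lb, as.character(h)), cards = cards)
    give_reward(la, ep$reward_gambler)
    give_reward(lb, ep$reward_bank)
    hand_g[t] <- ep$gambler$hand; hand_c[t] <- ep$croupier$hand
    reward_bank[t] <- ep$reward_bank
    if (length(ep$gambler$states))
      hist_a[[length(hist_a) + 1L]] <- data.frame(
        trial = t, state = as.character(ep$gambler$states),
        action = ep$gambler$actions)
    if (length(ep$croupier$states))
      hist_b[[length(hist_b) + 1L]] <- data.frame(
        trial = t, state = as.character(ep$croupier$states),
        action = ep$croupier$actions)
  }
  hist_a <- if (length(hist_a)) do.call(rbind, hist_a) else
    data.frame(trial = integer(0), state = character(0),
               action = integer(0))
  hist_b <- if (length(hist_b)) do.call(rbind, hist_b) else
    data.frame(trial = integer(0), state = character(0),
               action = integer(0))
  traj <- data.frame(
    trial = seq_len(n_trials), hand_gambler = hand_g, hand_croupier = hand_c,
    reward_bank = reward_bank,
    rate_bank_reward = as.numeric(running_rate(reward_bank, alpha,
                                               init = 0)))
  strat <- function(hist, states) {
    out <- lapply(as.character(states), function(s)
      estimate_strategy(hist, s)$p)
    names(out) <- as.character(states)
    out
  }
  list(trajectory = traj, history_a = hist_a, history_b = hist_b,
       summary = list(
         mean_bank_reward = mean(reward_bank),
         draw_prob_gambler = strat(hist_a, 11:18),
         draw_prob_croupier = strat(hist_b, 13:19)))
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Match result: %s, %d trials\n", x$game, nrow(x$trajectory)))
  utils::str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}

snapshot_learner <- function(learner) {
  if (inherits(learner, "prl_learner") || inherits(learner, "pcov_learner")) {
    list(type = class(learner)[1],
         weights = apply(learner$weights, 1, identity, simplify = FALSE))
  } else if (inherits(learner, "td_learner")) {
    list(type = "td_learner", q = as.list(learner$tab$q))
  } else if (inherits(learner, "re_learner")) {
    list(type = "re_learner", propensities = lapply(learner$pvs, `[[`, "q"))
  } else {
    list(type = class(learner)[1])
  }
}

write_match_artifacts <- function(res, la, lb, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$trajectory, file.path(output_dir, "trajectory.csv"),
            row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(player_a = snapshot_learner(la),
                            player_b = snapshot_learner(lb)),
                       file.path(output_dir, "snapshots.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
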