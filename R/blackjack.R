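#' Card-value distribution
#'
#' Infinite-deck approximation of a standard 52-card deck: the drawing
#' probability is constant regardless of history, with value 10 (ten, jack,
#' queen, king) carrying mass 4/13 and each of the values 2--9 and 11 (ace)
#' mass 1/13. The `"piquet32"` variant is the 32-card deck used in human
#' experiments (7, 8, 9 and ace at 1/8 each, value 10 at 4/8); it has no
#' printed analytic oracle and is provided for exploration only.
#'
#' @param type `"infinite"` (default) or `"piquet32"`.
#' @return An object of class `card_distribution`: a named probability
#'   vector over card values.
#' @export
card_distribution <- function(type = c("infinite", "piquet32")) {
  type <- match.arg(type)
  pmf <- if (type == "infinite") {
    c(rep(1 / 13, 8), 4 / 13, 1 / 13)
  } else {
    c(0, 0, 0, 0, 0, 1 / 8, 1 / 8, 1 / 8, 4 / 8, 1 / 8)
  }
  names(pmf) <- 2:11
  pmf <- pmf[pmf > 0]
  structure(pmf, class = "card_distribution", type = type)
}

#' Final hand-value distribution for a fixed stopping value
#'
#' Exact forward iteration of the drawing process: starting from hand 0,
#' all probability mass on hand values below the stopping value `s` is
#' repeatedly convolved with the card distribution until every value is at
#' least `s`; mass above 21 is aggregated into `bust`. At most
#' \eqn{\lceil s/2 \rceil + 1} draws occur since the smallest card is 2.
#'
#' @param s Stopping value, between 2 and 21: the player draws while the
#'   hand value is below `s` (at `s = 2` exactly one card is drawn and the
#'   final distribution equals the card distribution).
#' @param cards A [card_distribution()].
#' @return An object of class `stopping_pmf`: a list with `s` and `pmf`, a
#'   named probability vector over final values `s..21` plus `"bust"`.
#' @export
#' @examples
#' round(stopping_distribution(15)$pmf, 4)
stopping_distribution <- function(s, cards = card_distribution()) {
  if (s < 2 || s > 21) stop_invalid("stopping value must be in [2, 21]")
  vals <- as.integer(names(cards))
  top <- 21 + max(vals)          # largest reachable hand: <= 20 + 11
  mass <- numeric(top + 1)       # index h + 1 holds P(hand = h)
  mass[1] <- 1
  repeat {
    live <- which(mass > 0 & seq_along(mass) - 1 < s)
    if (!length(live)) break
    add <- numeric(top + 1)
    for (h1 in live) {
      add[h1 + vals] <- add[h1 + vals] + mass[h1] * cards
      mass[h1] <- 0
    }
    mass <- mass + add
  }
  pmf <- mass[(s:21) + 1]
  names(pmf) <- s:21
  pmf <- c(pmf, bust = sum(mass[(22:top) + 1]))
  structure(list(s = as.integer(s), pmf = pmf), class = "stopping_pmf")
}

#' @export
print.stopping_pmf <- function(x, ...) {
  cat(sprintf("Final hand-value distribution, stopping value s = %d\n", x$s))
  print(round(x$pmf, 4))
  invisible(x)
}

#' Bank payoff of one blackjack game
#'
#' +1 if the bank wins, -1 if the gambler wins (zero-sum). A gambler bust
#' loses immediately whatever the croupier does; otherwise a croupier bust
#' loses, and otherwise the higher final hand wins with a standoff (equal
#' hands) awarded to the bank.
#'
#' @param h_gambler,h_croupier Final hand values; a bust may be given as
#'   `"bust"`, `NA`, or any value above 21.
#' @return +1 or -1 (the gambler's payoff is the negative).
#' @export
bank_payoff <- function(h_gambler, h_croupier) {
  busted <- function(h) is.na(h) || identical(h, "bust") ||
    (is.numeric(h) && h > 21)
  if (busted(h_gambler)) return(1)
  if (busted(h_croupier)) return(-1)
  if (h_croupier >= h_gambler) 1 else -1
}

#' Expected bank payoff matrix over stopping strategies
#'
#' Entry \eqn{(s, b)} is the expectation of [bank_payoff()] under the
#' product of the two final-hand distributions of
#' [stopping_distribution()], for gambler stopping values `s = 11..18`
#' (rows) and croupier stopping values `b = 13..19` (columns). The game is
#' zero-sum: the gambler's expected payoff is the negative entry.
#'
#' @param cards A [card_distribution()].
#' @param gambler_range,croupier_range Integer vectors of stopping values
#'   spanning the modeled decision ranges.
#' @return A numeric matrix of class `payoff_matrix` with dimnames set to
#'   the stopping values; entries lie in `[-1, 1]`.
#' @export
mean_payoff_matrix <- function(cards = card_distribution(),
                               gambler_range = 11:18,
                               croupier_range = 13:19) {
  dist <- function(s) stopping_distribution(s, cards)
  gd <- lapply(gambler_range, dist)
  cd <- lapply(croupier_range, dist)
  entry <- function(ps, pb) {
    f <- suppressWarnings(as.numeric(names(ps$pmf)))  # bust -> NA
    g <- suppressWarnings(as.numeric(names(pb$pmf)))
    pay <- outer(f, g, function(ff, gg) {
      ifelse(is.na(ff), 1, ifelse(is.na(gg), -1, ifelse(gg >= ff, 1, -1)))
    })
    as.numeric(ps$pmf %*% pay %*% pb$pmf)
  }
  m <- matrix(0, length(gambler_range), length(croupier_range),
              dimnames = list(gambler = gambler_range,
                              croupier = croupier_range))
  for (i in seq_along(gd)) for (j in seq_along(cd))
    m[i, j] <- entry(gd[[i]], cd[[j]])
  structure(m, class = c("payoff_matrix", "matrix"))
}

#' @export
print.payoff_matrix <- function(x, digits = 4, ...) {
  cat("Expected bank payoff (rows: gambler stop, cols: croupier stop)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Saddle points of a payoff matrix
#'
#' A saddle point is an entry that is the maximum in its row and the
#' minimum in its column (the row player maximizes, the column player
#' minimizes); for a zero-sum game such a pair is a minimax solution and a
#' pure Nash equilibrium.
#'
#' @param m A numeric matrix (e.g. from [mean_payoff_matrix()]).
#' @param tol Tie tolerance.
#' @return A list with `found` (logical) and `pairs`, a data frame with
#'   one row per saddle point (`row`, `col`, labels and `value`); zero rows
#'   means no pure equilibrium exists.
#' @export
find_saddle_point <- function(m, tol = 1e-12) {
  m <- unclass(m)
  row_max <- apply(m, 1, max)
  col_min <- apply(m, 2, min)
  hits <- which(m >= row_max[row(m)] - tol & m <= col_min[col(m)] + tol,
                arr.ind = TRUE)
  rlab <- if (is.null(rownames(m))) as.character(hits[, 1])
          else rownames(m)[hits[, 1]]
  clab <- if (is.null(colnames(m))) as.character(hits[, 2])
          else colnames(m)[hits[, 2]]
  pairs <- data.frame(
    row = hits[, 1], col = hits[, 2],
    row_label = rlab, col_label = clab,
    value = m[hits], row.names = NULL, stringsAsFactors = FALSE)
  list(found = nrow(pairs) > 0, pairs = pairs)
}

#' Play one blackjack episode
#'
#' Deals cards by sampling the card distribution; the gambler draws until
#' its policy stops or the hand busts, then the croupier does the same, and
#' terminal rewards of +1/-1 are assigned by [bank_payoff()]. A policy may
#' be a fixed stopping value (draw strictly below it, no forced zones), or
#' a function `hand -> 1 (draw) / 0 (stop)` consulted only inside the
#' modeled decision range: below it the draw is forced (always safe), above
#' it the stop is forced (the trivial actions are not modeled).
#'
#' @param gambler_policy,croupier_policy Fixed stopping value or decision
#'   function (see Details).
#' @param cards A [card_distribution()].
#' @param seed Optional integer seed.
#' @param gambler_range,croupier_range Modeled decision ranges for policy
#'   functions.
#' @return A list with per-player card sequences, the decision log
#'   (`states`, `actions` for hands inside the modeled range), final hand
#'   values (`NA` = bust) and the terminal `reward_bank`/`reward_gambler`.
#' @export
play_blackjack_episode <- function(gambler_policy, croupier_policy,
                                   cards = card_distribution(), seed = NULL,
                                   gambler_range = c(11, 18),
                                   croupier_range = c(13, 19)) {
  vals <- as.integer(names(cards))
  with_seed(seed, {
    draw_card <- function() sample(vals, 1L, prob = cards)
    play_hand <- function(policy, range) {
      hand <- 0L
      drawn <- integer(0)
      states <- integer(0)
      actions <- integer(0)
      repeat {
        act <- if (is.function(policy)) {
          if (hand < range[1]) 1L
          else if (hand > range[2]) 0L
          else {
            a <- as.integer(policy(hand))
            states <- c(states, hand)
            actions <- c(actions, a)
            a
          }
        } else as.integer(hand < policy)
        if (!act) break
        card <- draw_card()
        drawn <- c(drawn, card)
        hand <- hand + card
        if (hand > 21) break
      }
      list(hand = if (hand > 21) NA_integer_ else hand, cards = drawn,
           states = states, actions = actions)
    }
    g <- play_hand(gambler_policy, gambler_range)
    cr <- if (is.na(g$hand)) {
      list(hand = NA_integer_, cards = integer(0), states = integer(0),
           actions = integer(0))                 # gambler loses immediately
    } else play_hand(croupier_policy, croupier_range)
    rb <- bank_payoff(g$hand, if (is.na(g$hand)) 0 else cr$hand)
    list(gambler = g, croupier = cr,
         reward_bank = rb, reward_gambler = -rb)
  })
}
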