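#' Inspector-game configuration
#'
#' The 2x2 bimatrix game between a lazy employee (work / shirk) and an
#' employer who may pay an inspection cost `i` (inspect / pass). Payoffs
#' (employee, employer):
#' work & inspect (0.5, 2-i); work & pass (0.5, 2);
#' shirk & inspect (0, 1-i); shirk & pass (1, 0).
#' For every `i` in (0, 1) the game has a unique, mixed Nash equilibrium.
#'
#' @param cost_i Inspection cost, in (0, 1).
#' @return An object of class `inspector_config` holding the cost and both
#'   payoff matrices (rows: employee work/shirk, columns: employer
#'   inspect/pass).
#' @export
inspector_config <- function(cost_i = 0.3) {
  if (cost_i <= 0 || cost_i >= 1)
    stop_invalid("cost_i must be in (0, 1) for an interior mixed equilibrium")
  actions <- list(employee = c("work", "shirk"),
                  employer = c("inspect", "pass"))
  employee <- matrix(c(0.5, 0, 0.5, 1), 2, 2,
                     dimnames = list(actions$employee, actions$employer))
  employer <- matrix(c(2 - cost_i, 1 - cost_i, 2, 0), 2, 2,
                     dimnames = list(actions$employee, actions$employer))
  structure(list(cost_i = cost_i, employee = employee, employer = employer),
            class = "inspector_config")
}

#' One round of the inspector game
#'
#' @param a_employee `"work"` or `"shirk"` (or 0/1 with 1 = shirk).
#' @param a_employer `"inspect"` or `"pass"` (or 0/1 with 1 = inspect).
#' @param cfg An [inspector_config()].
#' @return Numeric vector `c(r_employee, r_employer)`.
#' @export
#' @examples
#' inspector_step("shirk", "inspect", inspector_config(0.3))  # (0, 0.7)
inspector_step <- function(a_employee, a_employer,
                           cfg = inspector_config()) {
  row <- if (is.numeric(a_employee)) a_employee + 1
         else match(a_employee, rownames(cfg$employee))
  col <- if (is.numeric(a_employer)) 2 - a_employer
         else match(a_employer, colnames(cfg$employee))
  if (is.na(row) || is.na(col)) stop_invalid("unknown action")
  c(r_employee = cfg$employee[row, col], r_employer = cfg$employer[row, col])
}

#' Mixed Nash equilibrium of a 2x2 bimatrix game
#'
#' Generic indifference solver: the column player's mixture makes the row
#' player indifferent between its two rows and vice versa. Returns the
#' probability of the second row/column action. Degenerate payoffs (a zero
#' indifference denominator or a solution outside `[0, 1]`) are flagged
#' rather than silently returned.
#'
#' @param row_payoff,col_payoff 2x2 payoff matrices of the row and column
#'   player (rows = row-player actions, columns = column-player actions).
#' @return A list with `p_row2`, `p_col1`, the equilibrium `value_row` and
#'   `value_col`, the two indifference `residuals`, and `degenerate`.
#' @export
solve_mixed_2x2 <- function(row_payoff, col_payoff) {
  A <- unclass(row_payoff); B <- unclass(col_payoff)
  den_col <- A[1, 1] - A[1, 2] - A[2, 1] + A[2, 2]
  den_row <- B[1, 1] - B[1, 2] - B[2, 1] + B[2, 2]
  degenerate <- abs(den_col) < 1e-14 || abs(den_row) < 1e-14
  if (degenerate)
    return(list(p_row2 = NA_real_, p_col1 = NA_real_, value_row = NA_real_,
                value_col = NA_real_, residuals = c(NA_real_, NA_real_),
                degenerate = TRUE))
  q <- (A[2, 2] - A[1, 2]) / den_col       # P(column action 1)
  p <- (B[1, 1] - B[1, 2]) / den_row       # P(row action 2)
  row_mix <- c(1 - p, p); col_mix <- c(q, 1 - q)
  degenerate <- p < 0 || p > 1 || q < 0 || q > 1
  value_row <- as.numeric(row_mix %*% A %*% col_mix)
  value_col <- as.numeric(row_mix %*% B %*% col_mix)
  residuals <- c(
    row = as.numeric((A[1, ] - A[2, ]) %*% col_mix),
    col = as.numeric(row_mix %*% (B[, 1] - B[, 2])))
  list(p_row2 = p, p_col1 = q, value_row = value_row, value_col = value_col,
       residuals = residuals, degenerate = degenerate)
}

#' Mixed Nash equilibrium of the inspector game
#'
#' Solves the two indifference equations of the bimatrix game generically
#' (no hard-coded constants). At the unique interior equilibrium the
#' employee shirks with probability equal to the inspection cost
#' (`p_shirk = i`), the employer inspects with probability 1/2, the
#' employee's value is 0.5 for every `i`, and the employer's value is
#' `2 - 2i`.
#'
#' @param cfg An [inspector_config()].
#' @return A list with `p_shirk`, `p_inspect`, `v_employee`, `v_employer`,
#'   the indifference `residuals` and a `degenerate` flag.
#' @export
#' @examples
#' inspector_mixed_nash(inspector_config(0.2))
inspector_mixed_nash <- function(cfg = inspector_config()) {
  sol <- solve_mixed_2x2(cfg$employee, cfg$employer)
  list(p_shirk = sol$p_row2, p_inspect = sol$p_col1,
       v_employee = sol$value_row, v_employer = sol$value_col,
       residuals = sol$residuals, degenerate = sol$degenerate)
}
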