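#' Demographic and stochastic model parameters
#'
#' Bundles the four parameters every closed form consumes: the population size
#' `N`, the number of groups `M` arranged on a circle, the strategy mutation
#' probability `u` and the migration probability `v`. The scaled rates
#' `mu = N*u` and `nu = N*v` used by the large-population approximation are
#' derived and stored alongside.
#'
#' @param N Population size (integer, at least 3; the triplet kernels carry
#'   `N - 2` factors so sigma is reported only for `N >= 3`).
#' @param M Number of groups (integer, at least 1).
#' @param u Strategy mutation probability in `[0, 1]`.
#' @param v Migration probability in `[0, 1]`.
#'
#' @return An object of class `model_params`: a list with fields `N`, `M`,
#'   `u`, `v`, `mu`, `nu`.
#' @examples
#' p <- model_params(N = 100, M = 9, u = 0.07, v = 0.1)
#' p$mu  # N * u
#' @export
model_params <- function(N, M, u, v) {
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 3)
    stop("N must be a single integer >= 3", call. = FALSE)
  if (!is.numeric(M) || length(M) != 1L || M != round(M) || M < 1)
    stop("M must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(u) || length(u) != 1L || u < 0 || u > 1)
    stop("u must be a probability in [0, 1]", call. = FALSE)
  if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
    stop("v must be a probability in [0, 1]", call. = FALSE)
  structure(
    list(N = as.integer(N), M = as.integer(M), u = u, v = v,
         mu = N * u, nu = N * v),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Model parameters: N = %d individuals, M = %d groups, u = %g, v = %g\n",
              x$N, x$M, x$u, x$v))
  cat(sprintf("  scaled rates: mu = N*u = %g, nu = N*v = %g\n", x$mu, x$nu))
  invisible(x)
}

#' 2x2 payoff matrix for a two-strategy game
#'
#' Payoffs in strategy order (A, B): the row player using A receives `a`
#' against A and `b` against B; using B receives `c` against A and `d`
#' against B.
#'
#' @param a,b,c,d Finite real payoffs.
#' @return An object of class `payoff_matrix`.
#' @examples
#' # prisoner's dilemma with benefit 3 and cost 1
#' pd_payoff(b = 3, cost = 1)
#' @export
payoff_matrix <- function(a, b, c, d) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (!all(is.finite(vals))) stop("payoffs must be finite", call. = FALSE)
  structure(as.list(vals), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  cat("2x2 payoff matrix (row player):\n")
  print(m)
  invisible(x)
}

#' @describeIn payoff_matrix Prisoner's dilemma payoffs `[b-c, -c; b, 0]`
#'   for benefit `b` and cost `cost`.
#' @param cost Cost of cooperation.
#' @export
pd_payoff <- function(b, cost) payoff_matrix(b - cost, -cost, b, 0)

#' @describeIn payoff_matrix Snowdrift payoffs `[b-c/2, b-c; b, 0]`.
#' @export
sd_payoff <- function(b, cost) payoff_matrix(b - cost / 2, b - cost, b, 0)
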