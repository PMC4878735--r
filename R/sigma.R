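# Per-displacement building blocks of the closed forms: for each x in 1..M,
# S_plus(x)  = 3*Psi1 + 3*Psi2 - 2*Theta  (numerator terms),
# S_minus(x) = 3*Psi1 - 3*Psi2            (denominator terms),
# Theta(x)   = Phi1*Psi2 + Phi2*Psi1 + Phi3*alpha1.
sigma_terms <- function(p, pat) {
  stopifnot(inherits(pat, "migration_pattern"))
  if (pat$M != p$M)
    stop("migration pattern and model parameters disagree on M", call. = FALSE)
  pk <- pair_kernels(pat$f, p)
  tk <- triple_kernels(pat$f, p)
  a1 <- mutation_alpha(p)
  Theta <- tk$Phi1 * pk$Psi2 + tk$Phi2 * pk$Psi1 + tk$Phi3 * a1
  list(S_plus = 3 * pk$Psi1 + 3 * pk$Psi2 - 2 * Theta,
       S_minus = 3 * (pk$Psi1 - pk$Psi2),
       Psi1 = pk$Psi1, Psi2 = pk$Psi2, Theta = Theta, alpha1 = a1)
}

#' Stationary triplet identity probability
#'
#' The probability, in the neutral stationary distribution, that three
#' randomly chosen distinct individuals labelled 1, 2, 3 have strategies
#' `(d1, d2, d3)` (1 = A, 0 = B) and that individuals 2 and 3 share a group.
#' The closed form is `(1/(24M)) * sum_x T(x)` with, per displacement `x`,
#' `T = 3*Psi1 + 3*Psi2 + 2*Theta` when `d1 = d2 = d3`,
#' `T = 3*Psi1 - 3*Psi2` when `d1 = d2 != d3` or `d1 = d3 != d2`, and
#' `T = 3*Psi1 + 3*Psi2 - 2*Theta` when `d2 = d3 != d1`, where
#' `Theta = Phi1*Psi2 + Phi2*Psi1 + Phi3*alpha1` (kernels at `f(x)`).
#' Summing over the eight strategy triples gives the co-location probability
#' `(1/M) * sum_x Psi1(f(x))` of a random ordered pair.
#'
#' @param d1,d2,d3 Strategy bits in `{0, 1}`.
#' @param p A [model_params()] object.
#' @param pat A [global_pattern()]/[range_pattern()] migration pattern with
#'   matching `M`.
#' @return A probability in `[0, 1]`.
#' @examples
#' p <- model_params(100, 9, 0.07, 0.1)
#' triplet_probability(0, 1, 1, p, range_pattern(9, 1))
#' @export
triplet_probability <- function(d1, d2, d3, p, pat) {
  stopifnot(inherits(p, "model_params"))
  if (!all(c(d1, d2, d3) %in% c(0, 1)))
    stop("strategy bits must be 0 or 1", call. = FALSE)
  tm <- sigma_terms(p, pat)
  Tx <- if (d1 == d2 && d2 == d3) {
    3 * tm$Psi1 + 3 * tm$Psi2 + 2 * tm$Theta
  } else if (d2 == d3) {         # d2 = d3 != d1
    tm$S_plus
  } else {                       # d1 = d2 != d3 or d1 = d3 != d2 or handled above
    tm$S_minus
  }
  sum(Tx) / (24 * p$M)
}

#' Exact structural coefficient for an isotropic migration pattern
#'
#' The structural coefficient sigma quantifies how group structure and the
#' Moran update shift two-strategy competition under weak selection: strategy
#' A is favoured iff `sigma*a + b > c + sigma*d`. For a population of `N`
#' individuals on `M` circular groups with mutation probability `u`,
#' migration probability `v` and isotropic structure function `f`, the exact
#' value is
#' \deqn{\sigma = \frac{(N-2)\sum_x (3\Psi_1 + 3\Psi_2 - 2\Theta)}
#'                     {N \sum_x (3\Psi_1 - 3\Psi_2)}}
#' without self-interaction; including self-interaction adds `6M(1-alpha1)`
#' to the numerator. `u = 0` is a genuine 0/0 degeneracy (the population is
#' monomorphic without mutation) and raises an error.
#'
#' @inheritParams triplet_probability
#' @param include_self Logical; whether an individual also plays a game with
#'   itself (affects only the `I_AA` count).
#' @return An object of class `sigma_result`: list with `sigma`, `numerator`,
#'   `denominator` (stationary averages up to a common positive factor),
#'   `include_self`, and the inputs.
#' @examples
#' p <- model_params(100, 9, 0.07, 0)
#' sigma_exact(p, range_pattern(9, 1))$sigma  # (N-2)/N at v = 0
#' @export
sigma_exact <- function(p, pat, include_self = FALSE) {
  stopifnot(inherits(p, "model_params"))
  check_u_positive(p)
  tm <- sigma_terms(p, pat)
  num <- (p$N - 2) * sum(tm$S_plus)
  if (include_self) num <- num + 6 * p$M * (1 - tm$alpha1)
  den <- p$N * sum(tm$S_minus)
  new_sigma_result(num / den, num, den, include_self, p, pat$name)
}

check_u_positive <- function(p) {
  if (p$u <= 0)
    stop(paste("sigma is a 0/0 at u = 0: without mutation the stationary",
               "distribution is monomorphic and both averages vanish"),
         call. = FALSE)
  if (p$u > 1) stop("u must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

new_sigma_result <- function(sigma, num, den, include_self, p, pattern) {
  structure(list(sigma = sigma, numerator = num, denominator = den,
                 include_self = include_self,
                 N = p$N, M = p$M, u = p$u, v = p$v, pattern = pattern),
            class = "sigma_result")
}

#' @export
print.sigma_result <- function(x, ...) {
  cat(sprintf("Structural coefficient sigma = %.12g\n", x$sigma))
  cat(sprintf("  N = %d, M = %d, u = %g, v = %g, pattern = %s, self-interaction %s\n",
              x$N, x$M, x$u, x$v, x$pattern,
              if (isTRUE(x$include_self)) "included" else "excluded"))
  cat(sprintf("  numerator <I_AA N_B>_0 ~ %.12g, denominator <I_AB N_B>_0 ~ %.12g\n",
              x$numerator, x$denominator))
  invisible(x)
}

#' Closed-form structural coefficient under global migration
#'
#' Specializes the exact coefficient (self-interaction included) to global
#' migration, where the structure function is `1` at `x = M` and `-1/(M-1)`
#' elsewhere, giving
#' \deqn{\sigma_{ac} = \frac{(N-2)\left[3(1-\alpha_1) + (M-1)(3\alpha_2 +
#'   3\alpha_3 - 2\tau_1\alpha_1 - 2\tau_2\alpha_2 - 2\tau_3\alpha_3)\right]
#'   + 6M(1-\alpha_1)}{3N\left[1-\alpha_1+(M-1)(\alpha_2-\alpha_3)\right]}}
#' with the coefficients of [global_coefficients()].
#'
#' @param p A [model_params()] object with `M >= 2` and `u > 0`.
#' @return A `sigma_result` (self-interaction included).
#' @examples
#' sigma_global_closed(model_params(100, 19, 0.07, 0.1))$sigma
#' @export
sigma_global_closed <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$M < 2) stop("global migration needs M >= 2", call. = FALSE)
  check_u_positive(p)
  co <- global_coefficients(p)
  num <- (p$N - 2) *
    (3 * (1 - co$alpha1) +
       (p$M - 1) * (3 * co$alpha2 + 3 * co$alpha3 -
                      2 * co$tau1 * co$alpha1 -
                      2 * co$tau2 * co$alpha2 -
                      2 * co$tau3 * co$alpha3)) +
    6 * p$M * (1 - co$alpha1)
  den <- 3 * p$N * (1 - co$alpha1 + (p$M - 1) * (co$alpha2 - co$alpha3))
  new_sigma_result(num / den, num, den, TRUE, p, "global")
}

#' Large-population approximation of sigma under global migration
#'
#' The approximate structural coefficient (self-interaction included),
#' derived for large populations with coalescence times treated as
#' exponential and mutation/migration counts along a lineage as Poisson, as a
#' rational function of the group number `M` and the scaled rates `mu = N*u`,
#' `nu = N*v`. At `M = 1` both correction terms vanish and the value is 1.
#'
#' @param p A [model_params()] object.
#' @return The approximate sigma (a number).
#' @examples
#' sigma_approx(model_params(1000, 9, 0.001, 0.001))
#' @export
sigma_approx <- function(p) {
  stopifnot(inherits(p, "model_params"))
  M <- p$M; mu <- p$mu; nu <- p$nu
  den1 <- (3 + M + mu + M * mu) * (-3 + 3 * M - mu + M * mu + M * nu)
  den2 <- (3 + M + mu + M * mu) *
    (1 - 2 * M + M^2 + mu - 2 * M * mu + M^2 * mu - 2 * nu + 2 * M * nu -
       mu * nu + M * mu * nu + M * nu^2)
  num1 <- 2 * (3 - 6 * M + 3 * M^2 + mu - 2 * M * mu + M^2 * mu)
  num2 <- 2 * (1 - 3 * M + 3 * M^2 - M^3 + mu - 3 * M * mu + 3 * M^2 * mu -
                 M^3 * mu + M * nu - 2 * M^2 * nu + M^3 * nu + M * mu * nu -
                 2 * M^2 * mu * nu + M^3 * mu * nu)
  if (M == 1) return(1)  # both numerators vanish identically at M = 1
  if (den1 == 0 || den2 == 0)
    stop("approximate sigma is degenerate at these (M, mu, nu): zero denominator",
         call. = FALSE)
  1 + num1 / den1 + num2 / den2
}

#' Tilt of sigma: (sigma - 1)/(sigma + 1)
#'
#' The quantity `(sigma - 1)/(sigma + 1)` (the prisoner's-dilemma critical
#' cost-to-benefit ratio) computed directly as
#' `1 - N*sum_x(3Psi1 - 3Psi2) / sum_x((3N-3)Psi1 - 3Psi2 - (N-2)*Theta)`,
#' which is algebraically identical to transforming
#' `sigma_exact(..., include_self = FALSE)`. It is strictly decreasing in the
#' mutation probability, so sigma is too.
#'
#' @inheritParams sigma_exact
#' @return A number in `(-1, 1)`.
#' @export
sigma_tilt <- function(p, pat) {
  stopifnot(inherits(p, "model_params"))
  check_u_positive(p)
  tm <- sigma_terms(p, pat)
  N <- p$N
  1 - N * sum(tm$S_minus) /
    sum((3 * N - 3) * tm$Psi1 - 3 * tm$Psi2 - (N - 2) * tm$Theta)
}

#' Relative difference of accurate and approximate sigma
#'
#' `|sigma_ac - sigma_ap| / sigma_ac` under global migration, the measure of
#' how large a population must be before the large-population approximation
#' is trustworthy. It shrinks as `N` grows, as `M` shrinks, and as `u` or `v`
#' become small.
#'
#' @param p A [model_params()] object with `M >= 2`, `u > 0`.
#' @return A non-negative number.
#' @examples
#' relative_difference(model_params(1000, 9, 0.001, 0.001))  # < 1%
#' @export
relative_difference <- function(p) {
  ac <- sigma_global_closed(p)$sigma
  abs(ac - sigma_approx(p)) / ac
}

#' Critical cost-to-benefit ratios for cooperation
#'
#' Given a structural coefficient, cooperation is favoured over defection iff
#' `c/b` is below `(sigma - 1)/(sigma + 1)` in the prisoner's dilemma
#' (payoffs `[b-c, -c; b, 0]`) or below `2*sigma/(sigma + 2)` in the
#' snowdrift game (payoffs `[b-c/2, b-c; b, 0]`). Both thresholds increase
#' strictly with sigma: larger sigma gives cooperation more room.
#'
#' @param sigma A positive structural coefficient.
#' @return Named list `pd_ratio`, `sd_ratio`.
#' @examples
#' critical_ratios(1)  # pd 0, sd 2/3
#' @export
critical_ratios <- function(sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  list(pd_ratio = (sigma - 1) / (sigma + 1), sd_ratio = 2 * sigma / (sigma + 2))
}

#' Weak-selection abundance condition
#'
#' Strategy A is more abundant than B on average in the stationary
#' distribution under weak selection iff `sigma*a + b > c + sigma*d`.
#'
#' @param sigma A positive structural coefficient.
#' @param m A [payoff_matrix()].
#' @return Logical.
#' @examples
#' favors_A(2, payoff_matrix(1, 0, 0, 0))  # TRUE
#' @export
favors_A <- function(sigma, m) {
  stopifnot(inherits(m, "payoff_matrix"))
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  sigma * m$a + m$b > m$c + sigma * m$d
}
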