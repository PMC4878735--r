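#' Migration structure functions on the circular group lattice
#'
#' An isotropic migration pattern on `M` groups arranged in a circle is
#' characterized by a structure function `f(x)` for displacements
#' `x = 1, ..., M` (with `x = M` playing the role of displacement 0 under the
#' periodic boundary), satisfying `f(M) = 1`, the symmetry `f(x) = f(M - x)`,
#' and `|f(x)| <= 1`. `f` is the Fourier spectrum of the single-step migration
#' displacement distribution.
#'
#' `global_pattern()` is uniform dispersal to any of the other `M - 1` groups:
#' `f(x) = (1/(M-1)) * sum_{k=1}^{M-1} cos(2*pi*k*x/M)`, which equals 1 at
#' `x = M` and `-1/(M-1)` elsewhere.
#'
#' `range_pattern()` is uniform dispersal over all displacements of circular
#' distance at most `r` (range-`r` migration): `f(x) = (1/r) *
#' sum_{k=1}^{r} cos(2*pi*k*x/M)`, except that for even `M` with \code{r = M/2}
#' the displacement `M/2` is reachable one way only and the global-form sum
#' `(1/(M-1)) * sum_{k=1}^{M-1} cos(2*pi*k*x/M)` applies.
#'
#' The finite cosine sums are evaluated explicitly (via `cospi` for accuracy);
#' the analytic closed form of the global pattern is used as a cross-check in
#' the test-suite, not as the primary path.
#'
#' @param M Number of groups (`M >= 2`).
#' @param r Migration range, an integer in `1..floor(M/2)`.
#' @return An object of class `migration_pattern`: list with `M`, the numeric
#'   vector `f` of length `M` (`f[x]` is `f(x)`), and a descriptive `name`.
#' @examples
#' global_pattern(9)$f     # 1 at x = 9, -1/8 elsewhere
#' range_pattern(9, 1)$f   # nearest-neighbour migration
#' @export
global_pattern <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || M != round(M) || M < 2)
    stop("global migration needs at least two groups (M >= 2)", call. = FALSE)
  M <- as.integer(M)
  f <- vapply(seq_len(M), function(x) {
    k <- seq_len(M - 1L)
    sum(cospi(2 * k * x / M)) / (M - 1)
  }, numeric(1))
  new_migration_pattern(M, f, "global")
}

#' @rdname global_pattern
#' @export
range_pattern <- function(M, r) {
  if (!is.numeric(M) || length(M) != 1L || M != round(M) || M < 2)
    stop("range migration needs at least two groups (M >= 2)", call. = FALSE)
  M <- as.integer(M)
  if (!is.numeric(r) || length(r) != 1L || r != round(r) || r < 1 || r > M %/% 2)
    stop(sprintf("migration range r must lie in 1..floor(M/2) = 1..%d", M %/% 2),
         call. = FALSE)
  r <- as.integer(r)
  if (M %% 2L == 0L && r == M %/% 2L) {
    pat <- global_pattern(M)
    pat$name <- sprintf("range-%d", r)
    return(pat)
  }
  f <- vapply(seq_len(M), function(x) {
    k <- seq_len(r)
    sum(cospi(2 * k * x / M)) / r
  }, numeric(1))
  new_migration_pattern(M, f, sprintf("range-%d", r))
}

#' @rdname global_pattern
#' @details `single_group_pattern()` is the degenerate `M = 1` pattern
#'   (`f = 1` at the single displacement), under which sigma reduces to the
#'   well-mixed value `(N-2)/N`.
#' @export
single_group_pattern <- function() {
  new_migration_pattern(1L, 1, "single-group")
}

new_migration_pattern <- function(M, f, name) {
  stopifnot(length(f) == M)
  if (abs(f[M] - 1) > 1e-12)
    stop("structure function must satisfy f(M) = 1", call. = FALSE)
  if (M > 1L) {
    x <- seq_len(M - 1L)
    if (max(abs(f[x] - f[M - x])) > 1e-12)
      stop("structure function must satisfy f(x) = f(M - x)", call. = FALSE)
  }
  if (any(abs(f) > 1 + 1e-12))
    stop("structure function values must lie in [-1, 1]", call. = FALSE)
  structure(list(M = M, f = f, name = name), class = "migration_pattern")
}

#' @export
print.migration_pattern <- function(x, ...) {
  cat(sprintf("Isotropic migration pattern '%s' on M = %d groups\n", x$name, x$M))
  cat("  f(1..M):", paste(signif(x$f, 6), collapse = " "), "\n")
  invisible(x)
}

#' Structure function of the two-strategy mutation random walk
#'
#' For symmetric mutation between two strategies the mutation random walk on
#' the strategy cycle has structure function `g(x) = 1/2 + cos(pi*x)/2`:
#' `g(2) = 1` (displacement 0 on the 2-cycle), `g(1) = 0`, period 2.
#'
#' @param x Integer displacement(s).
#' @return `g(x)`, vectorized over `x`.
#' @examples
#' mutation_structure(1:2)  # 0 1
#' @export
mutation_structure <- function(x) {
  if (any(x != round(x))) stop("x must be integer-valued", call. = FALSE)
  1 / 2 + cospi(x) / 2
}

#' Coalescent-style kernels of the closed-form sigma
#'
#' The closed forms for the structural coefficient are built from scalar
#' kernels evaluated at a structure-function value `f`:
#' pair kernels
#' \deqn{\Psi_1(f) = \frac{1-v+vf}{1+(N-1)v(1-f)}, \quad
#'       \Psi_2(f) = \frac{(1-u)(1-v+vf)}{1+(N-1)u+(N-1)(1-u)v(1-f)},}
#' triple kernels with common denominator
#' `D = 2 + 2(N-2)u/3 + (N-2)(2-u)v(1-f)/3`
#' \deqn{\Phi_1(f) = \frac{2-u-v+vf}{D}, \quad
#'       \Phi_2(f) = \frac{(1-u)(2-v+vf)}{D}, \quad
#'       \Phi_3(f) = \frac{(2-u)(1-v+vf)}{D},}
#' and the pair strategy-identity coefficient
#' `alpha1 = (1-u)/(1+(N-1)u)`.
#' The kernels are Fourier-coefficient-like: they are bounded by 1 in
#' magnitude (and lie in `[0, 1]` whenever `f >= 0`; at strongly negative
#' `f`, e.g. two groups at high migration, they can be negative), and
#' `Psi2 <= Psi1` wherever the shared numerator `1 - v + v*f` is
#' non-negative, with equality iff `u = 0`. Denominators are bounded below
#' by 1 (pair) and 2 (triple), so plain arithmetic is numerically safe.
#'
#' @param f Structure-function value(s) in `[-1, 1]` (vectorized).
#' @param p A [model_params()] object.
#' @return `pair_kernels`: list with numeric `Psi1`, `Psi2` (same length as
#'   `f`). `triple_kernels`: list with `Phi1`, `Phi2`, `Phi3`.
#'   `mutation_alpha`: the scalar `alpha1`.
#' @examples
#' p <- model_params(100, 9, 0.07, 0.1)
#' pair_kernels(1, p)$Psi1  # 1 at f = 1
#' mutation_alpha(p)
#' @export
pair_kernels <- function(f, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(f < -1 - 1e-12 | f > 1 + 1e-12))
    stop("structure value f must lie in [-1, 1]", call. = FALSE)
  N <- p$N; u <- p$u; v <- p$v
  num <- 1 - v + v * f
  Psi1 <- num / (1 + (N - 1) * v * (1 - f))
  Psi2 <- (1 - u) * num / (1 + (N - 1) * u + (N - 1) * (1 - u) * v * (1 - f))
  list(Psi1 = Psi1, Psi2 = Psi2)
}

#' @rdname pair_kernels
#' @export
triple_kernels <- function(f, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(f < -1 - 1e-12 | f > 1 + 1e-12))
    stop("structure value f must lie in [-1, 1]", call. = FALSE)
  N <- p$N; u <- p$u; v <- p$v
  D <- 2 + 2 * (N - 2) * u / 3 + (N - 2) * (2 - u) * v * (1 - f) / 3
  list(Phi1 = (2 - u - v + v * f) / D,
       Phi2 = (1 - u) * (2 - v + v * f) / D,
       Phi3 = (2 - u) * (1 - v + v * f) / D)
}

#' @rdname pair_kernels
#' @export
mutation_alpha <- function(p) {
  stopifnot(inherits(p, "model_params"))
  (1 - p$u) / (1 + (p$N - 1) * p$u)
}

#' Coefficients of the global-migration closed form
#'
#' The closed form of sigma under global migration is written in terms of six
#' coefficients: `alpha1 = (1-u)/(1+(N-1)u)` and, with the shorthand
#' `V = M*v/(M-1)` and `D = 2 + 2(N-2)u/3 + (N-2)(2-u)V/3`,
#' \deqn{\alpha_2 = \frac{1-V}{1+(N-1)V}, \quad
#'       \alpha_3 = \frac{(1-u)(1-V)}{1+(N-1)u+(N-1)(1-u)V},}
#' \deqn{\tau_1 = \frac{(2-u)(1-V)}{D}, \quad
#'       \tau_2 = \frac{(1-u)(2-V)}{D}, \quad
#'       \tau_3 = \frac{2-u-V}{D}.}
#' These are the pair and triple kernels evaluated at the off-diagonal global
#' structure value `f = -1/(M-1)`: `alpha2 = Psi1`, `alpha3 = Psi2`,
#' `tau1 = Phi3`, `tau2 = Phi2`, `tau3 = Phi1` (note the reversed Phi order).
#'
#' @param p A [model_params()] object with `M >= 2`.
#' @return Named list `alpha1`, `alpha2`, `alpha3`, `tau1`, `tau2`, `tau3`.
#' @examples
#' global_coefficients(model_params(100, 9, 0.07, 0))$alpha2  # 1 at v = 0
#' @export
global_coefficients <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$M < 2) stop("global coefficients need M >= 2", call. = FALSE)
  N <- p$N; M <- p$M; u <- p$u; v <- p$v
  V <- M * v / (M - 1)
  D <- 2 + 2 * (N - 2) * u / 3 + (N - 2) * (2 - u) * V / 3
  list(alpha1 = (1 - u) / (1 + (N - 1) * u),
       alpha2 = (1 - V) / (1 + (N - 1) * V),
       alpha3 = (1 - u) * (1 - V) / (1 + (N - 1) * u + (N - 1) * (1 - u) * V),
       tau1 = (2 - u) * (1 - V) / D,
       tau2 = (1 - u) * (2 - V) / D,
       tau3 = (2 - u - V) / D)
}
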