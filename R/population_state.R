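#' Population configuration of strategies and group memberships
#'
#' A state of the group-structured population: per-individual strategy bits
#' (`1` = A, `0` = B) and group labels in `1..M`.
#'
#' @param strategies Integer vector of 0/1 strategy bits, length `N`.
#' @param groups Integer vector of group labels in `1..M`, same length.
#' @param M Number of groups.
#' @return An object of class `population_state`.
#' @examples
#' population_state(c(1, 1, 0), c(1, 1, 2), M = 2)
#' @export
population_state <- function(strategies, groups, M) {
  if (length(strategies) != length(groups))
    stop("strategies and groups must have the same length", call. = FALSE)
  if (!all(strategies %in% c(0L, 1L)))
    stop("strategies must be 0/1 bits", call. = FALSE)
  M <- as.integer(M)
  groups <- as.integer(groups)
  if (any(groups < 1L) || any(groups > M))
    stop("group labels must lie in 1..M", call. = FALSE)
  structure(list(strategies = as.integer(strategies), groups = groups,
                 N = length(groups), M = M),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state: N = %d individuals over M = %d groups, N_A = %d\n",
              x$N, x$M, sum(x$strategies)))
  print(occupancy(x))
  invisible(x)
}

#' Game and abundance counts of a state
#'
#' For each group `g` with `a_g` A-individuals and `b_g` B-individuals:
#' `I_AA = sum_g a_g*(a_g - 1)` (each unordered A-A pair counted twice; plus
#' `sum_g a_g` self-games when `include_self`), `I_AB = sum_g a_g*b_g`, and
#' the abundances `N_A`, `N_B`.
#'
#' @param st A [population_state()].
#' @param include_self Count an individual's game with itself in `I_AA`?
#' @return Named list `I_AA`, `I_AB`, `N_A`, `N_B` (integers).
#' @examples
#' st <- population_state(c(1, 1, 1, 0, 0), rep(1, 5), M = 1)
#' game_counts(st)  # I_AA = 6, I_AB = 6, N_B = 2
#' @export
game_counts <- function(st, include_self = FALSE) {
  stopifnot(inherits(st, "population_state"))
  occ <- occupancy(st)
  a <- occ$count_A; b <- occ$count_B
  I_AA <- sum(a * (a - 1L)) + if (include_self) sum(a) else 0L
  list(I_AA = as.integer(I_AA), I_AB = as.integer(sum(a * b)),
       N_A = sum(a), N_B = sum(b))
}

#' Per-group occupancy table
#'
#' @param st A [population_state()].
#' @return A data.frame with columns `group`, `count_A`, `count_B`.
#' @export
occupancy <- function(st) {
  stopifnot(inherits(st, "population_state"))
  g <- factor(st$groups, levels = seq_len(st$M))
  data.frame(group = seq_len(st$M),
             count_A = as.integer(tabulate(g[st$strategies == 1L], st$M)),
             count_B = as.integer(tabulate(g[st$strategies == 0L], st$M)))
}

#' Single-group counting identity for a mirrored pair of states
#'
#' With all individuals in one group, the states `(x, y)` and `(y, x)`
#' (A-count, B-count) carry equal stationary weight under neutrality. Summed
#' over the pair, `I_AA*N_B - I_AB*N_B = -2*x*y` and
#' `I_AB*N_B = (x + y)*x*y` (self-interaction excluded). Both the closed
#' forms and direct [game_counts()] aggregation are computed and must agree.
#'
#' @param x,y Non-negative A- and B-counts.
#' @return Named list `diff_sum`, `iab_sum`.
#' @examples
#' single_group_paired(3, 2)  # -12, 30
#' @export
single_group_paired <- function(x, y) {
  if (x < 0 || y < 0 || x != round(x) || y != round(y))
    stop("x and y must be non-negative integers", call. = FALSE)
  closed <- list(diff_sum = -2 * x * y, iab_sum = (x + y) * x * y)
  direct <- c(0, 0)
  for (st in list(c(x, y), c(y, x))) {
    n <- st[1] + st[2]
    if (n == 0) next
    gc <- game_counts(population_state(rep(c(1L, 0L), st), rep(1L, n), M = 1))
    direct <- direct + c(gc$I_AA * gc$N_B - gc$I_AB * gc$N_B, gc$I_AB * gc$N_B)
  }
  stopifnot(direct[1] == closed$diff_sum, direct[2] == closed$iab_sum)
  closed
}

#' Two-group counting identity for a quartet of symmetric states
#'
#' For two groups, a state is `(N_A1, N_B1; N_A2, N_B2)`. The four states
#' `(x-k, y-m; k, m)`, `(y-m, x-k; m, k)`, `(y-k, x-m; k, m)`,
#' `(x-m, y-k; m, k)` — related by swapping strategies and/or groups — carry
#' equal neutral stationary weight. Summed over the quartet,
#' `I_AA*N_B - I_AB*N_B = (k+m)*(x-y)^2 + 2*N*(k-m)^2 - 4*x*y` and
#' `I_AB*N_B = N*(2*x*y - (k+m)*N + 4*k*m)` (self-interaction excluded),
#' where `x + y = N`. At `k = m = 0` this is exactly double the
#' single-group pair identity. Verified against direct [game_counts()]
#' aggregation on every call.
#'
#' @param x,y Total A- and B-counts (`x + y = N`).
#' @param k,m A- and B-counts in group 2.
#' @param N Population size.
#' @return Named list `diff_sum`, `iab_sum`.
#' @examples
#' two_group_quartet(3, 1, 1, 0, 4)  # 0, 8
#' @export
two_group_quartet <- function(x, y, k, m, N) {
  vals <- c(x, y, k, m, N)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("arguments must be non-negative integers", call. = FALSE)
  if (x + y != N)
    stop("x + y must equal N", call. = FALSE)
  if (x - k < 0 || y - m < 0 || y - k < 0 || x - m < 0)
    stop("x-k, y-m, y-k, x-m must all be non-negative", call. = FALSE)
  closed <- list(diff_sum = (k + m) * (x - y)^2 + 2 * N * (k - m)^2 - 4 * x * y,
                 iab_sum = N * (2 * x * y - (k + m) * N + 4 * k * m))
  quartet <- list(c(x - k, y - m, k, m), c(y - m, x - k, m, k),
                  c(y - k, x - m, k, m), c(x - m, y - k, m, k))
  direct <- c(0, 0)
  for (q in quartet) {
    st <- population_state(rep(c(1L, 0L, 1L, 0L), q),
                           rep(c(1L, 1L, 2L, 2L), q), M = 2)
    gc <- game_counts(st)
    direct <- direct + c(gc$I_AA * gc$N_B - gc$I_AB * gc$N_B, gc$I_AB * gc$N_B)
  }
  stopifnot(direct[1] == closed$diff_sum, direct[2] == closed$iab_sum)
  closed
}
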