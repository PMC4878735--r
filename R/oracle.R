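#' Brute-force neutral Markov chain for tiny populations
#'
#' Enumerates the neutral (w = 0) Moran chain for small `(N, M)`, builds its
#' one-event transition matrix, and solves the stationary distribution. This
#' is the ground truth against which every closed form is checked.
#'
#' Two encodings are available. The raw chain has one state per assignment of
#' a (strategy, group) category to each labelled individual, `(2M)^N` states.
#' Because individuals are exchangeable, the vector of category counts is
#' itself a Markov chain (exact lumping); the lumped chain has one state per
#' multiset of size `N` over the `2M` categories and is the default. Both
#' give identical expectations for any count-based observable.
#'
#' Irreducibility requires `u > 0`, and `v > 0` whenever `M >= 2` (at `v = 0`
#' group occupancy is absorbing: a group, once emptied, is never repopulated,
#' so the chain is reducible; the `v = 0` limits are handled analytically by
#' the closed forms instead).
#'
#' @param p A [model_params()] object with small `N`, `M`.
#' @param r Migration range (ignored under `global = TRUE`; irrelevant when
#'   `M = 1`).
#' @param global Use global migration.
#' @param lumped Use the exact count-vector lumping (default) or the raw
#'   labelled chain.
#' @param max_states Refuse to enumerate more raw states than this.
#' @return An object of class `oracle_chain`: `states` (matrix, one row per
#'   state), `P` (row-stochastic transition matrix), `pi` (stationary
#'   probabilities), plus the inputs.
#' @examples
#' ch <- oracle_chain(model_params(3, 2, 0.5, 0.5), r = 1)
#' nrow(ch$P)  # 20 lumped states
#' @export
oracle_chain <- function(p, r = 1L, global = FALSE, lumped = TRUE,
                         max_states = 1e5) {
  stopifnot(inherits(p, "model_params"))
  if (p$u <= 0)
    stop("oracle chain needs u > 0 for irreducibility", call. = FALSE)
  if (p$M >= 2 && p$v <= 0)
    stop(paste("oracle chain is reducible at v = 0 (group occupancy is",
               "absorbing); use the analytic v = 0 limits instead"),
         call. = FALSE)
  n_raw <- (2 * p$M)^p$N
  if (n_raw > max_states)
    stop(sprintf("raw state space (2M)^N = %g exceeds the guard of %g states",
                 n_raw, max_states), call. = FALSE)
  offs <- if (p$M >= 2) migration_offsets(p$M, as.integer(r), global) else integer(0)
  K <- offspring_kernel(p, offs)
  if (lumped) {
    states <- enumerate_compositions(p$N, 2L * p$M)
    P <- lumped_transition_matrix(states, p, K)
  } else {
    states <- enumerate_raw_states(p$N, 2L * p$M)
    P <- raw_transition_matrix(states, p, K)
  }
  pi <- stationary_distribution(P)
  structure(list(states = states, P = P, pi = pi, p = p,
                 r = if (global) NA_integer_ else as.integer(r),
                 global = global, lumped = lumped),
            class = "oracle_chain")
}

#' @export
print.oracle_chain <- function(x, ...) {
  cat(sprintf(
    "Neutral Moran oracle chain: N = %d, M = %d, u = %g, v = %g, %s states (%s)\n",
    x$p$N, x$p$M, x$p$u, x$p$v, nrow(x$P),
    if (x$lumped) "lumped" else "raw"))
  invisible(x)
}

# category index: 1..M are (B, group), M+1..2M are (A, group)
cat_strategy <- function(cat, M) as.integer(cat > M)
cat_group <- function(cat, M) ifelse(cat > M, cat - M, cat)

# K[c_parent, c_offspring]: offspring category distribution given the parent.
offspring_kernel <- function(p, offs) {
  M <- p$M; u <- p$u; v <- p$v
  nc <- 2L * M
  strat_p <- function(sp, so) if (sp == so) 1 - u / 2 else u / 2
  K <- matrix(0, nc, nc)
  for (cp in seq_len(nc)) {
    sp <- cat_strategy(cp, M); gp <- cat_group(cp, M)
    for (so in 0:1) {
      ps <- strat_p(sp, so)
      if (M == 1L) {
        K[cp, so * M + 1L] <- K[cp, so * M + 1L] + ps
      } else {
        K[cp, so * M + gp] <- K[cp, so * M + gp] + ps * (1 - v)
        for (d in offs) {
          gd <- 1L + (gp - 1L + d) %% M
          K[cp, so * M + gd] <- K[cp, so * M + gd] + ps * v / length(offs)
        }
      }
    }
  }
  K
}

# all count vectors of length k summing to n (multisets), one row each
enumerate_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- list()
  for (first in 0:n) {
    rest <- enumerate_compositions(n - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

enumerate_raw_states <- function(n, k) {
  as.matrix(expand.grid(rep(list(seq_len(k)), n)))
}

lumped_transition_matrix <- function(states, p, K) {
  n_states <- nrow(states)
  nc <- ncol(states)
  N <- p$N
  key <- apply(states, 1, paste, collapse = ",")
  index <- stats::setNames(seq_len(n_states), key)
  P <- matrix(0, n_states, n_states)
  for (s in seq_len(n_states)) {
    n <- states[s, ]
    for (c1 in which(n > 0L)) {          # parent category
      w1 <- n[c1] / N
      for (c2 in which(n > 0L)) {        # dying category
        w2 <- n[c2] / N
        for (c3 in which(K[c1, ] > 0)) { # offspring category
          n2 <- n
          n2[c2] <- n2[c2] - 1L
          n2[c3] <- n2[c3] + 1L
          t_idx <- index[[paste(n2, collapse = ",")]]
          P[s, t_idx] <- P[s, t_idx] + w1 * w2 * K[c1, c3]
        }
      }
    }
  }
  P
}

raw_transition_matrix <- function(states, p, K) {
  n_states <- nrow(states)
  N <- p$N
  nc <- 2L * p$M
  # base-(2M) encoding of rows for O(1) lookup
  enc <- function(row) as.integer(sum((row - 1) * nc^(seq_len(N) - 1)) + 1)
  index <- integer(n_states)
  index[vapply(seq_len(n_states), function(i) enc(states[i, ]), integer(1))] <-
    seq_len(n_states)
  P <- matrix(0, n_states, n_states)
  for (s in seq_len(n_states)) {
    st <- states[s, ]
    for (i in seq_len(N)) {        # reproducer
      for (j in seq_len(N)) {      # dier
        for (c3 in which(K[st[i], ] > 0)) {
          st2 <- st
          st2[j] <- c3
          t_idx <- index[enc(st2)]
          P[s, t_idx] <- P[s, t_idx] + K[st[i], c3] / N^2
        }
      }
    }
  }
  P
}

#' Stationary distribution of a finite chain
#'
#' Solves `pi P = pi`, `sum(pi) = 1` by a dense linear solve on the
#' transposed system with a normalization row. Residuals above `1e-12` (or a
#' singular system, as happens for reducible chains) raise an error.
#'
#' @param P A row-stochastic matrix (irreducible).
#' @return The stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  n <- nrow(P)
  if (max(abs(rowSums(P) - 1)) > 1e-12)
    stop("P is not row-stochastic", call. = FALSE)
  A <- t(P) - diag(n)
  A[n, ] <- 1
  rhs <- c(rep(0, n - 1L), 1)
  pi <- tryCatch(solve(A, rhs), error = function(e)
    stop(paste("stationary solve failed (singular system - the chain is",
               "likely reducible, e.g. v = 0 or u = 0):", conditionMessage(e)),
         call. = FALSE))
  if (max(abs(as.vector(pi %*% P) - pi)) > 1e-12)
    stop("stationary residual above 1e-12", call. = FALSE)
  pi
}

# per-state observables from an oracle chain: returns matrix with one row per
# state and named columns
oracle_observables <- function(chain) {
  M <- chain$p$M
  counts <- if (chain$lumped) chain$states else
    t(apply(chain$states, 1, function(row) tabulate(row, 2L * M)))
  b <- counts[, seq_len(M), drop = FALSE]
  a <- counts[, M + seq_len(M), drop = FALSE]
  N_A <- rowSums(a); N_B <- rowSums(b)
  sum_a2 <- rowSums(a^2)
  I_AB <- rowSums(a * b)
  cbind(N_A = N_A, N_B = N_B, sum_a2 = sum_a2,
        I_AA_excl = sum_a2 - N_A, I_AA_incl = sum_a2, I_AB = I_AB)
}

#' Definitional sigma from the stationary distribution
#'
#' `sigma = <I_AA*N_B>_0 / <I_AB*N_B>_0` computed directly as a
#' stationary-weighted sum over all enumerated states — no closed forms
#' involved. This is the independent check of [sigma_exact()].
#'
#' @param chain An [oracle_chain()].
#' @param include_self Include self-games in `I_AA`?
#' @return A `sigma_result`.
#' @examples
#' ch <- oracle_chain(model_params(3, 2, 0.5, 0.5), r = 1)
#' sigma_by_definition(ch)$sigma
#' @export
sigma_by_definition <- function(chain, include_self = FALSE) {
  stopifnot(inherits(chain, "oracle_chain"))
  ob <- oracle_observables(chain)
  iaa <- if (include_self) ob[, "I_AA_incl"] else ob[, "I_AA_excl"]
  num <- sum(chain$pi * iaa * ob[, "N_B"])
  den <- sum(chain$pi * ob[, "I_AB"] * ob[, "N_B"])
  if (den == 0) stop("degenerate: <I_AB*N_B>_0 = 0", call. = FALSE)
  new_sigma_result(num / den, num, den, include_self, chain$p,
                   if (chain$global) "global" else sprintf("range-%d", chain$r))
}

#' Definitional triplet identity probability
#'
#' The stationary probability that a uniformly random ordered triple of
#' distinct individuals has strategies `(d1, d2, d3)` with individuals 2 and
#' 3 co-located, computed by counting triples in every enumerated state. The
#' independent check of [triplet_probability()].
#'
#' @inheritParams sigma_by_definition
#' @param d1,d2,d3 Strategy bits in `{0, 1}`.
#' @return A probability.
#' @export
triplet_probability_by_definition <- function(chain, d1, d2, d3) {
  stopifnot(inherits(chain, "oracle_chain"))
  p <- chain$p
  if (p$N < 3) stop("triplet probabilities need N >= 3", call. = FALSE)
  M <- p$M
  counts <- if (chain$lumped) chain$states else
    t(apply(chain$states, 1, function(row) tabulate(row, 2L * M)))
  per_state <- vapply(seq_len(nrow(counts)), function(s) {
    n <- counts[s, ]
    bg <- n[seq_len(M)]; ag <- n[M + seq_len(M)]
    n2 <- if (d2 == 1) ag else bg
    n3 <- if (d3 == 1) ag else bg
    pairs23 <- sum(n2 * (n3 - as.integer(d2 == d3)))
    tot1 <- if (d1 == 1) sum(ag) else sum(bg)
    pairs23 * (tot1 - as.integer(d1 == d2) - as.integer(d1 == d3))
  }, numeric(1))
  sum(chain$pi * per_state) / (p$N * (p$N - 1) * (p$N - 2))
}

#' Definitional pair probability Pr(s1 = 1, s2 = 0)
#'
#' The stationary probability that of two randomly chosen distinct
#' individuals the first plays A and the second plays B. Its closed form is
#' `(1 - alpha1)/4`, the normalization that makes the self-interaction
#' correction `6M(1 - alpha1)` of the closed-form sigma consistent.
#'
#' @inheritParams sigma_by_definition
#' @return A probability.
#' @export
pair_probability_by_definition <- function(chain) {
  stopifnot(inherits(chain, "oracle_chain"))
  ob <- oracle_observables(chain)
  p <- chain$p
  sum(chain$pi * ob[, "N_A"] * ob[, "N_B"]) / (p$N * (p$N - 1))
}

#' Stationary expectations bridging counts and triplet probabilities
#'
#' Returns the stationary expectations of the unrestricted index sums
#' `sum_{l,i,j} h_i.h_j (1-s_l) s_i s_j = N_B * sum_g a_g^2`,
#' `sum_{l,i} (1-s_l) s_i = N_B * N_A`, and
#' `sum_{l,i,j} h_i.h_j (1-s_l) s_i (1-s_j) = N_B * I_AB`, which connect the
#' game-count averages to the distinct-triple identity probabilities:
#' the first minus the second equals `N(N-1)(N-2) * Pr(0,1,1, coloc)` and the
#' third equals `N^2(N-1) * Pr(0,1,0, coloc)`.
#'
#' @inheritParams sigma_by_definition
#' @return Named list `triple_AA`, `pair_A`, `triple_AB`.
#' @export
bridge_expectations <- function(chain) {
  stopifnot(inherits(chain, "oracle_chain"))
  ob <- oracle_observables(chain)
  list(triple_AA = sum(chain$pi * ob[, "N_B"] * ob[, "sum_a2"]),
       pair_A = sum(chain$pi * ob[, "N_B"] * ob[, "N_A"]),
       triple_AB = sum(chain$pi * ob[, "N_B"] * ob[, "I_AB"]))
}
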