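#' Configuration of a Moran-process simulation
#'
#' The frequency-dependent Moran process on the group-structured population:
#' each generation one individual reproduces with probability proportional to
#' fitness `1 + w * payoff` (uniformly under neutrality, `w = 0`) and one
#' individual, possibly the parent, dies uniformly. The offspring keeps the
#' parent's strategy with probability `1 - u`, otherwise mutates to a uniform
#' strategy (effective switch probability `u/2`); it stays in the parent's
#' group with probability `1 - v`, otherwise migrates uniformly to one of the
#' distinct groups within circular displacement `r` (or to any of the other
#' `M - 1` groups under global migration).
#'
#' @param params A [model_params()] object.
#' @param r Migration range in `1..floor(M/2)`, or `NULL` with
#'   `global = TRUE`.
#' @param global Use global migration instead of a finite range.
#' @param payoff A [payoff_matrix()] (only used when `w > 0`).
#' @param w Selection intensity, `>= 0`.
#' @param include_self Whether payoff includes a self-game.
#' @param generations Number of birth-death events to simulate.
#' @param burn_in Events discarded before averaging (default 5% of
#'   `generations`).
#' @param seed Integer RNG seed; every run is reproducible given the seed.
#' @param snapshot_times Optional increasing generation indices at which to
#'   record per-group occupancy.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params, r = 1L, global = FALSE,
                              payoff = payoff_matrix(0, 0, 0, 0), w = 0,
                              include_self = FALSE,
                              generations = 1e6, burn_in = NULL,
                              seed = 1L, snapshot_times = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(payoff, "payoff_matrix"))
  if (w < 0) stop("selection intensity w must be >= 0", call. = FALSE)
  if (is.null(burn_in)) burn_in <- floor(0.05 * generations)
  if (generations <= burn_in || burn_in < 0)
    stop("need generations > burn_in >= 0", call. = FALSE)
  if (!global) {
    if (params$M < 2 && params$v > 0)
      stop("migration with M = 1 is undefined; use v = 0", call. = FALSE)
    if (params$M >= 2 &&
        (r < 1 || r > params$M %/% 2))
      stop("migration range r must lie in 1..floor(M/2)", call. = FALSE)
  } else if (params$M < 2) {
    stop("global migration needs M >= 2", call. = FALSE)
  }
  structure(list(params = params, r = if (global) NA_integer_ else as.integer(r),
                 global = global, payoff = payoff, w = w,
                 include_self = include_self,
                 generations = as.numeric(generations),
                 burn_in = as.numeric(burn_in), seed = as.integer(seed),
                 snapshot_times = snapshot_times),
            class = "simulation_config")
}

# Distinct reachable displacements (as offsets in 1..M-1) for the migration
# kernel: range r < M/2 reaches 2r groups, r = M/2 (even M) reaches M - 1,
# global reaches M - 1.
migration_offsets <- function(M, r, global) {
  if (global || (M %% 2L == 0L && !is.na(r) && r == M %/% 2L))
    return(seq_len(M - 1L))
  sort(unique(c(seq_len(r), M - seq_len(r))))
}

#' Per-individual total payoffs
#'
#' `p_i` is the sum of payoffs from games with every other member of `i`'s
#' group (plus a self-game when `include_self`).
#'
#' @param st A [population_state()].
#' @param m A [payoff_matrix()].
#' @param include_self Include the self-game?
#' @return Numeric vector of length `N`.
#' @examples
#' st <- population_state(c(1, 1, 1, 0), rep(1, 4), M = 1)
#' payoff_vector(st, payoff_matrix(1, 2, 3, 4))  # A's: 2a + b; B: 3c
#' @export
payoff_vector <- function(st, m, include_self = FALSE) {
  stopifnot(inherits(st, "population_state"), inherits(m, "payoff_matrix"))
  occ <- occupancy(st)
  a <- occ$count_A[st$groups]; b <- occ$count_B[st$groups]
  s <- st$strategies
  p <- ifelse(s == 1L, (a - 1L) * m$a + b * m$b, a * m$c + (b - 1L) * m$d)
  if (include_self) p <- p + ifelse(s == 1L, m$a, m$d)
  p
}

#' One birth-death event of the Moran process
#'
#' Advances the population by one generation. Draws that are not supplied are
#' sampled from R's RNG; any of them can be forced for testing the mechanics
#' (`reproducer`, `dier`, `mutate_to`, `displacement`).
#'
#' @param st A [population_state()].
#' @param cfg A [simulation_config()] (supplies u, v, kernel, payoffs, w).
#' @param reproducer,dier Optional indices forcing the birth/death draws.
#' @param mutate_to Optional forced offspring strategy (0/1), `NA` to force
#'   no mutation.
#' @param displacement Optional forced circular displacement (`0` forces no
#'   migration); must be reachable under the configured kernel.
#' @return List with the new `state` and the realized `reproducer`, `dier`,
#'   `offspring_strategy`, `offspring_group`.
#' @export
step_population <- function(st, cfg, reproducer = NULL, dier = NULL,
                            mutate_to = NULL, displacement = NULL) {
  stopifnot(inherits(st, "population_state"), inherits(cfg, "simulation_config"))
  p <- cfg$params
  N <- st$N
  if (is.null(reproducer)) {
    if (cfg$w == 0) {
      reproducer <- sample.int(N, 1L)
    } else {
      fit <- 1 + cfg$w * payoff_vector(st, cfg$payoff, cfg$include_self)
      if (any(fit < 0))
        stop("negative fitness: selection intensity w too strong for these payoffs",
             call. = FALSE)
      reproducer <- sample.int(N, 1L, prob = fit)
    }
  }
  if (is.null(dier)) dier <- sample.int(N, 1L)
  # offspring strategy: parent's with prob 1-u, else uniform over {A, B}
  if (is.null(mutate_to)) {
    s_off <- if (runif(1) < p$u) sample(c(0L, 1L), 1L) else
      st$strategies[reproducer]
  } else if (is.na(mutate_to)) {
    s_off <- st$strategies[reproducer]
  } else {
    s_off <- as.integer(mutate_to)
  }
  # offspring group: parent's with prob 1-v, else uniform over reachable groups
  offs <- migration_offsets(p$M, cfg$r, cfg$global)
  g_par <- st$groups[reproducer]
  if (is.null(displacement)) {
    g_off <- if (p$v > 0 && runif(1) < p$v) {
      1L + (g_par - 1L + sample(offs, 1L)) %% p$M
    } else g_par
  } else if (displacement == 0) {
    g_off <- g_par
  } else {
    d <- as.integer(displacement) %% p$M
    if (!(d %in% offs)) stop("forced displacement not reachable", call. = FALSE)
    g_off <- 1L + (g_par - 1L + d) %% p$M
  }
  strategies <- st$strategies; groups <- st$groups
  strategies[dier] <- s_off; groups[dier] <- g_off
  list(state = population_state(strategies, groups, p$M),
       reproducer = reproducer, dier = dier,
       offspring_strategy = s_off, offspring_group = g_off)
}

# Uniform random initial state under the config's seed-independent draw
# (callers set the seed).
random_state <- function(p) {
  population_state(sample(c(0L, 1L), p$N, replace = TRUE),
                   sample.int(p$M, p$N, replace = TRUE), p$M)
}

#' Monte-Carlo estimate of sigma under neutrality
#'
#' Runs the neutral (`w = 0`) Moran process and estimates
#' `sigma = <I_AA*N_B>_0 / <I_AB*N_B>_0` by time averages of the two
#' observables after burn-in. The standard error is computed by batch means
#' (100 batches): the batchwise ratio estimates are treated as approximately
#' independent. The hot loop is compiled code driven by R's RNG, so results
#' are reproducible from the seed.
#'
#' @param cfg A [simulation_config()] with `w = 0` and `u > 0`.
#' @param n_batches Number of batches for the batch-means standard error.
#' @return An object of class `sigma_estimate`: `sigma_hat`, `se`,
#'   `n_generations`, `mean_iaa_nb`, `mean_iab_nb`, `include_self`, `seed`.
#' @examples
#' cfg <- simulation_config(model_params(20, 5, 0.1, 0.1), r = 1,
#'                          generations = 2e5, seed = 42)
#' run_neutral_sigma(cfg)
#' @export
run_neutral_sigma <- function(cfg, n_batches = 100L) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$w != 0)
    stop("the sigma estimator is defined under neutrality; set w = 0",
         call. = FALSE)
  p <- cfg$params
  check_u_positive(p)
  set.seed(cfg$seed)
  st <- random_state(p)
  offs <- migration_offsets(p$M, cfg$r, cfg$global)
  res <- cpp_moran_neutral(st$strategies, st$groups, p$M, p$u, p$v,
                           as.integer(offs), cfg$generations, cfg$burn_in,
                           as.integer(n_batches), cfg$include_self)
  ratios <- res$batch_iaa_nb / res$batch_iab_nb
  structure(list(sigma_hat = res$mean_iaa_nb / res$mean_iab_nb,
                 se = stats::sd(ratios) / sqrt(length(ratios)),
                 n_generations = cfg$generations - cfg$burn_in,
                 mean_iaa_nb = res$mean_iaa_nb,
                 mean_iab_nb = res$mean_iab_nb,
                 include_self = cfg$include_self, seed = cfg$seed),
            class = "sigma_estimate")
}

#' @export
print.sigma_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo sigma estimate: %.6f (SE %.6f)\n", x$sigma_hat, x$se))
  cat(sprintf("  %g post-burn-in generations, self-interaction %s, seed %d\n",
              x$n_generations,
              if (isTRUE(x$include_self)) "included" else "excluded", x$seed))
  invisible(x)
}

#' Occupancy trajectories of the Moran process
#'
#' Runs the process and records the per-group strategy occupancy
#' `(count_A, count_B)` at the requested generations. Useful for inspecting
#' the high-frequency steady states: at `v = 0` group occupancy is absorbing
#' (eventually one group holds everyone); at `v = 1` all groups are occupied
#' and each strategy spreads nearly uniformly.
#'
#' @param cfg A [simulation_config()] with non-empty `snapshot_times`.
#' @return A data.frame with columns `generation`, `group`, `count_A`,
#'   `count_B`.
#' @export
run_occupancy <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  times <- sort(unique(as.numeric(cfg$snapshot_times)))
  if (length(times) == 0)
    stop("snapshot_times must be non-empty", call. = FALSE)
  p <- cfg$params
  set.seed(cfg$seed)
  st <- random_state(p)
  offs <- migration_offsets(p$M, cfg$r, cfg$global)
  res <- cpp_moran_occupancy(st$strategies, st$groups, p$M, p$u, p$v,
                             as.integer(offs), times, cfg$w,
                             c(cfg$payoff$a, cfg$payoff$b, cfg$payoff$c,
                               cfg$payoff$d), cfg$include_self)
  data.frame(generation = rep(times, each = p$M),
             group = rep(seq_len(p$M), length(times)),
             count_A = as.integer(res$count_A),
             count_B = as.integer(res$count_B))
}

#' Write occupancy snapshots as TSV
#'
#' @param occ A data.frame from [run_occupancy()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(occ, path) {
  utils::write.table(occ[, c("group", "count_A", "count_B", "generation")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
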