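# shared parameter grids for property-style tests

kernel_grid <- function() {
  expand.grid(f = c(-1, -0.5, -1 / 8, 0, 0.3, 0.9, 1),
              u = c(0, 0.07, 0.5, 1),
              v = c(0, 0.1, 0.6, 1),
              N = c(3, 10, 100))
}

random_params <- function(n, seed = 20160524) {
  set.seed(seed)
  data.frame(N = sample(3:500, n, replace = TRUE),
             M = sample(2:50, n, replace = TRUE),
             u = runif(n, 0.001, 1),
             v = runif(n, 0.001, 1))
}
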