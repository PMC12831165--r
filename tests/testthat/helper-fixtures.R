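# shared fixture builders (everything is generated in code; no data files)

triangle_traj <- function() {
  trajectory(0:10, c(0, 2, 4, 6, 8, 10, 8, 6, 4, 2, 0))
}

toy_structure_file <- function(gap = 4.4, sep = 19.9, ...) {
  path <- tempfile(fileext = ".pdb")
  gen_toy_structure(gap, sep, path = path, ...)
  path
}

# a random smooth pulse trajectory for property-style loops
random_pulse <- function(seed) {
  set.seed(seed)
  tp <- runif(1, 10, 40)
  ta <- tp + runif(1, 30, 80)
  tt <- seq(0, 150, by = runif(1, 0.5, 2))
  amp <- runif(1, 5, 80)
  r <- ta / tp
  a <- log(0.05) / (log(r) - (r - 1))
  s <- tt / tp
  v <- amp * ifelse(s <= 0, 0, exp(a * (log(pmax(s, 1e-12)) - (s - 1))))
  trajectory(tt, v)
}
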