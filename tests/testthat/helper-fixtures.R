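# Shared fixtures: coarse geometries keep unit tests fast; the acceptance
# tests use the study defaults.

coarse_params <- function(seed = 1L, ...) {
  geometry_params(target_edge = 1.8, seed = seed, ...)
}

coarse_config <- function(..., geometry = list()) {
  geometry$target_edge <- geometry$target_edge %||% 1.8
  study_config(..., geometry = geometry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force series/parallel reduction of a ligament spring set
reduce_spring_set <- function(ss) {
  sp <- ss$springs
  per_strand <- vapply(split(sp, sp$strand), function(s) {
    1 / sum(1 / s$k)
  }, numeric(1))
  sum(per_strand)
}

# first-principles Welch test by explicit summation
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1); v2 <- sum((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

random_tensor <- function() stats::runif(6, -5, 5)
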