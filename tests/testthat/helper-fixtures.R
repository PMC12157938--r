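# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small trial set with strong class structure (4 subjects x 7 x 4)
small_trialset <- function() {
  cached("small_ts", generate_trialset(
    n_subjects = 4, n_gestures = 7, n_reps = 4,
    class_separation = 3, seed = 101
  ))
}

# matching null set (identical config, no gesture effect)
null_trialset <- function() {
  cached("null_ts", generate_trialset(
    n_subjects = 4, n_gestures = 7, n_reps = 4,
    class_separation = 0, seed = 101
  ))
}

small_bandpower <- function() {
  cached("small_bp", extract_features(small_trialset(), variant = "bandpower"))
}

null_bandpower <- function() {
  cached("null_bp", extract_features(null_trialset(), variant = "bandpower"))
}

# seeded permutation without touching the caller's RNG stream
with_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(x)
}

# independent brute-force oracle: exact two-sided signed-rank p by full
# enumeration of the 2^n sign patterns (n <= 12 or so)
enum_wilcoxon_p <- function(a, b, alternative = "two.sided") {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_le, p_ge))
  )
}
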