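# Internal helpers shared across modules.

#' @importFrom stats rnorm median fft sd var predict plogis rbinom runif
#' @importFrom utils write.csv read.csv head
NULL

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate code with a private RNG stream: the global .Random.seed is
# saved/restored so generators never leak state into the caller's session.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# 1/f^alpha noise by spectral shaping of white Gaussian noise,
# normalized to unit standard deviation (zero mean by construction: DC removed).
pink_noise <- function(n, alpha = 1) {
  stopifnot(n >= 2)
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)              # symmetric frequency index
  scale <- ifelse(f == 0, 0, 1 / f^(alpha / 2))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

# phase unwrapping (jump threshold pi), same convention as MATLAB unwrap
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  dp <- diff(p)
  dmod <- (dp + pi) %% (2 * pi) - pi
  dmod[dmod == -pi & dp > 0] <- pi
  p + c(0, cumsum(dmod - dp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
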