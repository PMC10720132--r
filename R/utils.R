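# Internal helpers shared across modules.

# Multiplicative log-normal noise with unit mean and coefficient of
# variation `cv`; length-n vector of factors. cv = 0 returns exact ones so
# noiseless runs are bit-reproducible.
lognormal_noise <- function(n, cv) {
  if (cv < 0) abort("`noise_cv` must be >= 0.", class = "coopcell_error_param")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "coopcell_error_param")
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be %s.", name, if (strict) "> 0" else ">= 0"),
          class = "coopcell_error_param")
  }
  invisible(x)
}

# scoped seed: set the RNG state for a reproducible block without
# clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Toroidal shift of a matrix by (di, dj); used by the lattice models.
mat_shift <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- ((seq_len(n1) - 1 - di) %% n1) + 1
  j <- ((seq_len(n2) - 1 - dj) %% n2) + 1
  m[i, j, drop = FALSE]
}
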