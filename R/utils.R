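# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a finite scalar")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

# Deterministic per-item child seed; stays below 2^31 - 1.
# The product is at most ~1e14, exactly representable in a double.
childSeed <- function(seed, k) {
  v <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k)
  as.integer(v %% 2147483647)
}

stopIf <- function(cond, ...) if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)

# Truncated-normal draw by rejection; bounds are guaranteed to bracket mean.
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# Stable fingerprint of numeric content without external digest packages.
contentFingerprint <- function(...) {
  txt <- paste(vapply(list(...), function(x)
    paste(format(x, digits = 12), collapse = ","), character(1)),
    collapse = "|")
  # FNV-1a over the serialized text
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
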