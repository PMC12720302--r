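#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Stable 31-bit string/integer hash used to derive stage and subject seeds.
# Polynomial rolling hash over UTF-8 bytes, modulus 2^31 - 1; pure integer
# arithmetic in doubles (exact below 2^53) so it is identical across platforms.
hash31 <- function(...) {
  parts <- vapply(list(...), function(p) paste0(as.character(p), collapse = ","),
                  character(1))
  key <- paste(parts, collapse = "|")
  bytes <- as.integer(charToRaw(key))
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Derive a reproducible child seed from a master seed
#'
#' Stage and per-subject seeds are stable hashes of the master seed and a
#' label, so toggling one pipeline stage never shifts another stage's
#' random stream, and per-subject streams do not depend on cohort size.
#'
#' @param master Integer master seed.
#' @param ... Labels (character or numeric) identifying the consumer.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "simulate")
#' derive_seed(42, "subject", 1, 17)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  hash31(format(as.integer(master)), ...)
}

# Run code with a temporary RNG state; restores (or removes) .Random.seed.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Undefined-statistic sentinel policy: undefined values (CV at zero mean,
# entropy of silence, ...) are NA_real_ carriers plus a classed warning so
# callers can log them; they are excluded from aggregation means, never
# silently coerced to zero.
sentinel <- function(feature, reason) {
  warn(
    sprintf("feature '%s' undefined: %s; reported as sentinel (NA)", feature, reason),
    class = "neurodep_sentinel"
  )
  NA_real_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
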