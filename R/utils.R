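#' @keywords internal
"_PACKAGE"

# Argument-checking helpers. All user-facing generators and operators validate
# through these so error classes are uniform across modules.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("cardiopipe_invalid_argument", "error")))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop_invalid(name, " must be an integer >= ", min, " (got ", deparse(x), ")")
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi ||
      (hi_open && x >= hi))
    stop_invalid(name, " must lie in [", lo, ", ", hi, if (hi_open) ")" else "]")
  as.numeric(x)
}

# Evaluate `expr` under a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards, so every generator is a pure function of its
# arguments. Mixing in an offset keeps sub-stage seeds distinct but derived
# from one global seed.
with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stage label, staying below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480000)
}

#' Min-max rescale a vector to [0, 1], mapping a degenerate range to 0
#' @noRd
rescale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}
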