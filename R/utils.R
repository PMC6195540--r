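# Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so simulators are pure in (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

# Length of the maximal leading run of `base` in each string.
leading_run <- function(x, base = "T") {
  m <- regexpr(paste0("^", base, "+"), x)
  len <- attr(m, "match.length")
  len[m < 0L] <- 0L
  as.integer(len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
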