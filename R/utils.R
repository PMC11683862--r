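# Internal helpers shared across modules.

# round() in R rounds half to even; split sizes need a platform-stable
# half-away-from-zero rule.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lfer <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    stop_lfer(what, " must be finite numeric, got: ",
              paste(utils::head(x, 5), collapse = ", "))
  }
  invisible(x)
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a per-stage substream seed from a global seed so that adding a
# stage never perturbs the draws of earlier stages. The stage label is
# folded with a polynomial rolling hash (order-sensitive, so "rep12" and
# "rep21" land in different streams); the result stays below 2^31.
substream_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 99991
  (as.integer(seed) %% 21000L) * 100000L + as.integer(h)
}
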