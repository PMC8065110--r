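# Shared internal helpers.

# Mean Earth radius (m); all great-circle arithmetic in the package uses a
# spherical Earth with this radius so distances, the map projection and the
# speed filter are mutually consistent.
BT_EARTH_RADIUS <- 6371008.8

# Metres per degree of arc on the package sphere.
BT_M_PER_DEG <- BT_EARTH_RADIUS * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. seed = NULL runs in the ambient RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic stream of sub-seeds below 2^31 derived from a master seed,
# so pipeline stages draw from independent, reproducible streams.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k)
}

stop_bt <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop_bt(msg)
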