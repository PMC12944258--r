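#' Convert a treadmill belt speed from km/h to m/s
#'
#' The package works internally in SI units (metres, seconds). Belt speeds
#' are conventionally reported in km/h; the conversion factor is exactly
#' 1/3.6.
#'
#' @param speed_kmh Numeric vector of speeds in km/h.
#' @return Speeds in m/s.
#' @examples
#' kmh_to_ms(3.0)  # 0.8333...
#' @export
kmh_to_ms <- function(speed_kmh) {
  speed_kmh / 3.6
}

# Run `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation helpers do not perturb the
# global stream.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-trial RNG seed from (base seed, participant, speed index).
# Kept well below 2^31 to stay in integer range.
trial_seed <- function(seed, participant, speed_idx) {
  s <- (abs(as.numeric(seed)) %% 100000) * 20011 +
    as.numeric(participant) * 211 + as.numeric(speed_idx) * 17
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
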