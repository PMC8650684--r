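#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the session RNG.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

#' 32-bit FNV-1a string hash
#'
#' Deterministic, platform-independent hash used for substructure identifiers
#' and fingerprint bit assignment. Returns a non-negative double < 2^32.
#' @noRd
fnv1a <- function(x) {
  prime <- 16777619
  vapply(x, function(s) {
    bytes <- utf8ToInt(enc2utf8(s))
    h <- 2166136261
    for (b in bytes) {
      # xor touches only the low byte, so do it there and keep the rest
      lo <- h %% 256
      h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
      # 32-bit modular multiply in doubles without losing precision:
      # split h into 16-bit halves (each product stays below 2^53)
      hi <- h %/% 65536
      lo <- h %% 65536
      h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

nm_to_angstrom <- function(x) x * 10

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
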