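# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible substream seed from a root seed and a key
#'
#' Maps a root seed plus a string key to a new 31-bit seed
#' deterministically. Each assay generator, bootstrap run and simulation
#' replicate draws from its own derived substream, so adding one component
#' (a new key) never perturbs the draws of the others.
#'
#' @param seed Root integer seed.
#' @param key A single string naming the substream.
#' @return An integer seed in `[0, 2^31)`.
#' @examples
#' derive_seed(1, "cafe/TH")
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.character(key), length(key) == 1L)
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1000003 * 1000003 + h) %% 2147483647)
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_invalid("`", name, "` = ", format(x), " is outside its valid range")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_invalid("`", name, "` must be an integer >= ", min)
  }
  invisible(as.integer(x))
}
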