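# Derived seeds for chunked / multi-stage sampling.
# Documented contract: stream k of a run rooted at `seed` uses
# (seed + 1000003 * k) mod (2^31 - 1).  Keeps every derived seed a valid
# 32-bit integer and makes chunked execution scheduler-independent.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 1000003 * as.double(k)) %% 2147483647)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

check_prob <- function(x, name, open_upper = TRUE) {
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x <= 0 || !hi_ok)
    stop(sprintf("'%s' must be a probability in (0, %s)", name,
                 if (open_upper) "1" else "1]"), call. = FALSE)
  as.numeric(x)
}
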