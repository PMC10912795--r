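#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

stop_lfpdbs <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "lfpdbs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_scalar_num <- function(x, name, lo = -Inf, hi = Inf,
                             open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_lfpdbs(sprintf("`%s` must be a single finite number", name),
                "lfpdbs_validation_error")
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop_lfpdbs(sprintf("`%s` = %g outside allowed range", name, x),
                "lfpdbs_validation_error")
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring prior RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-component substream seed derived from one global seed.
# Kept strictly below 2^31 so it is always a valid R integer.
substream_seed <- function(seed, stream) {
  seed <- as.double(seed)
  stream <- as.double(stream)
  as.integer((seed * 48271 + stream * 9973 + 12345) %% 2147483647)
}

# Half-open interval membership [lo, hi)
in_interval <- function(t, lo, hi) t >= lo & t < hi

# Merge overlapping/contiguous half-open intervals given as a 2-column matrix.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(numeric(0), ncol = 2L))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    k <- nrow(out)
    if (iv[i, 1L] <= out[k, 2L]) {
      out[k, 2L] <- max(out[k, 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}
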