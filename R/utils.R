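# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# row-wise median over a matrix, NA-omitting; all-NA rows -> NA.
# Complete rows take a vectorized path (one sort keyed by row index);
# rows with gaps fall back to a per-row median.
row_medians <- function(m) {
  r <- nrow(m)
  cc <- ncol(m)
  if (r == 0L || cc == 0L) return(rep(NA_real_, r))
  n_na <- rowSums(is.na(m))
  out <- rep(NA_real_, r)
  comp <- n_na == 0L
  if (any(comp)) {
    mc <- m[comp, , drop = FALSE]
    o <- matrix(mc[order(as.vector(row(mc)), as.vector(mc))],
                ncol = cc, byrow = TRUE)
    h <- cc %/% 2L
    out[comp] <- if (cc %% 2L == 1L) o[, h + 1L] else (o[, h] + o[, h + 1L]) / 2
  }
  part <- which(!comp & n_na < cc)
  if (length(part)) {
    out[part] <- apply(m[part, , drop = FALSE], 1L, function(v)
      stats::median(v[!is.na(v)]))
  }
  out
}

stop_mismatch <- function(a, b, what) {
  if (!identical(dim(a), dim(b))) {
    stop(what, ": grids do not share dimensions (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")", call. = FALSE)
  }
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)
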