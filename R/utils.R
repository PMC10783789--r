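# Internal utilities: seed plumbing, assertions, small numeric helpers.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so that
#' seeded package functions do not disturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed derived from a master seed and integer offsets.
# Keeps values in [1, 2^31 - 2] so they remain valid 32-bit R seeds.
child_seed <- function(seed, ...) {
  offs <- c(...)
  v <- as.double(seed) %% 2147483647
  for (k in offs) v <- (v * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(v %% 2147483645 + 1)
}

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

# seconds -> frames, rounding to nearest integer (package-wide convention)
sec_to_frames <- function(s, frame_rate) as.integer(round(s * frame_rate))

# contiguous temporal fold index sets over 1..n
make_folds <- function(n, folds = 10) {
  stop_if_not(folds >= 2, "need at least 2 folds")
  stop_if_not(n >= folds, "fewer frames (", n, ") than folds (", folds, ")")
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(folds), function(f) seq.int(starts[f], ends[f]))
}

# Fit-on-train standardizer (columns = features). Constant columns get sd 1.
fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2, std$mean, "-"), 2, std$sd, "/")
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

# min-max scale a vector to [0, 1]; NULL when the range is zero
scale_minmax <- function(x) {
  r <- range(x)
  if (!all(is.finite(r)) || r[1] == r[2]) return(NULL)
  (x - r[1]) / (r[2] - r[1])
}
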