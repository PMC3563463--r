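# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Reflect-pad a matrix by `k` pixels on every side.
pad_reflect <- function(x, k) {
  if (k == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (k >= nr || k >= nc) stop("padding exceeds image size")
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  x[ri, ci, drop = FALSE]
}

# 2D linear filtering (correlation with the kernel as laid out in [row, col]
# space) with reflected boundary handling. Kernel must be odd-sized.
filter_reflect <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  k <- max(kr, kc) %/% 2L
  kern <- matrix(0, 2L * k + 1L, 2L * k + 1L)
  r0 <- k + 1L - kr %/% 2L; c0 <- k + 1L - kc %/% 2L
  kern[seq_len(kr) + r0 - 1L, seq_len(kc) + c0 - 1L] <- kernel
  # filter2 convolves (flips the kernel); rotate 180 degrees so this
  # function correlates with the mask exactly as laid out
  kern <- kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern))), drop = FALSE]
  xp <- pad_reflect(x, k)
  out <- EBImage::filter2(xp, kern, boundary = "circular")
  out[seq_len(nrow(x)) + k, seq_len(ncol(x)) + k, drop = FALSE]
}

# Local max / min over a (2k+1)^2 window via shifted comparisons,
# replicate-padded at the borders.
local_extreme <- function(x, k, fun = pmax) {
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (dr in -k:k) for (dc in -k:k) {
    if (dr == 0L && dc == 0L) next
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    out <- fun(out, x[ri, ci, drop = FALSE])
  }
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_odd_window <- function(w) is.numeric(w) && length(w) == 1L && w >= 3 && (w %% 2L == 1L)
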