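# internal helpers

# wrap angles into (-pi, pi]
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

# node index on the row-major grid used by the solver (1-based)
node_index <- function(row, col, nx) (row - 1L) * nx + col

# reshape one movie column (length nx*ny, row-major) into an ny x nx matrix
# indexed [row, col]
as_frame <- function(vcol, nx, ny) t(matrix(vcol, nrow = nx, ncol = ny))

frame_to_col <- function(m) as.vector(t(m))

# column-chunked FFT of a (nt x nnode) matrix; returns Mod^2 or complex
chunked_mvfft <- function(x, chunk = 256L, inverse = FALSE) {
  n <- ncol(x)
  out <- matrix(0 + 0i, nrow = nrow(x), ncol = n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[, i:j] <- stats::mvfft(x[, i:j, drop = FALSE], inverse = inverse)
    i <- j + 1L
  }
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
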