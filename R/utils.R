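# Internal helpers shared across modules.

.kB <- 1.380649e-23  # Boltzmann constant, J/K (exact, SI 2019)

#' Package logging
#'
#' Lightweight leveled logger. Messages are emitted with `message()` and can be
#' silenced with `options(specklerheo.verbose = FALSE)`. Seeded operations log
#' their seed at INFO level so any run can be reproduced.
#'
#' @param level one of "INFO", "WARN", "DEBUG"
#' @param ... pieces pasted into the log line
#' @return invisibly, the formatted line
#' @keywords internal
sr_log <- function(level = "INFO", ...) {
  line <- paste0("[", level, "] ", paste0(..., collapse = ""))
  if (isTRUE(getOption("specklerheo.verbose", TRUE))) message(line)
  invisible(line)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    sr_log("INFO", "seed = ", seed)
  }
  force(expr)
}

# Centred moving average with symmetrically shrinking windows at the edges.
moving_average <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n <= 2L) return(x)
  half <- (width - 1L) %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

# Rolling least-squares slope of y vs x over a (2h+1)-point centred window,
# with symmetric shrinkage at the edges (minimum 2 points, one-sided at the
# very ends). Returns list(slope, edge) where edge flags shrunk windows.
rolling_slope <- function(x, y, width) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  slope <- numeric(n)
  edge <- logical(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    if (h < 1L) {                       # one-sided 2-point fallback at ends
      j <- if (i == 1L) c(1L, 2L) else c(n - 1L, n)
      slope[i] <- (y[j[2L]] - y[j[1L]]) / (x[j[2L]] - x[j[1L]])
      edge[i] <- TRUE
    } else {
      idx <- (i - h):(i + h)
      xm <- x[idx] - mean(x[idx])
      slope[i] <- sum(xm * y[idx]) / sum(xm^2)
      edge[i] <- h < half
    }
  }
  list(slope = slope, edge = edge)
}

# Roman numeral for regime labels (I..XX is plenty).
roman <- function(i) as.character(utils::as.roman(i))

# Longest run of TRUE; returns a logical vector keeping only that run.
longest_true_run <- function(v) {
  if (!any(v)) return(v & FALSE)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  out <- rep(FALSE, length(v))
  out[starts[best]:ends[best]] <- TRUE
  out
}

stop_sr <- function(...) stop(paste0(...), call. = FALSE)
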