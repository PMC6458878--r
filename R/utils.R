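# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# 10*log10 with a floor to keep -Inf out of downstream arithmetic
db <- function(p, floor = 1e-30) 10 * log10(pmax(p, floor))

undb <- function(x) 10^(x / 10)

# log-then-average PSD estimates carry the chi^2_2 log-mean bias:
# E[10*log10(P_hat)] = 10*log10(P) - 10*log10(e)*gamma  (gamma = 0.5772...)
LOG_PSD_BIAS_DB <- 10 * log10(exp(1)) * 0.57721566490153286

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# derive a stream of reproducible child seeds from one master seed
child_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# truncated-normal draws by rejection; degenerates cleanly for sd = 0
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower <= upper)
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal: mean outside [lower, upper]")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

round_to_grid <- function(x, step = 0.5) round(x / step) * step

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
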