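`%||%` <- function(a, b) if (is.null(a)) b else a

## cumulative trapezoidal integral of y over x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

## wrap angles into (-pi, pi]
wrap_pi <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

## evaluate code with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

## scalar-or-function parameter evaluated at arc positions s
eval_field <- function(f, s) {
  if (is.function(f)) f(s) else rep_len(f, length(s))
}

stop_flagwave <- function(msg, class) {
  stop(structure(class = c(class, "flagwave_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
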