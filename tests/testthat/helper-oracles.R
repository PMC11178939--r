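## Independent reference implementations used as test oracles. These stay
## deliberately naive and separate from the package code paths they check.

## circle through three points (closed form), used to initialize the
## geometric fit independently of the Kasa path
circle_through_3 <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy)
}

## brute-force geometric least-squares circle: direct minimization of
## sum((||p - c|| - r)^2) from a 3-point closed-form start
geom_circle_fit <- function(x, y) {
  n <- length(x)
  ctr <- circle_through_3(c(x[1], y[1]),
                          c(x[ceiling(n / 2)], y[ceiling(n / 2)]),
                          c(x[n], y[n]))
  r0 <- mean(sqrt((x - ctr[1])^2 + (y - ctr[2])^2))
  obj <- function(p) sum((sqrt((x - p[1])^2 + (y - p[2])^2) - p[3])^2)
  o <- stats::optim(c(ctr, r0), obj, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  list(center = o$par[1:2], r = o$par[3], value = o$value)
}

## literal step-down Holm adjustment (loop form)
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, min(1, (m - i + 1) * ps[i]))
    adj[i] <- run
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## dense noiseless circle-arc trace of radius R spanning `span` radians
arc_trace <- function(R, span = 1.5, n = 1000, phase = 0, ccw = TRUE) {
  ang <- phase + (if (ccw) 1 else -1) * seq(0, span, length.out = n)
  cbind(R * cos(ang), R * sin(ang))
}
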