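# Shared fixtures and independent oracles, built in code at test time.

# A uniform field with optional square particles stamped in.
# squares: list of list(r, c, side, level)
make_field <- function(nr = 64, nc = 64, background = 200, squares = list(),
                       pixel_area = 0.25) {
  m <- matrix(background, nr, nc)
  for (s in squares) {
    m[s$r:(s$r + s$side - 1L), s$c:(s$c + s$side - 1L)] <- s$level
  }
  micrograph_field(m, pixel_area)
}

# Brute-force convex-hull membership by Caratheodory: a point is in the
# hull of S iff it lies in some triangle (or segment) of points of S.
# Independent of the chull()-based implementation path.
brute_in_hull <- function(p, S, tol = 1e-9) {
  n <- nrow(S)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- S[i, ]; b <- S[j, ]; cc <- S[k, ]
    d <- (b[2] - cc[2]) * (a[1] - cc[1]) + (cc[1] - b[1]) * (a[2] - cc[2])
    if (abs(d) < tol) next
    l1 <- ((b[2] - cc[2]) * (p[1] - cc[1]) + (cc[1] - b[1]) * (p[2] - cc[2])) / d
    l2 <- ((cc[2] - a[2]) * (p[1] - cc[1]) + (a[1] - cc[1]) * (p[2] - cc[2])) / d
    l3 <- 1 - l1 - l2
    if (l1 >= -tol && l2 >= -tol && l3 >= -tol) return(TRUE)
  }
  # fall back to segments for degenerate point sets
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- S[i, ]; b <- S[j, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cross) > tol) next
    t1 <- sum((p - a) * (b - a)) / max(sum((b - a)^2), tol)
    if (t1 >= -tol && t1 <= 1 + tol) return(TRUE)
  }
  FALSE
}

# Independently coded CCsurf arithmetic: same quantity, different
# computation route (log-domain product/quotient).
ccsurf_oracle <- function(P, Sp, Sr, D, W, Ss) {
  ifelse(P == 0, 0,
         exp(log(P) + log(Sp) + log(Sr) - log(D) - log(W) - log(Ss)))
}

# Three-point age model used across chronology tests.
three_point_model <- function() {
  build_age_model(data.frame(depth = c(100, 200, 300), age = c(10, 20, 26)))
}
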