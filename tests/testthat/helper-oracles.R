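# Independent oracles used across the suite. Each reimplements a quantity by
# brute force / direct definition, never by calling the package's own path.

# Gini mean difference: O(n^2) over all unordered pairs
gmd_brute <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) s <- s + abs(x[i] - x[j])
  }
  2 * s / (n * (n - 1))
}

# two-sample KS D: explicit sup over all pooled breakpoints
ks_brute <- function(x, y) {
  br <- sort(unique(c(x, y)))
  f1 <- vapply(br, function(b) mean(x <= b), numeric(1))
  f2 <- vapply(br, function(b) mean(y <= b), numeric(1))
  max(abs(f1 - f2))
}

# exact dip via linear programming: for every placement of the mode between
# adjacent distinct order statistics, minimise the sup-distance t subject to
# band, monotonicity and convex-then-concave shape constraints, using
# boot::simplex ('>=' rows must go through A2/b2)
dip_lp_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  ux <- unique(x)
  m <- length(ux)
  if (m == 1) {
    return(0.5)
  }
  cnt <- as.vector(table(match(x, ux)))
  b <- cumsum(cnt) / n
  a <- c(0, b[-m])
  v <- ux
  nv <- m + 1 # g_1..g_m, t
  best <- Inf
  for (s in 0:m) {
    A1 <- NULL
    b1 <- NULL
    A2 <- NULL
    b2 <- NULL
    add <- function(row, rhs) {
      A1 <<- rbind(A1, row)
      b1 <<- c(b1, rhs)
    }
    addge <- function(row, rhs) {
      A2 <<- rbind(A2, row)
      b2 <<- c(b2, rhs)
    }
    for (i in 1:m) {
      r <- rep(0, nv)
      r[i] <- 1
      r[nv] <- -1
      add(r, a[i]) # g_i - t <= a_i
      r <- rep(0, nv)
      r[i] <- 1
      r[nv] <- 1
      addge(r, b[i]) # g_i + t >= b_i
    }
    for (i in seq_len(m - 1)) {
      r <- rep(0, nv)
      r[i] <- 1
      r[i + 1] <- -1
      add(r, 0) # monotone
    }
    r <- rep(0, nv)
    r[m] <- 1
    add(r, 1) # g_m <= 1
    if (s >= 3) {
      for (i in 1:(s - 2)) {
        d1 <- v[i + 1] - v[i]
        d2 <- v[i + 2] - v[i + 1]
        r <- rep(0, nv)
        r[i] <- -d2
        r[i + 1] <- d1 + d2
        r[i + 2] <- -d1
        add(r, 0) # convex triples left of the mode
      }
    }
    if (m - s >= 3) {
      for (i in (s + 1):(m - 2)) {
        d1 <- v[i + 1] - v[i]
        d2 <- v[i + 2] - v[i + 1]
        r <- rep(0, nv)
        r[i] <- d2
        r[i + 1] <- -(d1 + d2)
        r[i + 2] <- d1
        add(r, 0) # concave triples right of the mode
      }
    }
    sol <- boot::simplex(
      a = c(rep(0, m), 1), A1 = A1, b1 = b1,
      A2 = A2, b2 = b2, maxi = FALSE
    )
    if (sol$solved >= 0) best <- min(best, sol$value)
  }
  best
}

# numerical moments of a dist_spec by integrating the density
moments_numeric <- function(spec) {
  p <- spec$params
  dens <- function(x) {
    switch(spec$family,
      normal = dnorm(x, p$mean, p$sd),
      lognormal = dlnorm(x, p$meanlog, p$sdlog),
      weibull = dweibull(x, p$shape, p$scale),
      beta = dbeta(x, p$shape1, p$shape2)
    )
  }
  lims <- switch(spec$family,
    normal = c(-Inf, Inf),
    lognormal = c(0, Inf),
    weibull = c(0, Inf),
    beta = c(0, 1)
  )
  raw <- function(k) {
    stats::integrate(function(x) x^k * dens(x), lims[1], lims[2],
      rel.tol = 1e-10, abs.tol = 1e-12
    )$value
  }
  m1 <- raw(1)
  mu <- function(k) {
    stats::integrate(function(x) (x - m1)^k * dens(x), lims[1], lims[2],
      rel.tol = 1e-10, abs.tol = 1e-12
    )$value
  }
  v <- mu(2)
  c(mean = m1, variance = v, skewness = mu(3) / v^1.5, kurtosis_excess = mu(4) / v^2 - 3)
}

# standard fixtures
normal01 <- function() dist_spec("normal", mean = 0, sd = 1)

bimodal_normal_spec <- function(delta = 4, w = 0.5, sd = 1) {
  mixture_spec(
    list(
      dist_spec("normal", mean = 0, sd = sd),
      dist_spec("normal", mean = delta, sd = sd)
    ),
    weights = c(w, 1 - w)
  )
}

two_group_df <- function(x1, x2) {
  tibble::tibble(
    group = rep(c("g1", "g2"), c(length(x1), length(x2))),
    value = c(x1, x2)
  )
}
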