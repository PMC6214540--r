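# Independent oracles and shared fixtures for the test suite.

paper_tis <- function() c(100, 150, 250, 500, 750, 1000)
dixon_tes <- function() 0.92 + 0.66 * (0:10)

# Exhaustive grid search for the IR fit: T1 on a 1-ms grid, S0 and C
# profiled. For each candidate T1 the model is S0*sqrt(E^2 + C^2) =
# sqrt(A*E^2 + B) with A = S0^2 >= 0, B = (S0*C)^2 >= 0, so on squared
# signals the profile is a clipped linear least-squares fit; the original
# objective is then evaluated on the amplitude scale.
t1_grid_oracle <- function(ti, s, tsat = 4500, grid = seq(50, 3000, by = 1)) {
  s2 <- s^2
  n <- length(ti)
  E2 <- outer(ti, grid, function(t, t1)
    (1 - 2 * exp(-t / t1) + exp(-tsat / t1))^2)
  mE <- colMeans(E2); mS <- mean(s2)
  den <- colSums(E2^2) - n * mE^2
  A <- pmax((colSums(E2 * s2) - n * mE * mS) / pmax(den, 1e-300), 0)
  B <- pmax(mS - A * mE, 0)
  pred <- sqrt(E2 * rep(A, each = n) + rep(B, each = n))
  obj <- colSums((s - pred)^2)
  grid[which.min(obj)]
}

# Dense grid search for the water-fat fit: fat fraction and T2* on 0.1
# grids, total amplitude profiled analytically per grid point.
ff_grid_oracle <- function(te, s, delta_f,
                           ff_grid = seq(0, 100, by = 0.1),
                           t2_grid = seq(5, 60, by = 0.1)) {
  phi <- ff_grid / 100
  cosv <- cos(2 * pi * delta_f * te / 1000)
  base <- sqrt(outer(cosv, phi, function(cc, p)
    (1 - p)^2 + p^2 + 2 * p * (1 - p) * cc))
  ss <- sum(s^2)
  best <- c(Inf, NA, NA)
  for (t2 in t2_grid) {
    g <- base * exp(-te / t2)
    num <- colSums(g * s)
    obj <- ss - num^2 / colSums(g^2)
    j <- which.min(obj)
    if (obj[j] < best[1]) best <- c(obj[j], ff_grid[j], t2)
  }
  list(ff_pct = best[2], t2star_ms = best[3])
}

# Exact two-sided one-sample Wilcoxon signed-rank p-value by enumeration
# of all 2^n sign assignments (assumes no zeros and no tied |values|).
wilcoxon_exact_p <- function(v) {
  v <- v[v != 0]
  n <- length(v)
  r <- rank(abs(v))
  obs <- sum(r[v > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- drop(signs %*% r)
  min(1, 2 * min(mean(W <= obs), mean(W >= obs)))
}

# small standard phantom + in/opposed simulation used by several files
seg_fixture <- function(seed = 5, nslices = 1, noise_sigma = 1.6) {
  ph <- make_phantom(96, 96, nslices, seed = seed)
  io <- simulate_in_opposed(
    ph, acquisition_spec("in_opposed", noise_sigma = noise_sigma, seed = seed))
  list(phantom = ph, series = io,
       in_phase = io$images[, , 1, 2], labels = ph$labels[, , 1])
}
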