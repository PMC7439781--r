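# Shared oracles and small builders used across the suite.

# brute-force strain invariants by index summation (independent of the
# package's vectorised formulas)
brute_invariants <- function(C, n) {
  I1 <- 0
  for (i in 1:3) I1 <- I1 + C[i, i]
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + C[i, j] * C[i, j]
  I2 <- 0.5 * (I1^2 - s)
  I4 <- 0
  for (i in 1:3) for (j in 1:3) I4 <- I4 + C[i, j] * n[i] * n[j]
  c(I1 = I1, I2 = I2, I4 = I4)
}

# brute-force term-by-term energy from the four-term expression
brute_energy <- function(p, I1, I2, I4) {
  p$c1 * (I1 - 3) + p$c2 * (I2 - 3) +
    p$D1 * (exp(p$D2 * (I1 - 3)) - 1) +
    p$K1 / p$K2 * (exp(p$K2 * (I4 - 1)^2) - 1)
}

# random volume-preserving deformation gradient (det = 1)
random_unimodular <- function() {
  X <- matrix(rnorm(9, sd = 0.25), 3, 3) + diag(3)
  X / det(X)^(1 / 3)
}

# random rotation matrix via QR
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# central finite difference of the incompressible restricted energy
fd_stress_difference <- function(params, lt, lz, h = 1e-6) {
  W <- function(a, b) aortafsi:::.energy_incompressible(params, a, b)
  c(dtheta = lt * (W(lt + h, lz) - W(lt - h, lz)) / (2 * h),
    dz     = lz * (W(lt, lz + h) - W(lt, lz - h)) / (2 * h))
}

# straight cylinder geometry builder
cylinder_geometry <- function(radius = 10, length = 60, n_rings = 7,
                              wall = 2, configuration = "zero_load") {
  vessel_geometry(seq(0, length, length.out = n_rings), radius, wall,
                  configuration = configuration)
}

# Monte Carlo permutation p-value for the pooled t statistic
perm_t_p <- function(a, b, B = 1e5) {
  v <- c(a, b)
  n <- length(v)
  na <- length(a)
  t_obs <- abs(stats::t.test(a, b, var.equal = TRUE)$statistic)
  IDX <- vapply(seq_len(B), function(i) sample.int(n, na), integer(na))
  va <- matrix(v[IDX], na, B)
  sa <- colSums(va)
  ssa <- colSums(va^2)
  sb <- sum(v) - sa
  ssb <- sum(v^2) - ssa
  nb <- n - na
  vara <- (ssa - sa^2 / na) / (na - 1)
  varb <- (ssb - sb^2 / nb) / (nb - 1)
  sp <- sqrt(((na - 1) * vara + (nb - 1) * varb) / (n - 2))
  tt <- abs((sa / na - sb / nb) / (sp * sqrt(1 / na + 1 / nb)))
  mean(tt >= t_obs - 1e-12)
}
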