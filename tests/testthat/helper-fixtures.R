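# Shared fixtures and independent oracles. Oracles are implemented from
# first principles, separately from the package code paths they check.

# small uniform echogram grid (pings x bins, 1 m bins)
flatGrid <- function(np = 20, nb = 30, sv = -70, freq = 38, alpha = 0.01,
                     stage = "raw") {
  echogramGrid(freq, matrix(sv, np, nb), depthEdges = 0:nb,
               absorption = alpha, stage = stage)
}

# analytic CTD profile with linear density increase
rampProfile <- function(station = "p1", lat = 77, n = 51, t0 = 2,
                        dTdz = 0, s0 = 35, dz = 1) {
  depth <- (seq_len(n) - 1) * dz
  ctdProfile(station, depth, t0 + dTdz * depth, rep(s0, n), latitude = lat)
}

# --- independent water-mass oracle: direct transcription of the rule
# table, one row at a time, density row checked before temperature rows
waterMassOracle <- function(SA, CT, sigma) {
  one <- function(sa, ct, st) {
    if (ct <= 0) {
      if (st <= 27.97) return("POLAR")
      if (ct <= -1.1) return("CBSDW")
      return("INTERMEDIATE")
    }
    if (sa >= 35.06) {
      if (ct > 2) return("ATLANTIC") else return("MODIFIED_ATLANTIC")
    }
    "WARM_POLAR"
  }
  mapply(one, SA, CT, sigma)
}

# --- independent Francois-Garrison oracle (literal term-by-term coding)
fgOracle <- function(fkHz, Tc, S, z, pH) {
  theta <- 273 + Tc
  cc <- 1412 + 3.21 * Tc + 1.19 * S + 0.0167 * z
  f1 <- 2.8 * (S / 35)^0.5 * 10^(4 - 1245 / theta)
  boric <- (8.86 / cc * 10^(0.78 * pH - 5)) * 1 * f1 * fkHz^2 / (f1^2 + fkHz^2)
  f2 <- (8.17 * 10^(8 - 1990 / theta)) / (1 + 0.0018 * (S - 35))
  p2 <- 1 - 1.37e-4 * z + 6.2e-9 * z^2
  mgso4 <- (21.44 * (S / cc) * (1 + 0.025 * Tc)) * p2 * f2 * fkHz^2 / (f2^2 + fkHz^2)
  p3 <- 1 - 3.83e-5 * z + 4.9e-10 * z^2
  a3 <- if (Tc <= 20)
    4.937e-4 - 2.59e-5 * Tc + 9.11e-7 * Tc^2 - 1.50e-8 * Tc^3
  else
    3.964e-4 - 1.146e-5 * Tc + 1.45e-7 * Tc^2 - 6.5e-10 * Tc^3
  (boric + mgso4 + a3 * p3 * fkHz^2) / 1000
}

# --- brute-force Kendall tau-b and exact permutation p for small n
kendallOracle <- function(x, y) {
  n <- length(x)
  tauOf <- function(a, b) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    s / sqrt((choose(n, 2)) * (choose(n, 2))) # untied: denominator = n(n-1)/2
  }
  obs <- tauOf(x, y)
  perms <- asplit(permutationsOf(n), 1)
  taus <- vapply(perms, function(p) tauOf(x, y[p]), numeric(1))
  # two-sided exact p: probability of |tau| at least as extreme
  list(tau = obs, p = mean(abs(taus) >= abs(obs) - 1e-12))
}

permutationsOf <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# --- brute-force ANOSIM over all label permutations
anosimOracle <- function(d, groups) {
  n <- attr(d, "Size")
  dm <- as.matrix(d)
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(dm[lower.tri(dm)])
  rOf <- function(g) {
    bw <- wi <- c()
    for (i in 2:n) for (j in 1:(i - 1)) {
      if (g[i] == g[j]) wi <- c(wi, rk[i, j]) else bw <- c(bw, rk[i, j])
    }
    (mean(bw) - mean(wi)) / (n * (n - 1) / 4)
  }
  obs <- rOf(groups)
  perms <- asplit(permutationsOf(n), 1)
  rs <- vapply(perms, function(p) rOf(groups[p]), numeric(1))
  list(R = obs, p = mean(rs >= obs - 1e-12))
}

# default-scene fixture shared by recovery tests (built once per run)
defaultScene <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) {
      sc <- simulationConfig(seed = seed)
      sim <- simulateEchograms(sc)
      pp <- preprocessEchograms(sim$grids)
      mv38 <- computeMvbs(pp$grids$f38)
      mv120 <- computeMvbs(pp$grids$f120)
      cache <<- list(config = sc, sim = sim, clean = pp,
                     mv38 = mv38, mv120 = mv120,
                     classified = classifyCells(mv38, mv120))
    }
    cache
  }
})
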