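# Shared fixtures (cached per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the default study-condition preparation pair
default_pair <- function() {
  cached("default_pair", {
    cfg <- synth_config(seed = 11)
    list(control = generate_preparation(cfg), ttx = generate_ttx(cfg),
         config = cfg)
  })
}

# classification products for the default pair
default_analysis <- function() {
  cached("default_analysis", {
    pair <- default_pair()
    smap <- classify_dpmap(pair$control$dpmap)
    thr <- calibrate_threshold(pair$ttx$dpmap)
    seg <- extract_orbit_segments(pair$control$dpmap, smap)
    neuro <- apply_myogenic_mask(smap, seg, thr)
    list(smap = smap, thr = thr, seg = seg, neuro = neuro)
  })
}

# small quiet preparation (no events, no ripple, no noise)
quiet_prep <- function() {
  cached("quiet_prep", {
    cfg <- synth_config(length_mm = 60, duration_s = 30, boluses = list(),
                        contractions = list(), myogenic_amp_mm = 0,
                        myogenic_pressure_mmhg = 0, noise_d_sd_mm = 0,
                        noise_p_sd_mmhg = 0, seed = 5)
    generate_preparation(cfg)
  })
}

# hand-built dpmap from raw matrices on a uniform grid
toy_dpmap <- function(D, P, dt = 0.25, dx = 1) {
  nx <- nrow(D); nt <- ncol(D)
  dmap <- structure(list(positions_mm = (seq_len(nx) - 0.5) * dx,
                         times_s = (seq_len(nt) - 1) * dt, D = D),
                    class = "diameter_map")
  pmap <- structure(list(positions_mm = dmap$positions_mm,
                         times_s = dmap$times_s, P = P),
                    class = "pressure_map")
  bundle_dpmap(dmap, pmap, list(condition = "synthetic"))
}

## ---- independent oracles ----

# exhaustive maximum-probability path over all 3^n state sequences,
# using the same emission/transition model as the decoder
viterbi_enumerate <- function(z, params = trend_hmm_params()) {
  n <- length(z)
  states <- as.matrix(expand.grid(rep(list(1:3), n)))
  mu <- params$mu
  logA <- log(params$A)
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    lp <- sum(-(z - mu[s])^2 / 2)
    if (n > 1) lp <- lp + sum(logA[cbind(s[-n], s[-1])])
    if (lp > best + 1e-12) { best <- lp; best_path <- s }
  }
  best_path
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
mw_enumerate <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  mu <- n1 * length(b) / 2
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(N, n1)
  Us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# Fisher two-sided p by direct enumeration of all tables with the margins
fisher_enumerate <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  pobs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) / choose(m + n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

chi2_hand <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
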