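# shared fixtures and independent oracles, all built in code

# simple all-beam-on trace from a function of time
fn_trace <- function(f, duration_s = 60, rate_hz = 30, label = "other") {
  tt <- seq(0, duration_s, by = 1 / rate_hz)
  surrogate_trace(times = tt, amplitudes = f(tt),
                  beam_on = rep(TRUE, length(tt)),
                  label = label, nominal_rate = rate_hz)
}

# brute-force voxel-set oracle for the overlap metrics: masks as sets of
# voxel coordinate strings
oracle_metrics <- function(a, b) {
  key <- function(m) {
    idx <- which(m$data, arr.ind = TRUE)
    paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
  }
  A <- key(a); B <- key(b)
  inter <- length(intersect(A, B))
  list(dsc = 2 * inter / (length(A) + length(B)),
       oi = inter / length(A),
       vol_a = length(A) * prod(a$spacing) / 1000,
       vol_b = length(B) * prod(b$spacing) / 1000)
}

# brute-force centroid: average voxel-center coordinates one voxel at a
# time
oracle_centroid <- function(m) {
  idx <- which(m$data, arr.ind = TRUE)
  out <- c(0, 0, 0)
  for (r in seq_len(nrow(idx))) {
    out <- out + m$origin + (idx[r, ] - 0.5) * m$spacing
  }
  out / nrow(idx)
}

# full-enumeration Mann-Whitney oracle: two-sided p over all label
# assignments of the pooled sample
oracle_mw <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_for <- function(sel) sum(r[sel]) - nx * (nx + 1) / 2
  obs <- u_for(seq_len(nx))
  all_u <- apply(utils::combn(nx + ny, nx), 2, u_for)
  p_lo <- mean(all_u <= obs)
  p_hi <- mean(all_u >= obs)
  list(U = obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# random mask on a small grid
random_mask <- function(dim3 = c(16, 16, 16), p = 0.2,
                        spacing = c(1, 2, 3)) {
  voxel_mask(array(stats::runif(prod(dim3)) < p, dim = dim3),
             spacing = spacing)
}

# 26-connected one-voxel dilation (edge-clamped), used for the
# one-voxel-layer containment check
dilate26 <- function(m) {
  d <- dim(m); out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- out | m[xs, ys, zs]
  }
  out
}

# dual-surrogate synthesis with study-default channels and optional
# injected bellows lag / relative noise
make_pair <- function(seed, lag_ms = 0, noise_frac = 0, duration_s = 45,
                      kind = "irregular", params = list()) {
  params$duration_s <- params$duration_s %||% duration_s
  prog <- make_breathing_curve(kind, params, seed = seed)
  amp <- prog$metadata$params$amplitude_cm *
    prog$metadata$params$surface_ratio
  synthesize_surrogates(
    prog,
    rpm_model = surrogate_model(gain = 10, sampling_rate_hz = 30,
                                noise_sd = noise_frac * 10 * amp),
    bellows_model = surrogate_model(gain = 2.5, lag_ms = lag_ms,
                                    sampling_rate_hz = 38,
                                    noise_sd = noise_frac * 2.5 * amp),
    seed = seed + 1000L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
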