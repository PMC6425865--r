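# Independent oracles and fixture builders used across the suite.

# Fisher exact p for a 2x2 table by direct hypergeometric enumeration of the
# single free cell (independent of the package's general r x c recursion).
fisher_2x2_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Render a synthetic fluorescence field: uniform background plus a disc of
# extra per-pixel signal, with optional Gaussian noise. Returns the pieces a
# CTCF measurement needs, plus the true total signal.
render_fluorescence_cell <- function(side = 80, radius = 15, signal = 40,
                                     background = 12, noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(background, side, side)
    ctr <- (side + 1) / 2
    ii <- matrix(rep(seq_len(side), side), nrow = side)
    cell <- (ii - ctr)^2 + (t(ii) - ctr)^2 <= radius^2
    img[cell] <- img[cell] + signal
    if (noise_sd > 0) img <- img + matrix(rnorm(side^2, sd = noise_sd), side)
    list(image = img, cell_mask = cell,
         integrated_density = sum(img[cell]),
         area = sum(cell),
         background_mean = mean(img[!cell]),
         true_total_signal = signal * sum(cell))
  })
}

# Freeman-Halton p for a 3 x 3 table by brute force: materialize every table
# with the observed margins from a fully vectorized grid over the four free
# cells (a code path independent of the package's depth-first recursion).
fisher_3x3_bruteforce <- function(m) {
  stopifnot(nrow(m) == 3, ncol(m) == 3)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  g <- expand.grid(a11 = 0:min(rs[1], cs[1]), a12 = 0:min(rs[1], cs[2]),
                   a21 = 0:min(rs[2], cs[1]), a22 = 0:min(rs[2], cs[2]))
  a13 <- rs[1] - g$a11 - g$a12
  a23 <- rs[2] - g$a21 - g$a22
  a31 <- cs[1] - g$a11 - g$a21
  a32 <- cs[2] - g$a12 - g$a22
  a33 <- cs[3] - a13 - a23
  ok <- a13 >= 0 & a23 >= 0 & a31 >= 0 & a32 >= 0 & a33 >= 0
  lconst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  lp <- lconst - (lgamma(g$a11 + 1) + lgamma(g$a12 + 1) + lgamma(a13 + 1) +
                  lgamma(g$a21 + 1) + lgamma(g$a22 + 1) + lgamma(a23 + 1) +
                  lgamma(a31 + 1) + lgamma(a32 + 1) + lgamma(a33 + 1))[ok]
  lp_obs <- lconst - sum(lgamma(m + 1))
  min(sum(exp(lp[lp <= lp_obs + log1p(1e-7)])), 1)
}

# Rotate a matrix by 90 degrees (for rotation-invariance checks).
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# Rigid-motion transform of a track table.
transform_tracks <- function(tracks, angle = 0, dx = 0, dy = 0, scale = 1) {
  x <- tracks$x_um * scale; y <- tracks$y_um * scale
  tracks$x_um <- cos(angle) * x - sin(angle) * y + dx
  tracks$y_um <- sin(angle) * x + cos(angle) * y + dy
  tracks
}

# Random small count matrix with non-degenerate margins.
random_count_matrix <- function(nr, nc, total) {
  m <- matrix(0L, nr, nc)
  idx <- sample(nr * nc, total, replace = TRUE)
  tab <- tabulate(idx, nbins = nr * nc)
  m[] <- tab
  dimnames(m) <- list(paste0("r", seq_len(nr)), paste0("c", seq_len(nc)))
  m
}
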