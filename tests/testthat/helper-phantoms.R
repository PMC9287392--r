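# Shared small fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small grid keeps unit tests fast; the nerve still spans ~25 mm
small_spec <- function(...) {
  phantom_spec(grid_shape = c(24L, 24L, 16L), ...)
}

# straight tube along +y: collinear control points
straight_spec <- function(...) {
  ctr <- (c(24, 24, 16) - 1) * 2 / 2
  cp <- cbind(rep(ctr[1], 2), ctr[2] + c(-12, 12), rep(ctr[3], 2))
  phantom_spec(grid_shape = c(24L, 24L, 16L), centerline_ctrl_points = cp, ...)
}

# healthy-profile noiseless phantom on the small grid
noiseless_phantom <- function() {
  cached("noiseless", function() make_phantom(small_spec(snr = Inf, seed = 7)))
}

# healthy-profile SNR-20 phantom + fitted tensors and maps
noisy_fitted <- function() {
  cached("noisy_fitted", function() {
    ph <- make_phantom(small_spec(snr = 20, seed = 7))
    tf <- fit_tensor_lls(merge_b0_pairs(ph$dwi))
    list(ph = ph, tf = tf, maps = scalar_maps(tf))
  })
}

# tiny gradient table: 2 b0 (AP/PA) + n directions
tiny_gradients <- function(n = 12, b = 2000, seed = 9) {
  dirs <- make_gradient_scheme(n, seed = seed, n_iter = 200)
  gradient_table(c(0, 0, rep(b, n)), rbind(0, 0, dirs),
                 c("AP", "PA", rep("none", n)))
}

# random symmetric positive-definite-ish 3x3 tensor components
random_tensor <- function() {
  A <- matrix(rnorm(9), 3)
  m <- crossprod(A) / 3
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# brute-force eigenvalues via the characteristic polynomial (oracle)
charpoly_eigenvalues <- function(m) {
  # det(m - x I) = -x^3 + tr x^2 - c2 x + det
  tr <- sum(diag(m))
  c2 <- m[1, 1] * m[2, 2] - m[1, 2]^2 + m[1, 1] * m[3, 3] - m[1, 3]^2 +
    m[2, 2] * m[3, 3] - m[2, 3]^2
  dt <- det(m)
  r <- polyroot(c(dt, -c2, tr, -1))
  sort(Re(r), decreasing = TRUE)
}

# brute-force two-sided Mann-Whitney p by full enumeration (oracle)
enumerate_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  u_of <- function(sel) {
    r <- rank(all)
    sum(r[sel]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  mu <- nx * ny / 2
  us <- apply(idx, 2, function(sel) {
    r <- rank(all)
    sum(r[sel]) - nx * (nx + 1) / 2
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
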