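# Independent brute-force oracle for the exact two-sided Mann-Whitney U
# p-value: enumerate every assignment of the pooled ranks to group A, build
# the exact null distribution of U, and take min(1, 2 * smaller tail)
# including the observed value. Only valid without ties.
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n_a <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  splits <- utils::combn(n, n_a)
  u_null <- apply(splits, 2, function(ix) sum(r[ix]) - n_a * (n_a + 1) / 2)
  p_lo <- mean(u_null <= u_obs)
  p_hi <- mean(u_null >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

default_scheme <- function() bvalue_scheme(c(100, 500, 900, 1300, 1700))

# single-lesion phantom helpers kept small so fits stay fast
uniform_lesion <- function(d = 1.44e-3, k = 0.69, s0 = 1000,
                           necrotic_fraction = 0) {
  lesion_spec(
    center = c(8, 8, 3), radii = c(4, 4, 2),
    d_app_mean = d, d_app_sd = 0, k_app_mean = k, k_app_sd = 0,
    s0_mean = s0, s0_sd = 0, necrotic_fraction = necrotic_fraction
  )
}

small_phantom <- function(seed = 1, ...) {
  make_phantom(
    grid_shape = c(16, 16, 6), lesions = list(uniform_lesion(...)),
    scheme = default_scheme(), seed = seed
  )
}

# minimal parameter_maps with given k_app values at the first voxels
toy_maps <- function(values, grid = c(4, 4, 1)) {
  n <- length(values)
  qc <- array(1L, grid)
  m <- array(NaN, grid)
  qc[seq_len(n)] <- 0L
  k <- m
  k[seq_len(n)] <- values
  d <- m
  d[seq_len(n)] <- 1e-3
  a <- m
  a[seq_len(n)] <- 1.2e-3
  s <- m
  s[seq_len(n)] <- 1000
  parameter_maps(s0 = s, d_app = d, k_app = k, adc = a, qc = qc)
}
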