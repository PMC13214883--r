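# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# Two fixed orthonormal spectrum-space directions plus a mean, on a small
# axis: the scaffold for rank-2 and exact-linear constructions.
toy_basis <- function(n_channels = 60, seed = 11) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n_channels * 2), ncol = 2)))
  list(wn = seq(100, 100 + 5 * (n_channels - 1), by = 5),
       mean = abs(rnorm(n_channels)),
       v1 = q[, 1], v2 = q[, 2])
}

# Series whose spectra are s(t) = mean + z1(t) v1 + z2(t) v2.
latent_series <- function(times, z1, z2, basis = toy_basis(),
                          noise_sd = 0, batch_id = "toy") {
  m <- outer(rep(1, length(times)), basis$mean) +
    outer(z1, basis$v1) + outer(z2, basis$v2)
  if (noise_sd > 0)
    m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow = nrow(m))
  spectra_series(times, basis$wn, m, batch_id = batch_id)
}

# The exact-linear construction: z1 linear in t, z2 affine in z1, so the
# anticipation model class contains the truth.
exact_linear_series <- function(times = 0:90, basis = toy_basis()) {
  latent_series(times, z1 = 0.5 + 0.05 * times,
                z2 = 2 + 3 * (0.5 + 0.05 * times), basis = basis,
                batch_id = "exact-linear")
}

random_series <- function(n_times = 8, n_channels = 30, seed = 3) {
  set.seed(seed)
  spectra_series(seq_len(n_times) - 1,
                 seq(100, by = 10, length.out = n_channels),
                 matrix(abs(rnorm(n_times * n_channels)) + 0.5,
                        nrow = n_times),
                 batch_id = "random")
}

# Small, fast synthetic preset for tests that only need shape, not the
# full 666-channel axis.
small_preset <- function(name, ...) {
  synthetic_preset(name, axis_step = 50, ...)
}
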