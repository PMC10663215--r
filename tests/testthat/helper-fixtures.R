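## Shared fixtures built in code.

## deterministic mass/pixel samples with known densities
fixture_samples <- function(n = 50, seed = 421, sigma_scale = 1) {
  dens <- generator_density_model()
  dens$sigma <- dens$sigma * sigma_scale
  make_mass_dataset(n, density = dens, seed = seed)
}

## a small scene list for pipeline tests
fixture_scenes <- function(n = 2, size = 64, seed = 11, sigma0 = FALSE) {
  dens <- if (sigma0) {
    d <- default_surface_density()
    d$sigma[] <- 0
    d
  } else generator_density_model()
  lapply(seq_len(n), function(i) {
    generate_scene(size = size, density = dens, seed = seed + i)
  })
}

## brute-force per-class IoU from label maps via index sets (test oracle)
brute_force_iou <- function(truth, pred, n_class) {
  sapply(seq_len(n_class) - 1L, function(k) {
    ti <- which(truth == k)
    pi <- which(pred == k)
    u <- length(union(ti, pi))
    if (u == 0) NA_real_ else 100 * length(intersect(ti, pi)) / u
  })
}

expect_grad_matches_fd <- function(value_fn, param, indices, tol = 1e-5) {
  for (idx in indices) {
    eps <- 1e-6
    vp <- param$base
    vp[idx] <- vp[idx] + eps
    up <- value_fn(vp)
    vm <- param$base
    vm[idx] <- vm[idx] - eps
    dn <- value_fn(vm)
    fd <- (up - dn) / (2 * eps)
    testthat::expect_equal(param$grad[idx], fd, tolerance = tol)
  }
}
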