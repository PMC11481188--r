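# Small in-code fixtures shared across test files.

# Compact two-module plan for fast planted-recovery checks.
small_plan <- function() rbind(
  module_spec(1L, 35L, "quadratic", vertex_age = 12.5, curvature = -0.05, cor = 0.95),
  module_spec(2L, 35L, "linear", slope = 0.08, cor = 0.95),
  data.frame(module_id = 0L, n_transcripts = 30L, trajectory = "flat", slope = 0,
             vertex_age = NA_real_, curvature = 0, cor = 1, stringsAsFactors = FALSE)
)

# A noiseless single-module truth: exact latent quadratic, Poisson-free.
noiseless_truth <- function(vertex = 14, n = 35, seed = 3L) {
  ages <- generate_ages(n, seed = seed)
  plan <- module_spec(1L, 5L, "quadratic", vertex_age = vertex,
                      curvature = 0.05, cor = 1)
  ground_truth(ages, module_plan = plan,
               noise = list(dispersion = 0, shared_sd = 0, staining_sd = 0),
               seed = seed)
}

# Two planted correlated blocks with near-zero cross-talk, directly on the
# latent (Gaussian) scale; for netmod unit tests.
planted_blocks <- function(n_per = 40, n_samples = 40, r_within = 0.9,
                           seed = 11L) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  noise_sd <- sqrt((1 - r_within) / r_within)
  mat <- rbind(
    t(vapply(seq_len(n_per), function(i) f1 + rnorm(n_samples, 0, noise_sd),
             numeric(n_samples))),
    t(vapply(seq_len(n_per), function(i) f2 + rnorm(n_samples, 0, noise_sd),
             numeric(n_samples))))
  rownames(mat) <- c(sprintf("a%02d", seq_len(n_per)),
                     sprintf("b%02d", seq_len(n_per)))
  list(mat = mat, truth = rep(1:2, each = n_per))
}
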