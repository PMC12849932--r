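# Shared small-scale fixtures, all generated in code.

small_neural_spec <- function(noise = 1, amplitude = 1,
                              a = c(A1S3 = 1, A1S1 = 2, A3S1 = 3),
                              b = c(A1S3 = 3, A1S1 = 2, A3S1 = 1),
                              signal = list(general = 1:2, altruistic = 3:4,
                                            strategic = 5:6, linear = 7:8)) {
  neural_gen_spec(n_parcels = 20L, voxels_per_parcel = 20L,
                  signal_parcels = signal, signal_amplitude = amplitude,
                  neural_noise_sd = noise, a_by_condition = a,
                  b_by_condition = b)
}

# zero-structure spec: pure noise parcels, constant motive loadings
null_neural_spec <- function(n_parcels = 20L, voxels_per_parcel = 20L, noise = 1) {
  neural_gen_spec(n_parcels = n_parcels, voxels_per_parcel = voxels_per_parcel,
                  signal_parcels = list(), signal_amplitude = 0,
                  neural_noise_sd = noise,
                  a_by_condition = c(A1S3 = 1, A1S1 = 1, A3S1 = 1),
                  b_by_condition = c(A1S3 = 1, A1S1 = 1, A3S1 = 1))
}

# deterministic rating table with perfectly coherent factor blocks
coherent_ratings <- function(n = 12) {
  set.seed(99)
  com <- runif(n, 20, 80)
  obl <- runif(n, 20, 80)
  data.frame(participant_id = sprintf("s%02d", seq_len(n)),
             benefactor_type = rep(c("altruistic", "strategic"), length.out = n),
             cost = rep(task_constants()$costs, length.out = n),
             care = com, gratitude = com, guilt = com,
             second_order_belief = obl, obligation = obl,
             indebtedness = (com + obl) / 2,
             stringsAsFactors = FALSE)
}

# brute-force two-sided exact Mann-Whitney p by enumerating rank assignments
mw_exact_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  if (u_obs > mu) min(1, 2 * mean(us >= u_obs)) else min(1, 2 * mean(us <= u_obs))
}
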