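# minimal labelled track builder for unit tests
make_track <- function(x, y, alpha = rep(1, length(x)),
                       K = rep(1, length(x)),
                       state = rep(2L, length(x))) {
  difftrack:::make_sim_track(x, y, alpha, K, state, model = "SSM")
}

# small SSM track list for pipeline tests
sim_ssm_batch <- function(n, T_range = c(20, 50), alpha_range = c(0.1, 1.9),
                          K_range = c(1e-12, 1e6)) {
  lapply(seq_len(n), function(i)
    simulate_ssm(sim_config("SSM",
                            T = sample(seq(T_range[1], T_range[2]), 1),
                            alpha_range = alpha_range, K_range = K_range)))
}
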