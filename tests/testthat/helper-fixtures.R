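# Small hand-built graphs used across tests.

# star K_{1,k}: node 1 is the hub
star_society <- function(k, admin = integer()) {
  society(k + 1, cbind(1L, 1L + seq_len(k)), admin = admin)
}

# path 1-2-...-n
path_society <- function(n, admin = integer()) {
  society(n, cbind(seq_len(n - 1), 2:n), admin = admin)
}

# quick parameter sets for small, fast runs
small_params <- function(...) {
  model_params(N = 100, t_max = 300, ...)
}
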