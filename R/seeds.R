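# Deterministic seed fan-out. One user seed derives independent child seeds
# per (stream, index) pair by folding integers into a 31-bit state; the same
# scheme runs inside the compiled ensemble loop, so R-level compositions of
# bootstrap_resample() + cluster_variables() reproduce ensemble rows exactly.
#
# Streams: 1 = per-p scan, 2 = per-bootstrap, 3 = per-restart,
#          4 = per-null-dataset, 5 = null ensemble, 6 = reported partition,
#          7 = per-p null seed.
fold_seed <- function(h, k) {
  .fold_seed_cpp(as.double(h %% 2147483647), as.double(k))
}

# set.seed() needs a 32-bit integer; folded seeds already are
as_r_seed <- function(seed) as.integer(seed %% 2147483647)
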