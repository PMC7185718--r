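# small shared fixtures: short stimuli and a reduced signal path used by the
# slower integration tests
short_spec <- function(sep = 6, reps = 10)
  stimulus_spec(semitone_sep = sep, repetitions = reps)

tiny_opts <- function()
  model_opts(n_channels = 48, f_low = 320, nmf_iter = 30)

# deterministic peripheral/central chain without competition noise
quiet_chain <- function(sep = 6, reps = 10, q = 8) {
  sig <- generate_aba(short_spec(sep, reps))
  P <- peripheral_analysis(sig, stage_competition("peripheral", c_n = 0),
                           q = q)
  C <- central_analysis(P, stage_competition("central", c_n = 0))
  list(signal = sig, P = P, C = C)
}
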