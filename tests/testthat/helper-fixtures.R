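# Shared fixtures: tiny configurations and record sets built in code.

tiny_config <- function(...) {
  tp_config(feat_units = 5L, lstm_units = 6L, attn_units = 7L, n_attn = 5L,
            summary_units = 8L, dropout = 0, seed = 3L, ...)
}

tiny_records <- function(seed = 7L)
  synth_generate(synth_spec(n = c(noTP = 3, SP = 3, mTP = 2, cTP = 2, luTP = 2),
                            seed = seed))

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
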