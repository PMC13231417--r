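# structural parameter universe of the translational model
.tm_structural <- c("k_elim", "k_translate", "cl", "v1", "v2", "q")
.tm_alpha <- paste0("alpha_", .tm_structural)
.tm_all_names <- c(.tm_structural, .tm_alpha)
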