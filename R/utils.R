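# sample() treats a length-1 numeric x as 1:x; always index instead
sample_vec <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}
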