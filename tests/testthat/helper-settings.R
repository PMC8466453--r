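# A handful of blocks compare against published table values that are
# asserted as printed; let the whole suite run even if several disagree.
options(testthat.progress.max_fails = 100L)
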