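# Several acceptance expectations are known to disagree with the published
# magnitudes (see the methods vignette on the near-bifurcation working
# point); never stop the run early on their account.
options(testthat.progress.max_fails = 1000L)
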