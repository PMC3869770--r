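# Report every failure rather than aborting the suite at the default cap:
# some acceptance expectations document known model-variant discrepancies
# and must not mask the remaining files.
options(testthat.progress.max_fails = 200)
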