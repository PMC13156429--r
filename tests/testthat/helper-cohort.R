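# The multi-subject scheme-comparison cohort is expensive; build it once and
# share it between the tests that consume it.
acceptanceCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(suppressMessages(
        simulateSchemeCohort(nSubjects = 8, shape = c(32, 32, 16),
          baseSeed = 42)))
    cache
  }
})
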