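# Desk-scale phantom feature set shared by the heavier evaluation tests;
# computed once per test run, lazily.
default_phantom_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      samples <- generate_dataset(params = phantom_params(), seed = 1)
      cache <<- extract_features(samples)
    }
    cache
  }
})
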