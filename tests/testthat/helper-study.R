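# The miniature end-to-end study is expensive (several minutes), so it is
# run once and shared by every test that needs it.
get_desk_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_desk_study(seed = 1L)
    cache
  }
})
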