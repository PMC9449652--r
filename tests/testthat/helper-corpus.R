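## Small shared component corpora, built once per test run.
.corpus_cache <- new.env(parent = emptyenv())

cached_corpus <- function(key, ...) {
  if (is.null(.corpus_cache[[key]]))
    .corpus_cache[[key]] <- simulate_component_corpus(...)
  .corpus_cache[[key]]
}
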