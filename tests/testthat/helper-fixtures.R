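# Shared fixtures, built lazily and cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

fixture_corpus <- function() {
  cached("corpus", function()
    generate_synthetic_corpus(30, promoter_length = 400, gc_fraction = 0.38,
                              plant_elements = TRUE, seed = 101))
}

fixture_placeback <- function(msrl, seed = 1L) {
  cached(sprintf("pb_%d_%d", msrl, seed), function()
    build_placeback(placeback_config(msrl, "test_scale", seed = seed)))
}

fixture_placeback_set <- function() {
  cached("pb_set", function() list(
    fixture_placeback(5, 1), fixture_placeback(5, 2),
    fixture_placeback(40, 3), fixture_placeback(40, 4)))
}

fixture_ensemble <- function() {
  cached("ensemble", function()
    build_determiner_ensemble("test_scale", seed = 10))
}

random_promoter_seq <- function(n = 400) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

TETO_SEQ <- "TCCCTATCAGTGATAGAGATCTCCCTATCAGTGATAGAGA"
MIG1O_SEQ <- "GTATTAAACCCGGGGTA"
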