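# Independent oracles used across test files.

# Pearson chi-square by the observed-vs-expected cell sum, independent of the
# closed form used in the package.
brute_chisq <- function(a, b, c, d) {
  o <- matrix(as.numeric(c(a, c, b, d)), 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

random_tables <- function(n, max_count = 500, seed = 1) {
  set.seed(seed)
  data.frame(a = sample.int(max_count, n, replace = TRUE),
             b = sample.int(max_count, n, replace = TRUE),
             c = sample.int(max_count, n, replace = TRUE),
             d = sample.int(max_count, n, replace = TRUE))
}

# Giggle worked-example cell counts: causative uses 0 (less-transparent) / 7
# (more-transparent), 649 non-causative uses; all other verbs 468,636 / 3,676
# causative and 1,908,895 non-causative.
giggle_counts <- function() {
  data.frame(verb = c("giggle", "rest"),
             n_less = c(0, 468636), n_more = c(7, 3676),
             n_other = c(649, 1908895), stringsAsFactors = FALSE)
}

# Flat semantic profile for lexica where semantics should not matter.
flat_profiles <- function(verbs, value = 0.5) {
  data.frame(verb = verbs, event_merge_unit = value, autonomy_unit = value,
             directive_unit = value, requires_unit = value,
             stringsAsFactors = FALSE)
}

tiny_fit_inputs <- function(n_verbs = 6, seed = 1, corpus_tokens = 5e4) {
  spec <- synth_spec(n_verbs = n_verbs, corpus_tokens = corpus_tokens)
  latents <- gen_latent_semantics(spec, seed = seed)
  counts <- gen_counts(spec, latents, seed = seed + 1)
  profiles <- semantic_profiles(gen_ratings(spec, latents, seed = seed + 2))
  list(spec = spec, latents = latents, counts = counts, profiles = profiles)
}
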