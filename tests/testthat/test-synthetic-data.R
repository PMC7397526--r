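test_that("latent semantics are reproducible, collinear, and noise-free at sd 0", {
  spec <- synth_spec(n_verbs = 30)
  l1 <- gen_latent_semantics(spec, seed = 5)
  l2 <- gen_latent_semantics(spec, seed = 5)
  expect_identical(l1, l2)
  expect_true(all(l1$event_merge >= 0 & l1$event_merge <= 1))

  l0 <- gen_latent_semantics(synth_spec(n_verbs = 30, rater_noise_sd = 0),
                             seed = 5)
  expect_equal(l0$autonomy, l0$event_merge)
  expect_equal(l0$requires, l0$event_merge)

  # default noise: the four latents stay highly correlated (large-lexicon
  # Monte-Carlo estimate of the generator's pairwise correlations)
  big <- gen_latent_semantics(synth_spec(n_verbs = 5000), seed = 1)
  cm <- cor(big[c("event_merge", "autonomy", "directive", "requires")])
  expect_true(all(cm[upper.tri(cm)] > 0.7))
})

test_that("gen_ratings emits one row per rater x verb x scale with LLN recovery", {
  spec <- synth_spec(n_verbs = 10, n_raters = 20)
  lat <- gen_latent_semantics(spec, seed = 2)
  r <- gen_ratings(spec, lat, seed = 3)
  expect_equal(nrow(r), 10 * 4 * 20)
  expect_true(all(r$value >= 0 & r$value <= 100))
  expect_identical(r, gen_ratings(spec, lat, seed = 3))

  # aggregate error shrinks as the rater panel grows
  err <- sapply(c(5, 40, 320), function(k) {
    sp <- synth_spec(n_verbs = 10, n_raters = k, rater_noise_sd = 0.2)
    m <- aggregate_ratings(gen_ratings(sp, lat, seed = 4))
    mean(abs(m$event_merge_mean / 100 - lat$event_merge))
  })
  expect_true(err[3] < err[1])
})

test_that("gen_counts conserves totals and follows the logistic allocation", {
  spec <- synth_spec(n_verbs = 25, corpus_tokens = 1e6)
  lat <- gen_latent_semantics(spec, seed = 6)
  counts <- gen_counts(spec, lat, seed = 7)
  tot <- with(counts, n_less + n_more + n_other)
  w <- seq_len(25)^(-1)
  expect_equal(tot, pmax(1, round(1e6 * w / sum(w))))
  expect_true(all(counts$n_less >= 0 & counts$n_more >= 0 & counts$n_other >= 0))

  # empirical P(LESS | causative) tracks plogis(beta0 + beta_sem * m) within
  # binomial error for well-attested verbs
  caus <- counts$n_less + counts$n_more
  keep <- caus >= 200
  p_hat <- counts$n_less[keep] / caus[keep]
  p_true <- plogis(spec$beta0 + spec$beta_sem * lat$event_merge[keep])
  expect_true(all(abs(p_hat - p_true) <
                    4 * sqrt(p_true * (1 - p_true) / caus[keep]) + 1e-3))

  # saturated logistic: every causative token of a high-merge verb is LESS
  hot <- synth_spec(n_verbs = 25, beta0 = 50, beta_sem = 50)
  ch <- gen_counts(hot, lat, seed = 8)
  expect_true(all(ch$n_more == 0))
})

test_that("gen_stream samples cells at their corpus proportions", {
  counts <- data.frame(verb = c("a", "b"), n_less = c(500, 0),
                       n_more = c(0, 250), n_other = c(250, 0))
  sampler <- gen_stream(counts)
  set.seed(30)
  tok <- sampler(1e5)
  expect_equal(mean(tok$verb == "a" & tok$form == "LESS"), 0.5, tolerance = 0.02)
  expect_equal(mean(tok$verb == "b" & tok$form == "MORE"), 0.25, tolerance = 0.02)
  expect_equal(tok$causative, as.integer(tok$form != "OTHER"))
  set.seed(30)
  expect_identical(sampler(100), tok[1:100, ])

  # single nonzero cell: all tokens identical
  one <- gen_stream(data.frame(verb = "x", n_less = 0, n_more = 9, n_other = 0))
  expect_true(all(one(50)$form == "MORE"))
  expect_error(gen_stream(data.frame(verb = "x", n_less = 0, n_more = 0,
                                     n_other = 0)), "all-zero")
})

test_that("gen_judgments has the stated shape, midpoint degeneracy and sign structure", {
  spec <- synth_spec(n_verbs = 20, n_participants = 48)
  lat <- gen_latent_semantics(spec, seed = 9)
  counts <- gen_counts(spec, lat, seed = 10)
  j <- gen_judgments(spec, lat, counts, seed = 11)
  expect_equal(nrow(j), 48 * 20 * 2)
  expect_true(all(j$rating %in% 1:5))

  # no semantics, no frequency bias, no noise: everything sits at category 3
  flat <- synth_spec(n_verbs = 20, gamma_sem = 0, gamma_freq = 0,
                     judgment_noise_sd = 0)
  j0 <- gen_judgments(flat, lat, counts, seed = 12)
  expect_true(all(j0$rating == 3))

  # sign recovery: high event-merge verbs prefer the less-transparent form,
  # so the MORE-minus-LESS difference score falls with m
  jm <- judgment_means(j)
  m <- lat$event_merge[match(jm$verb, lat$verb)]
  expect_lt(byverb_pearson(jm$diff, m), 0)
  expect_gt(byverb_pearson(jm$mean_less - jm$mean_more, m), 0.5)
})

test_that("synth_dataset is bit-reproducible and internally consistent", {
  spec <- synth_spec(n_verbs = 12, corpus_tokens = 1e5)
  d1 <- synth_dataset(spec, seed = 33)
  d2 <- synth_dataset(spec, seed = 33)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$judgments, d2$judgments)
  expect_identical(d1$profiles, d2$profiles)
  expect_setequal(d1$counts$verb, d1$profiles$verb)
  d3 <- synth_dataset(spec, seed = 34)
  expect_false(identical(d1$counts, d3$counts))
})

test_that("corpus predictors recover the direction of the generative allocation bias", {
  spec <- synth_spec()
  lat <- gen_latent_semantics(spec, seed = 44)
  counts <- gen_counts(spec, lat, seed = 45)
  pred <- construction_predictors(counts)
  b <- log((counts$n_less + 0.5) / (counts$n_more + 0.5)) -
    log((sum(counts$n_less) - counts$n_less + 0.5) /
          (sum(counts$n_more) - counts$n_more + 0.5))
  # the signed preemption predictor agrees with the bias in sign wherever
  # the verb is well attested, and correlates positively overall; the
  # chi-square magnitude additionally scales with Zipfian token frequency,
  # which caps the linear correlation well below 1 (see the rank correlation)
  attested <- counts$n_less + counts$n_more >= 100
  expect_gt(mean((sign(pred$preemption_less_raw) == sign(b))[attested]), 0.95)
  expect_gt(byverb_pearson(pred$preemption_less, b), 0.3)
  expect_gt(cor(pred$preemption_less, b, method = "spearman"), 0.8)
})
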