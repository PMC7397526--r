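test_that("init_weights is uniform on [-range, range] and seed-reproducible", {
  cfg <- learner_config(n_verbs = 10, n_runs = 1)
  set.seed(1); W1 <- init_weights(cfg)
  set.seed(1); W2 <- init_weights(cfg)
  expect_identical(W1, W2)
  expect_equal(dim(W1), c(10 + 1 + 4 + 1, 3))

  big <- learner_config(n_verbs = 1000, init_range = 0.5)
  set.seed(2)
  w <- as.vector(init_weights(big))  # > 3000 draws
  expect_true(all(w >= -0.5 & w <= 0.5))
  ks <- suppressWarnings(ks.test(w, "punif", -0.5, 0.5))
  expect_gt(ks$p.value, 1e-4)

  zero <- learner_config(n_verbs = 4, init_range = 0)
  set.seed(3)
  W0 <- init_weights(zero)
  expect_true(all(W0 == 0))
  expect_equal(unname(judge_verb(W0, 2, rep(0.3, 4), zero)), rep(1 / 3, 3))
})

test_that("encode_input lays out lexical one-hot, causative bit, semantics, bias", {
  cfg <- learner_config(n_verbs = 5)
  x <- encode_input(1, 1, c(0, 0, 0, 0), cfg)
  expect_equal(which(x != 0), c(1, 6, 11))  # lexical, causative, bias
  x2 <- encode_input(3, 0, c(0.2, 0.4, 0.6, 0.8), cfg)
  expect_equal(x2, c(0, 0, 1, 0, 0, 0, 0.2, 0.4, 0.6, 0.8, 1))
  # two verbs with identical semantics differ in exactly the two lexical slots
  x3 <- encode_input(4, 0, c(0.2, 0.4, 0.6, 0.8), cfg)
  expect_equal(which(x2 != x3), c(3, 4))
  expect_gte(sum(encode_input(2, 0, rep(0, 4), cfg) != 0), 2)
  expect_error(encode_input(6, 1, rep(0.5, 4), cfg), "out of range")
})

test_that("forward_pass is a softmax: positive, normalized, shift-invariant", {
  cfg <- learner_config(n_verbs = 4)
  set.seed(5)
  W <- init_weights(cfg)
  x <- encode_input(2, 1, runif(4), cfg)
  y <- forward_pass(W, x)
  net <- drop(crossprod(W, x))
  expect_equal(y, exp(net) / sum(exp(net)), ignore_attr = TRUE)
  expect_equal(sum(y), 1, tolerance = 1e-12)
  expect_true(all(y > 0))
  # adding a constant to every output's net input (via the always-on bias
  # unit) changes nothing: softmax shift invariance
  xb <- encode_input(2, 1, rep(0, 4), cfg)
  Wb <- W; Wb[nrow(Wb), ] <- Wb[nrow(Wb), ] + 2.5
  expect_equal(forward_pass(Wb, xb), forward_pass(W, xb), tolerance = 1e-12)
})

test_that("delta_update matches the brute-force update equation", {
  cfg <- learner_config(n_verbs = 4)
  set.seed(6)
  W <- init_weights(cfg)
  x <- encode_input(3, 1, runif(4), cfg)
  eta <- 0.05; lam <- 0.3
  W2 <- delta_update(W, x, "MORE", eta, lam)
  y <- forward_pass(W, x)
  t <- c(0, 1, 0)
  manual <- W
  for (i in seq_along(x)) for (j in 1:3)
    manual[i, j] <- W[i, j] + eta * ((t[j] - y[j]) * x[i] - lam * W[i, j])
  expect_equal(W2, manual, tolerance = 1e-12)

  # zero input with no decay leaves the weights untouched
  expect_equal(delta_update(W, numeric(length(x)), "LESS", eta, 0), W)
  # if the prediction is already exact, the error term vanishes
  Wdeg <- matrix(0, length(x), 3)
  ydeg <- forward_pass(Wdeg, x)
  Wup <- delta_update(Wdeg, x, "OTHER", eta, 0)
  expect_equal(Wup[, 3] - Wdeg[, 3], eta * (1 - 1 / 3) * x, tolerance = 1e-12)
  expect_error(delta_update(W, x, "BOGUS", eta, 0), "invalid target")
})

test_that("compiled and reference training engines agree draw for draw", {
  inp <- tiny_fit_inputs(n_verbs = 6, seed = 3)
  cfg <- learner_config(n_verbs = 6, epochs = 3, utterances_per_epoch = 150,
                        n_runs = 1)
  sem <- retreat:::unit_matrix(inp$profiles)
  sem <- sem[match(inp$counts$verb, rownames(sem)), ]
  set.seed(10); W0 <- init_weights(cfg)
  set.seed(20); rc <- train_run(W0, inp$counts, sem, cfg, engine = "C")
  set.seed(20); rr <- train_run(W0, inp$counts, sem, cfg, engine = "R")
  expect_equal(rc$W, rr$W, tolerance = 1e-12)
  expect_equal(rc$activations, rr$activations, tolerance = 1e-12)
})

test_that("training is reproducible and inert at eta -> 0^+ or zero epochs of data", {
  inp <- tiny_fit_inputs(n_verbs = 5, seed = 2)
  cfg <- learner_config(n_verbs = 5, epochs = 2, utterances_per_epoch = 100,
                        n_runs = 2, eta = 1e-12, decay = 0)
  f1 <- causative_learner(inp$counts, inp$profiles, cfg, seed = 9)
  f2 <- causative_learner(inp$counts, inp$profiles, cfg, seed = 9)
  expect_identical(f1$predictions, f2$predictions)
  # eta ~ 0: final weights stay at initialization
  set.seed(9 + 1)
  expect_equal(f1$weights[[1]], init_weights(cfg), tolerance = 1e-9,
               ignore_attr = TRUE)
  # record count: runs x (epochs + pre-training snapshot) x verbs
  expect_equal(nrow(f1$predictions), 2 * 3 * 5)
})

test_that("every prediction record is softmax-normalized and judging is idempotent", {
  inp <- tiny_fit_inputs(n_verbs = 6, seed = 8)
  cfg <- learner_config(n_verbs = 6, epochs = 4, utterances_per_epoch = 500,
                        n_runs = 3)
  fit <- causative_learner(inp$counts, inp$profiles, cfg, seed = 3)
  s <- with(fit$predictions, act_less + act_more + act_other)
  expect_true(all(abs(s - 1) < 1e-9))
  W <- fit$weights[[2]]
  sem <- fit$semantics[4, ]
  expect_identical(judge_verb(W, 4, sem, cfg), judge_verb(W, 4, sem, cfg))
  expect_equal(judge_verb(W, 4, sem, cfg),
               forward_pass(W, encode_input(4, 1, sem, cfg)),
               ignore_attr = TRUE)
})

test_that("untrained ensembles judge near-uniformly for small init_range", {
  inp <- tiny_fit_inputs(n_verbs = 6, seed = 12)
  cfg <- learner_config(n_verbs = 6, epochs = 1, utterances_per_epoch = 1,
                        n_runs = 40, init_range = 0.05)
  fit <- causative_learner(inp$counts, inp$profiles, cfg, seed = 5)
  ep0 <- ensemble_means(fit, epoch = 0)
  expect_equal(mean(ep0$act_less), 1 / 3, tolerance = 0.02)
  expect_equal(mean(ep0$act_more), 1 / 3, tolerance = 0.02)
  expect_equal(mean(ep0$act_other), 1 / 3, tolerance = 0.02)
})

test_that("activations converge to the conditional form frequencies (lambda = 0)", {
  # two verbs with opposite causative splits; judged activations over the
  # causative pair must approach each verb's empirical P(form | verb,
  # causative).  The ensemble mean is the converged estimate: a single run
  # fluctuates around the fixed point at a scale set by the constant eta.
  counts <- data.frame(verb = c("a", "b"), n_less = c(300, 60),
                       n_more = c(100, 140), n_other = c(400, 200))
  prof <- flat_profiles(counts$verb)
  cfg <- learner_config(n_verbs = 2, epochs = 50, utterances_per_epoch = 10000,
                        n_runs = 8, eta = 0.01, decay = 0)
  fit <- causative_learner(counts, prof, cfg, seed = 11)
  fin <- fitted(fit)
  for (v in counts$verb) {
    row <- counts[counts$verb == v, ]
    target <- row$n_less / (row$n_less + row$n_more)
    got <- with(fin[fin$verb == v, ], act_less / (act_less + act_more))
    expect_lt(abs(got - target), 0.02)
  }
})

test_that("stronger weight decay weakly shrinks judgment confidence", {
  counts <- data.frame(verb = c("a", "b"), n_less = c(400, 20),
                       n_more = c(40, 200), n_other = c(300, 300))
  prof <- flat_profiles(counts$verb)
  maxact <- sapply(c(0, 2, 10), function(lam) {
    cfg <- learner_config(n_verbs = 2, epochs = 10, utterances_per_epoch = 5000,
                          n_runs = 1, eta = 0.02, decay = lam)
    mean(apply(fitted(causative_learner(counts, prof, cfg, seed = 4))[
      , c("act_less", "act_more", "act_other")], 1, max))
  })
  expect_true(all(diff(maxact) <= 1e-6))
})

test_that("split-half trains on one half and judges the held-out half via shared weights", {
  inp <- tiny_fit_inputs(n_verbs = 8, seed = 6)
  # decay = 0 so untrained weights sit exactly at initialization (with decay
  # they additionally shrink by the decay factor, never receiving error terms)
  cfg <- learner_config(n_verbs = 8, epochs = 2, utterances_per_epoch = 300,
                        n_runs = 2, decay = 0)
  fit <- causative_learner(inp$counts, inp$profiles, cfg, seed = 2,
                           split_half = TRUE)
  expect_length(fit$train_verbs, 4)
  expect_length(fit$judged_verbs, 4)
  expect_setequal(c(fit$train_verbs, fit$judged_verbs), inp$counts$verb)
  # held-out lexical weights never move from their initialization
  set.seed(2 + 1)
  W0 <- init_weights(cfg)
  held_idx <- match(fit$judged_verbs, inp$counts$verb)
  expect_equal(fit$weights[[1]][held_idx, ], W0[held_idx, ],
               tolerance = 1e-12, ignore_attr = TRUE)

  # with init_range -> 0, held-out verbs with identical semantics get
  # identical predictions (only causative/semantic/bias weights speak)
  counts <- data.frame(verb = c("t1", "t2", "h1", "h2"),
                       n_less = c(200, 50, 10, 10), n_more = c(20, 150, 10, 10),
                       n_other = c(100, 100, 10, 10))
  prof <- flat_profiles(counts$verb, value = 0.5)
  cfg0 <- learner_config(n_verbs = 4, epochs = 2, utterances_per_epoch = 500,
                         n_runs = 1, init_range = 0)
  # force the held-out half to be h1/h2 by trying seeds until found
  for (s in 1:50) {
    f <- causative_learner(counts, prof, cfg0, seed = s, split_half = TRUE)
    if (setequal(f$judged_verbs, c("h1", "h2"))) break
  }
  if (setequal(f$judged_verbs, c("h1", "h2"))) {
    fin <- fitted(f)
    expect_equal(fin[fin$verb == "h1", c("act_less", "act_more", "act_other")],
                 fin[fin$verb == "h2", c("act_less", "act_more", "act_other")],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(causative_learner(counts[1, ], flat_profiles("t1"),
                                 learner_config(n_verbs = 1), seed = 1,
                                 split_half = TRUE),
               "too small to split")
})

test_that("predict() on novel semantic profiles uses semantics alone", {
  inp <- tiny_fit_inputs(n_verbs = 6, seed = 14)
  cfg <- learner_config(n_verbs = 6, epochs = 3, utterances_per_epoch = 1000,
                        n_runs = 2)
  fit <- causative_learner(inp$counts, inp$profiles, cfg, seed = 8)
  novel <- flat_profiles(c("new_hi", "new_lo"))
  novel[novel$verb == "new_hi", -1] <- 0.95
  novel[novel$verb == "new_lo", -1] <- 0.05
  p <- predict(fit, novel)
  expect_equal(nrow(p), 2)
  expect_equal(p$act_less + p$act_more + p$act_other, c(1, 1), tolerance = 1e-9)
  # identical profiles give identical predictions
  twin <- flat_profiles(c("x", "y"), value = 0.4)
  pt <- predict(fit, twin)
  expect_equal(pt$diff[1], pt$diff[2], tolerance = 1e-12)
})
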