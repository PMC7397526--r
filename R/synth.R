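#' Specification of the synthetic study
#'
#' Collects every parameter of the synthetic-data generator, which emulates
#' the three empirical inputs of the analysis — per-verb construction counts
#' from a corpus, multi-rater semantic ratings, and 5-point grammaticality
#' judgments — with the statistical structure the analysis assumes: Zipfian
#' verb frequencies, a semantics-linked logistic allocation of causative
#' tokens between the two causative structures, rater noise around a latent
#' event-merge value, and judgments driven by semantics plus a corpus
#' frequency bias.
#'
#' @param n_verbs lexicon size (default 60).
#' @param n_raters semantic raters per scale (default 20).
#' @param n_participants judgment participants per age group (default 48).
#' @param corpus_tokens total corpus size in tokens (default 2e6, the scale
#'   of a large conversational corpus).
#' @param zipf_exponent s: verb totals proportional to rank^(-s)
#'   (default 1).
#' @param p_causative probability a token of any verb is causative
#'   (default 0.1).
#' @param beta0,beta_sem intercept and slope of the logistic link from the
#'   latent event-merge value m to the probability that a causative token
#'   takes the less-transparent form: P(LESS | causative) =
#'   plogis(beta0 + beta_sem * m) (defaults 0 and 6: high-merge verbs are
#'   strongly less-transparent-biased, and the corpus as a whole prefers the
#'   less-transparent causative, as English does).
#' @param rater_noise_sd SD of the Gaussian rater noise on the 0-1 latent
#'   scale (default 0.1); also used for the subsidiary semantic latents.
#' @param gamma_sem,gamma_freq weights of the semantic and frequency-bias
#'   terms in the judgment generator (defaults 2 and 1).
#' @param judgment_noise_sd SD of per-participant judgment noise
#'   (default 0.5).
#' @return An object of class \code{"synth_spec"} (validated list).
#' @export
synth_spec <- function(n_verbs = 60L, n_raters = 20L, n_participants = 48L,
                       corpus_tokens = 2e6, zipf_exponent = 1,
                       p_causative = 0.1, beta0 = 0, beta_sem = 6,
                       rater_noise_sd = 0.1, gamma_sem = 2, gamma_freq = 1,
                       judgment_noise_sd = 0.5) {
  spec <- list(n_verbs = as.integer(n_verbs), n_raters = as.integer(n_raters),
               n_participants = as.integer(n_participants),
               corpus_tokens = corpus_tokens, zipf_exponent = zipf_exponent,
               p_causative = p_causative, beta0 = beta0, beta_sem = beta_sem,
               rater_noise_sd = rater_noise_sd, gamma_sem = gamma_sem,
               gamma_freq = gamma_freq, judgment_noise_sd = judgment_noise_sd)
  if (spec$n_verbs < 2 || spec$n_raters < 1 || spec$n_participants < 1)
    stop("n_verbs must be >= 2 and rater/participant counts >= 1")
  if (spec$corpus_tokens <= 0) stop("corpus_tokens must be positive")
  if (spec$p_causative <= 0 || spec$p_causative >= 1)
    stop("p_causative must lie in (0, 1)")
  if (spec$rater_noise_sd < 0 || spec$judgment_noise_sd < 0)
    stop("noise SDs must be >= 0")
  structure(spec, class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("Synthetic study specification\n")
  cat(sprintf("  %d verbs, %d raters/scale, %d participants/group\n",
              x$n_verbs, x$n_raters, x$n_participants))
  cat(sprintf("  corpus: %g tokens, Zipf s = %g, P(causative) = %g, allocation plogis(%g + %g m)\n",
              x$corpus_tokens, x$zipf_exponent, x$p_causative, x$beta0, x$beta_sem))
  cat(sprintf("  noise: rater %g; judgments gamma_sem = %g, gamma_freq = %g, noise %g\n",
              x$rater_noise_sd, x$gamma_sem, x$gamma_freq, x$judgment_noise_sd))
  invisible(x)
}

verb_labels <- function(n) sprintf("v%02d", seq_len(n))

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate latent verb semantics
#'
#' Draws the latent event-merge value m of every verb i.i.d. uniform on
#' (0, 1) and derives three subsidiary latents (autonomy, directive,
#' requires) as m plus Gaussian noise, clipped to [0, 1] — deliberately
#' highly collinear with the main scale, as empirical semantic predictors
#' are.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param seed optional seed; \code{NULL} uses the current RNG state.
#' @return Data frame \code{verb}, \code{event_merge}, \code{autonomy},
#'   \code{directive}, \code{requires}, values in [0, 1].
#' @export
gen_latent_semantics <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- spec$n_verbs
  m <- runif(n)
  sub <- function() clip01(m + rnorm(n, 0, spec$rater_noise_sd))
  data.frame(verb = verb_labels(n), event_merge = m, autonomy = sub(),
             directive = sub(), requires = sub(),
             stringsAsFactors = FALSE)
}

#' Generate a rater-level semantic rating table
#'
#' Each of \code{n_raters} raters positions each verb on each 0-100 analogue
#' scale at 100 times the (clipped) latent value plus Gaussian noise.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param latents output of \code{\link{gen_latent_semantics}}.
#' @param seed optional seed.
#' @return Data frame \code{rater}, \code{verb}, \code{scale}, \code{value};
#'   one row per (rater, verb, scale).
#' @export
gen_ratings <- function(spec, latents, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  scales <- SEMANTIC_SCALES
  latent_cols <- c("event_merge", "autonomy", "directive", "requires")
  grid <- expand.grid(rater = seq_len(spec$n_raters), verb = latents$verb,
                      scale = scales, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  lat <- unlist(latents[latent_cols])[
    (match(grid$scale, scales) - 1L) * spec$n_verbs +
      match(grid$verb, latents$verb)]
  grid$value <- 100 * clip01(lat + rnorm(nrow(grid), 0, spec$rater_noise_sd))
  grid
}

zipf_totals <- function(spec) {
  w <- seq_len(spec$n_verbs)^(-spec$zipf_exponent)
  pmax(1L, round(spec$corpus_tokens * w / sum(w)))
}

#' Generate a per-verb construction-count table
#'
#' Verb token totals follow a Zipfian law over frequency rank; each token is
#' causative with probability \code{p_causative}; each causative token takes
#' the less-transparent form with probability
#' \code{plogis(beta0 + beta_sem * m)}, so a verb's construction bias is
#' driven by its latent event-merge semantics; all remaining tokens are
#' non-causative uses.
#'
#' @inheritParams gen_ratings
#' @return Data frame \code{verb}, \code{n_less}, \code{n_more},
#'   \code{n_other}; per verb the three counts sum to its Zipfian total.
#' @export
gen_counts <- function(spec, latents, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  tot <- zipf_totals(spec)
  caus <- rbinom(spec$n_verbs, tot, spec$p_causative)
  p_less <- stats::plogis(spec$beta0 + spec$beta_sem * latents$event_merge)
  less <- rbinom(spec$n_verbs, caus, p_less)
  data.frame(verb = latents$verb, n_less = less, n_more = caus - less,
             n_other = tot - caus, stringsAsFactors = FALSE)
}

#' With-replacement utterance sampler over corpus counts
#'
#' Returns a sampler function drawing utterance tokens with probability
#' proportional to the count cells; tokens carry the verb, the construction
#' form and the derived causative flag (1 unless the form is OTHER).  The
#' sampler consumes the ambient RNG stream, so prefixes are reproducible
#' under \code{set.seed()}.
#'
#' @param counts construction-count table.
#' @return \code{function(n)} returning a data frame \code{verb},
#'   \code{form}, \code{causative} with \code{n} rows.
#' @export
gen_stream <- function(counts) {
  counts <- validate_counts(counts)
  probs <- cell_probabilities(counts)
  cum <- cumsum(probs)
  cum[length(cum)] <- 1
  verbs <- counts$verb
  function(n) {
    cell <- findInterval(runif(n), cum, left.open = TRUE) + 1L
    form <- FORMS[(cell - 1L) %% 3L + 1L]
    data.frame(verb = verbs[(cell - 1L) %/% 3L + 1L], form = form,
               causative = as.integer(form != "OTHER"),
               stringsAsFactors = FALSE)
  }
}

#' Empirical allocation bias of each verb
#'
#' The signed log-odds of the less- vs the more-transparent causative for
#' each verb, relative to the base rate over the remaining verbs, with +0.5
#' smoothing per cell so zero cells stay finite.  This is the frequency-bias
#' term b(v) of the judgment generator and the generative quantity the
#' corpus predictors are expected to track.
#'
#' @param counts construction-count table.
#' @return Numeric vector, one signed log-odds value per verb.
#' @export
allocation_bias <- function(counts) {
  l <- counts$n_less; m <- counts$n_more
  log((l + 0.5) / (m + 0.5)) -
    log((sum(l) - l + 0.5) / (sum(m) - m + 0.5))
}

#' Generate a grammaticality-judgment table
#'
#' Each participant's latent acceptability for a verb in the LESS sentence
#' type is \code{gamma_sem * (m - 1/2) + gamma_freq * b + noise}, where m is
#' the verb's latent event-merge value and b its smoothed signed log-odds of
#' LESS vs MORE in the corpus relative to the base rate; for the MORE
#' sentence type the semantic term is negated.  The latent is discretized to
#' the 1-5 scale by equal-width thresholds over its deterministic range
#' (noise spilling past the ends is clipped into the extreme categories).
#'
#' @inheritParams gen_ratings
#' @param counts construction-count table the frequency bias is computed
#'   from.
#' @param age_group label(s) for the generated group(s); groups share the
#'   generator.
#' @return Data frame \code{participant}, \code{age_group}, \code{verb},
#'   \code{sentence_type}, \code{rating} with
#'   \code{n_participants * n_verbs * 2} rows per group.
#' @export
gen_judgments <- function(spec, latents, counts, seed = NULL,
                          age_group = "adult") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  b <- allocation_bias(counts)
  m <- latents$event_merge[match(counts$verb, latents$verb)]
  half_range <- spec$gamma_sem * 0.5 + spec$gamma_freq * max(abs(b))
  one_group <- function(group) {
    grid <- expand.grid(participant = seq_len(spec$n_participants),
                        verb = counts$verb, sentence_type = c("LESS", "MORE"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(grid$verb, counts$verb)
    sem_sign <- ifelse(grid$sentence_type == "LESS", 1, -1)
    latent <- sem_sign * spec$gamma_sem * (m[i] - 0.5) +
      spec$gamma_freq * b[i] +
      rnorm(nrow(grid), 0, spec$judgment_noise_sd)
    rating <- if (half_range == 0) rep(3L, nrow(grid))
              else pmin(5L, pmax(1L, 1L + floor(5 * (latent + half_range) /
                                                  (2 * half_range))))
    data.frame(participant = paste0(group, "_p", grid$participant),
               age_group = group, verb = grid$verb,
               sentence_type = grid$sentence_type, rating = as.integer(rating),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(age_group, one_group))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running the four generators with seeds derived from
#' one master seed (latents: seed; ratings: seed + 1; counts: seed + 2;
#' judgments: seed + 3) and aggregating the ratings into semantic profiles.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param seed master seed.
#' @return List with \code{latents}, \code{ratings}, \code{counts},
#'   \code{judgments}, \code{profiles} and the \code{spec} and \code{seed}
#'   used.
#' @export
synth_dataset <- function(spec = synth_spec(), seed = 1L) {
  seed <- as.integer(seed)
  latents <- gen_latent_semantics(spec, seed = seed)
  ratings <- gen_ratings(spec, latents, seed = seed + 1L)
  counts <- gen_counts(spec, latents, seed = seed + 2L)
  judgments <- gen_judgments(spec, latents, counts, seed = seed + 3L)
  list(latents = latents, ratings = ratings, counts = counts,
       judgments = judgments, profiles = semantic_profiles(ratings),
       spec = spec, seed = seed)
}

#' Designed corpus for the overgeneralization-then-retreat trajectory
#'
#' Builds a small deterministic corpus with two semantic clusters: frequent
#' verbs with high event-merge semantics attested only in the
#' less-transparent causative (which therefore dominates causative tokens
#' corpus-wide), and less frequent low-merge verbs attested only in the
#' more-transparent causative.  One designated low-frequency target verb has
#' high-merge (LESS-cluster) semantics but all of its causative tokens in
#' the MORE form.  Early in training, shared causative and semantic weights
#' pull the target's LESS activation up with its semantic cluster; its own
#' lexical evidence then pulls it back down — the overgeneralization-then-
#' retreat pattern reported for verbs like \emph{come}, \emph{cry} and
#' \emph{laugh}.
#'
#' @param n_cluster verbs per semantic cluster (default 10).
#' @return List with \code{counts}, \code{profiles} (unit activations built
#'   directly from the designed latent values), \code{latents} and
#'   \code{target}, the label of the designed verb.
#' @export
overgeneralization_corpus <- function(n_cluster = 10L) {
  n <- 2L * n_cluster + 1L
  verbs <- verb_labels(n)
  m <- c(seq(0.75, 0.95, length.out = n_cluster),   # LESS cluster, frequent
         seq(0.05, 0.25, length.out = n_cluster),   # MORE cluster
         0.9)                                       # target: LESS semantics
  tot <- c(round(3000 / seq_len(n_cluster)),        # Zipf-ish within cluster
           round(800 / seq_len(n_cluster)), 150)
  caus <- round(0.5 * tot)
  less <- c(caus[seq_len(n_cluster)], integer(n_cluster), 0L)
  counts <- data.frame(verb = verbs, n_less = less, n_more = caus - less,
                       n_other = tot - caus, stringsAsFactors = FALSE)
  unit <- data.frame(verb = verbs, event_merge_unit = m, autonomy_unit = m,
                     directive_unit = m, requires_unit = m,
                     stringsAsFactors = FALSE)
  list(counts = counts, profiles = unit,
       latents = data.frame(verb = verbs, event_merge = m,
                            stringsAsFactors = FALSE),
       target = verbs[n])
}
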