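#' Fit an ensemble of discriminative causative learners
#'
#' The central model of the package.  Each of \code{config$n_runs} model runs
#' (one per simulated participant) is independently initialized and trained
#' online on utterances sampled with replacement from the corpus counts: the
#' input encodes the verb's identity, whether the utterance conveys causation
#' and the verb's four semantic activations; the target is the utterance's
#' construction form (less-transparent causative, more-transparent causative,
#' or other).  After every epoch each run is probed with learning switched
#' off and the causative unit set to 1; the softmax activations of the three
#' output units are its graded acceptability judgment for the verb.
#'
#' With \code{split_half = TRUE} the lexicon is randomly partitioned in two;
#' utterances are sampled only from the training half while judgments are
#' extracted for the held-out half, whose lexical weights stay at their
#' initial values — held-out predictions are carried entirely by the
#' causative, semantic and bias weights, probing semantics-driven
#' generalization to unseen verbs.
#'
#' Run \code{r} uses seed \code{seed + r}, so the whole ensemble is
#' bit-reproducible from the master seed.
#'
#' @param counts construction-count table: columns \code{verb},
#'   \code{n_less}, \code{n_more}, \code{n_other} (one row per verb).
#' @param profiles semantic profile table from
#'   \code{\link{semantic_profiles}} (needs the \code{*_unit} columns), with
#'   the same verb set as \code{counts}.
#' @param config a \code{\link{learner_config}}; \code{n_verbs} is taken
#'   from \code{counts}.
#' @param seed master seed for the ensemble.
#' @param split_half logical: train on a random half of the lexicon and
#'   judge the held-out half.
#' @param engine \code{"C"} (compiled) or \code{"R"} (reference
#'   implementation).
#' @return An object of class \code{"causative_learner"}: a list with
#'   \code{predictions} (data frame \code{run}, \code{epoch} (0 =
#'   pre-training), \code{verb}, \code{act_less}, \code{act_more},
#'   \code{act_other}), \code{weights} (list of final weight matrices, one
#'   per run), \code{config}, \code{verbs}, \code{judged_verbs},
#'   \code{train_verbs}, \code{seed}, \code{split_half}.
#' @examples
#' data <- synth_dataset(synth_spec(n_verbs = 12, corpus_tokens = 5e4), seed = 1)
#' fit <- causative_learner(data$counts, data$profiles,
#'                          learner_config(n_verbs = 12, epochs = 5,
#'                                         utterances_per_epoch = 2000,
#'                                         n_runs = 4),
#'                          seed = 1)
#' fit
#' head(fitted(fit))
#' @export
causative_learner <- function(counts, profiles, config = learner_config(),
                              seed = 1L, split_half = FALSE,
                              engine = c("C", "R")) {
  engine <- match.arg(engine)
  counts <- validate_counts(counts)
  config$n_verbs <- nrow(counts)
  if (config$n_verbs < 2 && split_half)
    stop("lexicon too small to split: need at least 2 verbs")
  sem <- unit_matrix(profiles)
  if (!setequal(rownames(sem), counts$verb))
    stop("counts and profiles cover different verb sets")
  sem <- sem[match(counts$verb, rownames(sem)), , drop = FALSE]
  if (ncol(sem) != config$n_semantic)
    stop("profiles carry ", ncol(sem), " semantic scales; config expects ",
         config$n_semantic)

  train_verbs <- judge_verbs <- seq_len(config$n_verbs)
  if (split_half) {
    set.seed(as.integer(seed))
    train_verbs <- sort(sample(config$n_verbs, config$n_verbs %/% 2L))
    judge_verbs <- setdiff(seq_len(config$n_verbs), train_verbs)
  }

  runs <- vector("list", config$n_runs)
  weights <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    set.seed(as.integer(seed) + r)
    W0 <- init_weights(config)
    res <- train_run(W0, counts, sem, config, judge_verbs = judge_verbs,
                     train_verbs = if (split_half) train_verbs else NULL,
                     engine = engine)
    weights[[r]] <- res$W
    a <- res$activations
    runs[[r]] <- data.frame(
      run = r,
      epoch = rep(0:config$epochs, each = length(judge_verbs)),
      verb = rep(counts$verb[judge_verbs], config$epochs + 1L),
      act_less = as.vector(a[, 1L, ]),
      act_more = as.vector(a[, 2L, ]),
      act_other = as.vector(a[, 3L, ]),
      stringsAsFactors = FALSE
    )
  }

  structure(list(
    predictions = do.call(rbind, runs),
    weights = weights,
    config = config,
    verbs = counts$verb,
    judged_verbs = counts$verb[judge_verbs],
    train_verbs = counts$verb[train_verbs],
    semantics = sem,
    seed = as.integer(seed),
    split_half = split_half,
    engine = engine
  ), class = "causative_learner")
}

#' Ensemble-mean activations per verb and epoch
#'
#' Averages the prediction records over runs, the model analogue of taking
#' the mean judgment across participants.
#'
#' @param object a \code{\link{causative_learner}} fit.
#' @param epoch epochs to keep (default all).
#' @return Data frame \code{epoch}, \code{verb}, \code{act_less},
#'   \code{act_more}, \code{act_other}, \code{diff} (more minus less).
#' @export
ensemble_means <- function(object, epoch = NULL) {
  p <- object$predictions
  if (!is.null(epoch)) p <- p[p$epoch %in% epoch, ]
  agg <- aggregate(p[c("act_less", "act_more", "act_other")],
                   by = list(epoch = p$epoch, verb = p$verb), FUN = mean)
  agg <- agg[order(agg$epoch, match(agg$verb, object$judged_verbs)), ]
  agg$diff <- agg$act_more - agg$act_less
  rownames(agg) <- NULL
  agg
}

#' @export
print.causative_learner <- function(x, ...) {
  cfg <- x$config
  cat("Ensemble of discriminative causative learners\n")
  cat(sprintf("  %d runs x %d epochs x %d utterances over %d verbs (seed %d, %s engine)\n",
              cfg$n_runs, cfg$epochs, cfg$utterances_per_epoch, cfg$n_verbs,
              x$seed, x$engine))
  if (x$split_half)
    cat(sprintf("  split-half: trained on %d verbs, judging %d held-out verbs\n",
                length(x$train_verbs), length(x$judged_verbs)))
  fin <- ensemble_means(x, epoch = cfg$epochs)
  cat(sprintf("  final-epoch mean activations: LESS %.3f, MORE %.3f, OTHER %.3f\n",
              mean(fin$act_less), mean(fin$act_more), mean(fin$act_other)))
  invisible(x)
}

#' @export
summary.causative_learner <- function(object, ...) {
  fin <- ensemble_means(object, epoch = object$config$epochs)
  structure(list(fit = object, final = fin), class = "summary.causative_learner")
}

#' @export
print.summary.causative_learner <- function(x, ...) {
  print(x$fit)
  cat("\nFinal-epoch ensemble-mean judgments (causative unit on):\n")
  fin <- x$final
  ord <- order(fin$diff)
  print(data.frame(verb = fin$verb, act_less = round(fin$act_less, 3),
                   act_more = round(fin$act_more, 3),
                   act_other = round(fin$act_other, 3),
                   diff = round(fin$diff, 3))[ord, ], row.names = FALSE)
  invisible(x)
}

#' @export
#' @describeIn causative_learner ensemble-mean final weight matrix.
coef.causative_learner <- function(object, ...) {
  Reduce(`+`, object$weights) / length(object$weights)
}

#' @export
#' @describeIn causative_learner final-epoch ensemble-mean activations per verb.
fitted.causative_learner <- function(object, ...) {
  ensemble_means(object, epoch = object$config$epochs)
}

#' Judgments from a fitted learner ensemble
#'
#' Probes the final-epoch weights of every run with the causative unit set to
#' 1 and learning off, and averages the activations over runs.  With
#' \code{newdata}, semantic profiles for arbitrary (possibly novel) verbs are
#' judged through the causative, semantic and bias weights alone, the lexical
#' block contributing nothing — the package's account of generalizing to a
#' verb never encountered in the corpus.
#'
#' @param object a \code{\link{causative_learner}} fit.
#' @param newdata optional profile table (\code{\link{semantic_profiles}}
#'   output) of verbs to judge through semantics alone; default: the fitted
#'   lexicon's judged verbs.
#' @param ... unused.
#' @return Data frame \code{verb}, \code{act_less}, \code{act_more},
#'   \code{act_other}, \code{diff}.
#' @export
predict.causative_learner <- function(object, newdata = NULL, ...) {
  cfg <- object$config
  if (is.null(newdata)) return(fitted(object)[-1L])
  sem <- unit_matrix(newdata)
  acts <- matrix(0, nrow(sem), 3L)
  for (W in object$weights) {
    Wsem <- W[(cfg$n_verbs + 1L):nrow(W), , drop = FALSE]  # causative, sem, bias
    net <- cbind(1, sem, 1) %*% Wsem
    e <- exp(net - apply(net, 1L, max))
    acts <- acts + e / rowSums(e)
  }
  acts <- acts / length(object$weights)
  data.frame(verb = rownames(sem), act_less = acts[, 1L],
             act_more = acts[, 2L], act_other = acts[, 3L],
             diff = acts[, 2L] - acts[, 1L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Plot activation trajectories of a fitted learner ensemble
#'
#' Draws the ensemble-mean activation of one output form per epoch, one line
#' per verb (base graphics), the package's version of the developmental
#' trajectory panels: watch a form's acceptability rise, overshoot and
#' retreat as evidence accumulates.
#'
#' @param x a \code{\link{causative_learner}} fit.
#' @param form which output unit to plot: \code{"LESS"}, \code{"MORE"},
#'   \code{"OTHER"} or \code{"DIFF"} (more minus less).
#' @param verbs verbs to include (default: all judged).
#' @param ... passed to \code{matplot}.
#' @return Invisibly, the epoch-by-verb matrix plotted.
#' @export
plot.causative_learner <- function(x, form = c("DIFF", "LESS", "MORE", "OTHER"),
                                   verbs = NULL, ...) {
  form <- match.arg(form)
  m <- ensemble_means(x)
  col <- switch(form, DIFF = "diff", LESS = "act_less", MORE = "act_more",
                OTHER = "act_other")
  if (is.null(verbs)) verbs <- x$judged_verbs
  traj <- sapply(verbs, function(v) m[m$verb == v, col])
  graphics::matplot(unique(m$epoch), traj, type = "l", lty = 1,
                    xlab = "epoch", ylab = paste(form, "activation"), ...)
  invisible(traj)
}
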