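#' @keywords internal
FORMS <- c("LESS", "MORE", "OTHER")

#' Configuration of the discriminative learner
#'
#' The model is a single-layer network: an input vector of \code{n_verbs}
#' orthogonal lexical units (1/0), one causative unit (1/0), \code{n_semantic}
#' continuous semantic units (0-1) and a constant bias, fully connected to
#' three softmax output units representing the construction form of the
#' utterance (less-transparent causative, more-transparent causative, other).
#' Training is online: each epoch presents \code{utterances_per_epoch} corpus
#' tokens sampled with replacement, each triggering one Widrow-Hoff delta-rule
#' update.  An ensemble of \code{n_runs} independently initialized and
#' independently sampled models plays the role of a participant group.
#'
#' @param n_verbs lexicon size (default 60).
#' @param n_semantic number of continuous semantic units (default 4).
#' @param epochs training epochs; judgments are extracted after each
#'   (default 50).
#' @param utterances_per_epoch tokens sampled per epoch (default 10000).
#' @param n_runs ensemble size (default 48, one model per simulated
#'   participant).
#' @param eta learning rate, > 0 (default 0.01).
#' @param decay weight-decay strength \code{lambda} >= 0 (default 0.5); the
#'   per-update pull is \code{lambda / utterances_per_epoch}, so a whole epoch
#'   applies the full \code{lambda}-scaled shrinkage.
#' @param init_range half-width of the uniform initial-weight distribution
#'   (default 0.5).
#' @return An object of class \code{"learner_config"} (a validated list).
#' @export
learner_config <- function(n_verbs = 60L, n_semantic = 4L, epochs = 50L,
                           utterances_per_epoch = 10000L, n_runs = 48L,
                           eta = 0.01, decay = 0.5, init_range = 0.5) {
  cfg <- list(n_verbs = as.integer(n_verbs), n_semantic = as.integer(n_semantic),
              n_outputs = 3L, epochs = as.integer(epochs),
              utterances_per_epoch = as.integer(utterances_per_epoch),
              n_runs = as.integer(n_runs), eta = eta, decay = decay,
              init_range = init_range)
  counts <- c(cfg$n_verbs, cfg$n_semantic, cfg$epochs,
              cfg$utterances_per_epoch, cfg$n_runs)
  if (any(is.na(counts)) || any(counts < 1))
    stop("n_verbs, n_semantic, epochs, utterances_per_epoch, n_runs must be positive integers")
  if (!is.finite(cfg$eta) || cfg$eta <= 0) stop("eta must be > 0")
  if (!is.finite(cfg$decay) || cfg$decay < 0) stop("decay must be >= 0")
  if (!is.finite(cfg$init_range) || cfg$init_range < 0)
    stop("init_range must be >= 0")
  structure(cfg, class = "learner_config")
}

#' @export
print.learner_config <- function(x, ...) {
  cat("Discriminative learner configuration\n")
  cat(sprintf("  input: %d lexical + 1 causative + %d semantic + bias -> %d softmax outputs\n",
              x$n_verbs, x$n_semantic, x$n_outputs))
  cat(sprintf("  training: %d runs x %d epochs x %d utterances, eta = %g, decay = %g, init range = %g\n",
              x$n_runs, x$epochs, x$utterances_per_epoch, x$eta, x$decay, x$init_range))
  invisible(x)
}

input_dim <- function(config) config$n_verbs + 1L + config$n_semantic + 1L

#' Initialize a weight matrix
#'
#' Weights are drawn i.i.d. uniform on \code{[-init_range, +init_range]}
#' from the current RNG stream, so results are reproducible under
#' \code{set.seed()}.  With \code{init_range = 0} every judgment is the
#' uniform (1/3, 1/3, 1/3).
#'
#' @param config a \code{\link{learner_config}}.
#' @return Numeric matrix of dimension \code{(n_verbs + n_semantic + 2) x 3}.
#' @export
init_weights <- function(config) {
  d <- input_dim(config)
  matrix(runif(d * config$n_outputs, -config$init_range, config$init_range),
         d, config$n_outputs, dimnames = list(NULL, FORMS))
}

#' Encode one utterance (or judgment probe) as an input vector
#'
#' @param verb 1-based verb index within the lexicon.
#' @param causative 0 or 1: does the utterance convey causation?
#' @param semantics numeric vector of unit-interval semantic activations for
#'   the verb (length \code{config$n_semantic}).
#' @param config a \code{\link{learner_config}}.
#' @return Numeric vector of length \code{input_dim}: one-hot lexical block,
#'   causative bit, semantic activations, constant bias 1.
#' @export
encode_input <- function(verb, causative, semantics, config) {
  if (verb < 1 || verb > config$n_verbs) stop("verb index out of range: ", verb)
  if (length(semantics) != config$n_semantic)
    stop("expected ", config$n_semantic, " semantic activations")
  x <- numeric(input_dim(config))
  x[verb] <- 1
  x[config$n_verbs + 1L] <- as.numeric(causative != 0)
  x[config$n_verbs + 1L + seq_len(config$n_semantic)] <- semantics
  x[length(x)] <- 1
  x
}

#' Softmax output activations for one input
#'
#' @param W weight matrix (inputs x outputs).
#' @param x input vector.
#' @return Activation vector: strictly positive, sums to 1.
#' @export
forward_pass <- function(W, x) {
  if (any(!is.finite(W))) stop("non-finite weights: training diverged")
  net <- drop(crossprod(W, x))
  e <- exp(net - max(net))
  e / sum(e)
}

#' One Widrow-Hoff delta-rule update with weight decay
#'
#' Applies \deqn{W_{ij} \leftarrow W_{ij} + \eta[(t_j - y_j) x_i -
#' \lambda_{step} W_{ij}]} where \code{t} is the one-hot target form and
#' \code{y = forward_pass(W, x)}.  With softmax outputs this is the
#' stochastic gradient of the cross-entropy loss (plus an L2 pull), so under
#' repeated sampling the outputs converge to the conditional form
#' probabilities of the training distribution.
#'
#' @param W weight matrix.
#' @param x input vector.
#' @param target target form: one of \code{"LESS"}, \code{"MORE"},
#'   \code{"OTHER"} (or its 1-based index).
#' @param eta learning rate.
#' @param lambda_step per-update decay (see \code{\link{learner_config}}).
#' @return The updated weight matrix.
#' @export
delta_update <- function(W, x, target, eta, lambda_step = 0) {
  j <- if (is.character(target)) match(toupper(target), FORMS) else as.integer(target)
  if (is.na(j) || j < 1 || j > ncol(W)) stop("invalid target form: ", target)
  y <- forward_pass(W, x)
  t <- numeric(ncol(W)); t[j] <- 1
  W * (1 - eta * lambda_step) + eta * outer(x, t - y)
}

#' Judge a verb: activations with the causative unit on, learning off
#'
#' A pure forward pass on \code{encode_input(verb, causative = 1, ...)}; the
#' activations of the three output units are the model's graded acceptability
#' judgment for the verb's causative forms.  No weights change.
#'
#' @inheritParams encode_input
#' @param W weight matrix.
#' @return Named activation vector over \code{c("LESS", "MORE", "OTHER")}.
#' @export
judge_verb <- function(W, verb, semantics, config) {
  y <- forward_pass(W, encode_input(verb, 1, semantics, config))
  names(y) <- FORMS
  y
}

cell_probabilities <- function(counts, restrict_to = NULL) {
  cells <- rbind(counts$n_less, counts$n_more, counts$n_other)  # 3 x n_verbs
  if (!is.null(restrict_to)) cells[, -restrict_to] <- 0
  tot <- sum(cells)
  if (tot <= 0) stop("all-zero corpus counts: nothing to sample")
  as.vector(cells) / tot  # verb-major order: (less, more, other) per verb
}

#' Train a single model run
#'
#' Runs \code{epochs * utterances_per_epoch} online delta-rule updates on
#' utterances sampled with replacement from the corpus cell counts, and
#' extracts judgments (causative unit = 1, learning off) for the requested
#' verbs after every epoch, plus a pre-training snapshot at epoch 0.  The
#' compiled engine and the reference pure-R engine consume the RNG stream
#' identically, so both are reproducible under \code{set.seed()} and agree
#' with each other.
#'
#' @param W initial weight matrix (see \code{\link{init_weights}}).
#' @param counts construction-count table (columns \code{verb},
#'   \code{n_less}, \code{n_more}, \code{n_other}).
#' @param sem matrix (n_verbs x n_semantic) of unit-interval semantic
#'   activations, rows in the order of \code{counts$verb}.
#' @param config a \code{\link{learner_config}}.
#' @param judge_verbs 1-based indices of the verbs to judge each epoch
#'   (default: all).
#' @param train_verbs 1-based indices of the verbs utterances may be sampled
#'   from (default: all); used for split-half validation.
#' @param engine \code{"C"} (compiled, default) or \code{"R"} (reference).
#' @return List with \code{W} (final weights) and \code{activations}, an
#'   array of dimension (judged verbs) x 3 x (epochs + 1), third dimension
#'   indexed from epoch 0.
#' @export
train_run <- function(W, counts, sem, config, judge_verbs = NULL,
                      train_verbs = NULL, engine = c("C", "R")) {
  engine <- match.arg(engine)
  if (nrow(counts) != config$n_verbs)
    stop("counts rows (", nrow(counts), ") must equal n_verbs (", config$n_verbs, ")")
  if (is.null(judge_verbs)) judge_verbs <- seq_len(config$n_verbs)
  probs <- cell_probabilities(counts, restrict_to = train_verbs)
  if (engine == "C") {
    res <- cpp_train(W, sem, probs, config$eta,
                     config$decay / config$utterances_per_epoch,
                     config$epochs, config$utterances_per_epoch,
                     as.integer(judge_verbs) - 1L)
    acts <- res$activations
  } else {
    res <- r_train(W, sem, probs, config, judge_verbs)
    acts <- res$activations
  }
  if (any(!is.finite(res$W)))
    stop("training diverged to non-finite weights (eta too large?)")
  dimnames(acts) <- list(counts$verb[judge_verbs], FORMS, 0:config$epochs)
  W <- res$W
  dimnames(W) <- list(NULL, FORMS)
  list(W = W, activations = acts)
}

# Reference engine: draw-for-draw identical to the compiled loop.
r_train <- function(W, sem, probs, config, judge_verbs) {
  cum <- cumsum(probs)
  cum[length(cum)] <- 1
  nv <- config$n_verbs
  lambda_step <- config$decay / config$utterances_per_epoch
  judge_all <- function(W) {
    vapply(judge_verbs, function(v) judge_verb(W, v, sem[v, ], config),
           numeric(3L))
  }
  acts <- array(NA_real_, c(length(judge_verbs), 3L, config$epochs + 1L))
  acts[, , 1L] <- t(judge_all(W))
  for (ep in seq_len(config$epochs)) {
    for (i in seq_len(config$utterances_per_epoch)) {
      cell <- findInterval(runif(1L), cum, left.open = TRUE) + 1L
      v <- (cell - 1L) %/% 3L + 1L
      form <- (cell - 1L) %% 3L + 1L
      x <- encode_input(v, form != 3L, sem[v, ], config)
      W <- delta_update(W, x, form, config$eta, lambda_step)
    }
    acts[, , ep + 1L] <- t(judge_all(W))
  }
  list(W = W, activations = acts)
}
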