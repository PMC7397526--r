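#' Per-verb difference scores
#'
#' The by-verb preference for the more-transparent over the less-transparent
#' causative: mean value for the MORE form minus mean value for the LESS
#' form.  Applies identically to human 1-5 ratings (aggregated over
#' participants) and to model activations (aggregated over runs); because
#' both the mean and the difference are linear, aggregating before or after
#' differencing gives the same scores.
#'
#' @param less,more numeric vectors of per-verb values for the two forms,
#'   aligned by position, or named vectors sharing names.
#' @return Named vector of \code{more - less} per verb.
#' @export
difference_scores <- function(less, more) {
  if (length(less) != length(more))
    stop("both forms must be present for every verb")
  if (!is.null(names(less)) && !is.null(names(more))) {
    if (!setequal(names(less), names(more)))
      stop("both forms must be present for every verb")
    more <- more[names(less)]
  }
  if (anyNA(less) || anyNA(more)) stop("missing form value for some verb")
  more - less
}

#' Aggregate judgment records to per-verb means
#'
#' @param judgments data frame with columns \code{participant},
#'   \code{age_group}, \code{verb}, \code{sentence_type}, \code{rating}
#'   (see \code{\link{read_judgments}}).
#' @param age_group optionally restrict to one age group.
#' @return Data frame \code{verb}, \code{mean_less}, \code{mean_more},
#'   \code{diff}.
#' @export
judgment_means <- function(judgments, age_group = NULL) {
  judgments <- validate_judgments(judgments)
  if (!is.null(age_group)) judgments <- judgments[judgments$age_group %in% age_group, ]
  m <- tapply(judgments$rating, list(judgments$verb, judgments$sentence_type), mean)
  if (!all(c("LESS", "MORE") %in% colnames(m)) || anyNA(m[, c("LESS", "MORE")]))
    stop("missing ratings for some verb x sentence-type cell")
  verbs <- unique(judgments$verb)
  data.frame(verb = verbs,
             mean_less = m[verbs, "LESS"], mean_more = m[verbs, "MORE"],
             diff = m[verbs, "MORE"] - m[verbs, "LESS"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' By-verb Pearson correlation
#'
#' Sample Pearson correlation across verbs.  A constant input is degenerate
#' (the correlation is undefined, e.g. for an untrained model whose
#' activations are identical for every verb) and raises an error rather than
#' silently returning 0; callers that must tolerate it use
#' \code{\link{model_fit_curve}}, which flags such epochs.
#'
#' @param x,y per-verb numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \code{[-1, 1]}.
#' @export
byverb_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be aligned by verb")
  if (length(x) < 3) stop("need at least 3 verbs")
  if (anyNA(x) || anyNA(y)) stop("missing values")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: constant vector has no defined correlation")
  cor(x, y)
}

#' Critical value of the correlation coefficient
#'
#' The smallest \code{|r|} significant at level \code{alpha} for the given
#' degrees of freedom (\code{df = n - 2}), from the exact t transform:
#' \deqn{r^* = t^* / \sqrt{t^{*2} + df}} with \code{t*} the upper-tail
#' quantile of Student's t on \code{df} degrees of freedom (\code{alpha} for
#' one-tailed, \code{alpha/2} for two-tailed tests).
#'
#' @param df degrees of freedom, >= 1.
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param tails \code{"one"} or \code{"two"}.
#' @return The critical correlation, in \code{[0, 1)}.
#' @examples
#' critical_r(58, 0.05)        # 0.21 to 2 dp
#' critical_r(58, 0.01)        # 0.30 to 2 dp
#' @export
critical_r <- function(df, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (df < 1) stop("df must be >= 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  p <- if (tails == "two") alpha / 2 else alpha
  tstar <- qt(1 - p, df)
  tstar / sqrt(tstar^2 + df)
}

#' Cross-language correlation matrix of semantic means vs difference scores
#'
#' Correlates, for every ordered pair of languages, one language's per-verb
#' event-merge rating means with another language's per-verb judgment
#' difference scores over a shared verb lexicon, and flags cells exceeding a
#' critical-r threshold.
#'
#' @param semantic_means named list: one per-verb named numeric vector of
#'   event-merge means per language.
#' @param diff_scores named list: one per-verb named numeric vector of adult
#'   difference scores per language.
#' @param alpha significance level for the flags (default 0.01).
#' @param tails tail specification for \code{\link{critical_r}}.
#' @return List with \code{r} (ratings-language x judgments-language matrix),
#'   \code{significant} (logical matrix \code{r > critical}), \code{critical}
#'   and \code{df}.
#' @export
crosslanguage_matrix <- function(semantic_means, diff_scores, alpha = 0.01,
                                 tails = "one") {
  verbs <- names(semantic_means[[1L]])
  ok <- vapply(c(semantic_means, diff_scores),
               function(v) setequal(names(v), verbs), TRUE)
  if (is.null(verbs) || !all(ok))
    stop("all languages must share one named verb lexicon")
  r <- outer(seq_along(semantic_means), seq_along(diff_scores),
             Vectorize(function(i, j)
               byverb_pearson(semantic_means[[i]][verbs],
                              diff_scores[[j]][verbs])))
  dimnames(r) <- list(names(semantic_means), names(diff_scores))
  crit <- critical_r(length(verbs) - 2L, alpha, tails)
  list(r = r, significant = r > crit, critical = crit, df = length(verbs) - 2L)
}

#' Per-epoch correlation of model activations with judgment means
#'
#' For every epoch, averages the ensemble's activations over runs, then
#' correlates across verbs the LESS activations with the LESS rating means,
#' MORE with MORE, and the difference scores with each other.  Epochs where
#' either vector is constant (for instance an untrained model) are flagged
#' as degenerate (\code{r = NA}, \code{degenerate = TRUE}) rather than
#' reported as 0.
#'
#' @param fit a \code{\link{causative_learner}} fit (or its
#'   \code{predictions} data frame).
#' @param judgments judgment records (see \code{\link{judgment_means}}) or a
#'   precomputed per-verb means table with columns \code{verb},
#'   \code{mean_less}, \code{mean_more}.
#' @param age_group optional age-group restriction, passed on.
#' @return An object of class \code{"model_fit_curve"}: data frame
#'   \code{epoch}, \code{form} (\code{LESS}, \code{MORE}, \code{DIFF}),
#'   \code{r}, \code{n_verbs}, \code{degenerate}.
#' @export
model_fit_curve <- function(fit, judgments, age_group = NULL) {
  means <- if (all(c("mean_less", "mean_more") %in% names(judgments))) judgments
           else judgment_means(judgments, age_group)
  acts <- if (inherits(fit, "causative_learner")) ensemble_means(fit)
          else {
            a <- aggregate(fit[c("act_less", "act_more")],
                           by = list(epoch = fit$epoch, verb = fit$verb), mean)
            a$diff <- a$act_more - a$act_less
            a
          }
  verbs <- intersect(unique(acts$verb), means$verb)
  if (length(verbs) < 3) stop("model and judgments share fewer than 3 verbs")
  means <- means[match(verbs, means$verb), ]
  hm <- list(LESS = means$mean_less, MORE = means$mean_more,
             DIFF = means$mean_more - means$mean_less)
  rows <- lapply(sort(unique(acts$epoch)), function(ep) {
    a <- acts[acts$epoch == ep, ]
    a <- a[match(verbs, a$verb), ]
    av <- list(LESS = a$act_less, MORE = a$act_more, DIFF = a$diff)
    do.call(rbind, lapply(names(hm), function(f) {
      degen <- sd(av[[f]]) == 0 || sd(hm[[f]]) == 0
      data.frame(epoch = ep, form = f,
                 r = if (degen) NA_real_ else cor(av[[f]], hm[[f]]),
                 n_verbs = length(verbs), degenerate = degen,
                 stringsAsFactors = FALSE)
    }))
  })
  structure(do.call(rbind, rows), class = c("model_fit_curve", "data.frame"))
}

#' @export
print.model_fit_curve <- function(x, ...) {
  fin <- x[x$epoch == max(x$epoch), ]
  cat("Model-judgment fit curve over", max(x$epoch), "epochs,",
      fin$n_verbs[1L], "verbs\n")
  cat("  final epoch:",
      paste(sprintf("%s r = %.3f", fin$form, fin$r), collapse = ", "), "\n")
  best <- x[x$form == "DIFF" & !x$degenerate, ]
  if (nrow(best))
    cat(sprintf("  best DIFF r = %.3f at epoch %d\n",
                max(best$r), best$epoch[which.max(best$r)]))
  invisible(x)
}

#' @export
plot.model_fit_curve <- function(x, ...) {
  forms <- c("LESS", "MORE", "DIFF")
  traj <- sapply(forms, function(f) x$r[x$form == f])
  graphics::matplot(unique(x$epoch), traj, type = "l", lty = 1:3, col = 1:3,
                    xlab = "epoch", ylab = "by-verb r", ylim = c(-1, 1), ...)
  graphics::legend("bottomright", legend = forms, lty = 1:3, col = 1:3, bty = "n")
  invisible(x)
}
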