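#' @keywords internal
SEMANTIC_SCALES <- c("EVENT_MERGE", "AUTONOMY", "DIRECTIVE", "REQUIRES")

#' Aggregate rater-level semantic ratings to per-verb means
#'
#' Each rater positions each verb on a continuous analogue scale (stored in
#' 0-100) for four semantic dimensions: event-merge (do causing and caused
#' event fuse into one event?), autonomy, directive/physical causation and
#' requires-causer.  Aggregation is the arithmetic mean across raters per
#' (verb, scale) cell.  Missing raters are tolerated; a (verb, scale) cell
#' with no rating at all is an error naming the verb and scale.
#'
#' @param ratings data frame with columns \code{rater}, \code{verb},
#'   \code{scale} and \code{value} (see \code{\link{read_ratings}}).
#' @return A data frame with one row per verb and one \code{<scale>_mean}
#'   column per scale, rows ordered by first appearance of the verb.
#' @export
aggregate_ratings <- function(ratings) {
  ratings <- validate_ratings(ratings)
  verbs <- unique(ratings$verb)
  scales <- unique(ratings$scale)
  means <- matrix(NA_real_, length(verbs), length(scales),
                  dimnames = list(verbs, scales))
  agg <- tapply(ratings$value, list(ratings$verb, ratings$scale), mean)
  means[] <- agg[verbs, scales, drop = FALSE]
  if (anyNA(means)) {
    miss <- which(is.na(means), arr.ind = TRUE)[1L, ]
    stop("no ratings for verb '", verbs[miss[1L]], "' on scale '",
         scales[miss[2L]], "'")
  }
  out <- data.frame(verb = verbs, means, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  names(out)[-1L] <- paste0(tolower(scales), "_mean")
  out
}

#' Min-max scale a vector to the unit interval
#'
#' @param x numeric vector, non-constant.
#' @return \code{(x - min) / (max - min)}, elementwise in \code{[0, 1]}.
#' @export
to_unit_interval <- function(x) {
  if (any(!is.finite(x))) stop("to_unit_interval() requires finite values")
  r <- range(x)
  if (r[1L] == r[2L])
    stop("degenerate input: constant values cannot be min-max scaled")
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Per-verb semantic profiles in mean, Z and unit-interval form
#'
#' Builds the two downstream representations of the semantic ratings: Z
#' scores across verbs per scale (the regression/correlation predictor form)
#' and min-max unit-interval activations (the model-input form, feeding the
#' four semantic units of the discriminative learner).  Both are monotone in
#' the per-verb means, so verb rank order per scale is preserved.
#'
#' @param ratings rater-level ratings (see \code{\link{aggregate_ratings}}),
#'   or a data frame that already carries \code{*_mean} columns.
#' @return A data frame with one row per verb: \code{verb} and, per scale,
#'   \code{<scale>_mean}, \code{<scale>_z} and \code{<scale>_unit} columns.
#' @examples
#' spec <- synth_spec(n_verbs = 8)
#' lat <- gen_latent_semantics(spec, seed = 1)
#' profiles <- semantic_profiles(gen_ratings(spec, lat, seed = 1))
#' @export
semantic_profiles <- function(ratings) {
  means <- if (any(grepl("_mean$", names(ratings)))) ratings
           else aggregate_ratings(ratings)
  mean_cols <- grep("_mean$", names(means), value = TRUE)
  out <- means[c("verb", mean_cols)]
  for (mc in mean_cols) {
    base <- sub("_mean$", "", mc)
    out[[paste0(base, "_z")]] <- standardize(means[[mc]])
    out[[paste0(base, "_unit")]] <- to_unit_interval(means[[mc]])
  }
  out
}

#' Extract the model-input activation matrix from a profile table
#'
#' @param profiles output of \code{\link{semantic_profiles}}.
#' @return Numeric matrix (verbs x scales) of unit-interval activations,
#'   rownames the verb labels.
#' @keywords internal
unit_matrix <- function(profiles) {
  cols <- grep("_unit$", names(profiles), value = TRUE)
  if (length(cols) == 0) stop("profiles carry no *_unit columns")
  m <- as.matrix(profiles[cols])
  rownames(m) <- profiles$verb
  m
}
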