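#' Pearson chi-square statistic for a 2x2 contingency table
#'
#' Computes the uncorrected Pearson statistic
#' \deqn{\chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' for a table with focal-verb row \code{(a, b)} and all-other-verbs row
#' \code{(c, d)}.  No continuity correction is applied and zero cells are
#' allowed: a table whose row (or column) marginal is zero carries no
#' association information and returns 0.
#'
#' @param a,b,c,d non-negative cell counts; \code{a}, \code{b} are the focal
#'   verb's counts in the two construction categories, \code{c}, \code{d} the
#'   summed counts of all other verbs.
#' @return The chi-square statistic, a single non-negative number.
#' @examples
#' chi_square_2x2(0, 7, 468636, 3676)
#' chi_square_2x2(10, 5, 20, 10)  # proportional rows -> 0
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  # corpus counts exceed sqrt(.Machine$integer.max); products need doubles
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (n == 0) stop("degenerate 2x2 table: all cells are zero")
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  if (m1 == 0 || m2 == 0 || m3 == 0 || m4 == 0) return(0)
  n * (a * d - b * c)^2 / (m1 * m2 * m3 * m4)
}

check_cells <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (length(cells) != 4 || any(!is.finite(cells)) || any(cells < 0))
    stop("cell counts must be four finite non-negative numbers")
  invisible(cells)
}

#' Signed chi-square bias of a focal verb toward a construction
#'
#' The magnitude is \code{\link{chi_square_2x2}}; the polarity is positive
#' when the focal verb's odds toward column 1 (the rated structure) exceed
#' the other-verbs' odds (\code{a*d > b*c}), negative when lower, and zero
#' for exactly proportional rows.  Swapping the two columns flips the sign
#' and preserves the magnitude.
#'
#' @inheritParams chi_square_2x2
#' @return A signed real number.
#' @examples
#' signed_bias(7, 0, 3676, 468636)   # focal verb biased toward column 1
#' signed_bias(0, 7, 468636, 3676)   # same table, columns swapped
#' @export
signed_bias <- function(a, b, c, d) {
  stat <- chi_square_2x2(a, b, c, d)
  sign(as.numeric(a) * as.numeric(d) - as.numeric(b) * as.numeric(c)) * stat
}

resolve_verb <- function(counts, verb) {
  if (nrow(counts) < 2)
    stop("need at least 2 verbs to compare a focal verb against the rest")
  i <- match(verb, counts$verb)
  if (is.na(i)) stop("unknown verb: ", verb)
  i
}

match_structure <- function(rated_structure) {
  match.arg(toupper(rated_structure), c("LESS", "MORE"))
}

#' Preemption statistic for one verb
#'
#' Builds a 2x2 table whose columns are the rated causative structure and the
#' competing causative structure, and whose rows are the focal verb versus the
#' sum over all other verbs in \code{counts} (the supplied verb set stands in
#' for the language as a whole), then returns the signed chi-square bias
#' toward the rated structure.
#'
#' @param counts construction-count table as returned by
#'   \code{\link{read_counts}} or \code{\link{gen_counts}}: columns
#'   \code{verb}, \code{n_less}, \code{n_more}, \code{n_other}.
#' @param verb focal verb label (must occur in \code{counts$verb}).
#' @param rated_structure \code{"LESS"} or \code{"MORE"}: which causative
#'   structure is being rated.
#' @return Signed chi-square statistic; positive when the verb is biased
#'   toward the rated structure relative to the base rate, negative when
#'   biased toward the competitor.
#' @seealso \code{\link{entrenchment_statistic}},
#'   \code{\link{construction_predictors}}
#' @export
preemption_statistic <- function(counts, verb, rated_structure = c("LESS", "MORE")) {
  rated <- match_structure(rated_structure[1L])
  i <- resolve_verb(counts, verb)
  less <- counts$n_less; more <- counts$n_more
  if (rated == "LESS") {
    signed_bias(less[i], more[i], sum(less[-i]), sum(more[-i]))
  } else {
    signed_bias(more[i], less[i], sum(more[-i]), sum(less[-i]))
  }
}

#' Entrenchment statistic for one verb
#'
#' As \code{\link{preemption_statistic}}, but the second column holds the
#' verb's uses in all non-causative structures (\code{n_other}).  Causative
#' uses of the competing structure are excluded from that column by
#' construction, so the tokens feeding preemption never feed entrenchment —
#' a deliberately conservative decomposition that minimizes collinearity
#' between the two predictors.
#'
#' @inheritParams preemption_statistic
#' @return Signed chi-square statistic, polarity as in
#'   \code{\link{preemption_statistic}}.
#' @export
entrenchment_statistic <- function(counts, verb, rated_structure = c("LESS", "MORE")) {
  rated <- match_structure(rated_structure[1L])
  i <- resolve_verb(counts, verb)
  col1 <- if (rated == "LESS") counts$n_less else counts$n_more
  other <- counts$n_other
  signed_bias(col1[i], other[i], sum(col1[-i]), sum(other[-i]))
}

#' Standardize a vector to Z scores
#'
#' Centers and scales by the sample standard deviation (n - 1 denominator).
#' A constant vector is a degenerate input and raises an error rather than
#' silently returning zeros.
#'
#' @param x numeric vector, length at least 2, non-constant.
#' @return Vector of the same length with mean 0 and sample SD 1.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("standardize() needs at least 2 values")
  if (any(!is.finite(x))) stop("standardize() requires finite values")
  s <- sd(x)
  if (s == 0) stop("degenerate input: constant vector cannot be standardized")
  (x - mean(x)) / s
}

#' Entrenchment/preemption predictor table for a verb set
#'
#' Computes, for every verb, the four signed chi-square statistics
#' (preemption and entrenchment, each for the less- and the more-transparent
#' structure) and standardizes each column to Z scores across verbs.  The two
#' preemption columns are the same table rated from opposite sides, so before
#' standardization they are exact negatives of one another.
#'
#' @inheritParams preemption_statistic
#' @return A data frame with one row per verb: \code{verb}, the standardized
#'   predictors \code{preemption_less}, \code{preemption_more},
#'   \code{entrenchment_less}, \code{entrenchment_more}, and the
#'   pre-standardization values in matching \code{*_raw} columns.
#' @examples
#' spec <- synth_spec(n_verbs = 10)
#' counts <- gen_counts(spec, gen_latent_semantics(spec, seed = 1), seed = 2)
#' construction_predictors(counts)
#' @export
construction_predictors <- function(counts) {
  counts <- validate_counts(counts)
  verbs <- counts$verb
  raw <- data.frame(
    verb = verbs,
    preemption_less_raw = vapply(verbs, function(v) preemption_statistic(counts, v, "LESS"), 0),
    preemption_more_raw = vapply(verbs, function(v) preemption_statistic(counts, v, "MORE"), 0),
    entrenchment_less_raw = vapply(verbs, function(v) entrenchment_statistic(counts, v, "LESS"), 0),
    entrenchment_more_raw = vapply(verbs, function(v) entrenchment_statistic(counts, v, "MORE"), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- data.frame(
    verb = verbs,
    preemption_less = standardize(raw$preemption_less_raw),
    preemption_more = standardize(raw$preemption_more_raw),
    entrenchment_less = standardize(raw$entrenchment_less_raw),
    entrenchment_more = standardize(raw$entrenchment_more_raw),
    stringsAsFactors = FALSE, row.names = NULL
  )
  cbind(out, raw[-1L])
}
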