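fail_rows <- function(bad, what, path = NULL) {
  where <- if (is.null(path)) "row" else paste0(basename(path), " line")
  # +1 for the header when reporting file lines
  lines <- if (is.null(path)) which(bad) else which(bad) + 1L
  stop(what, " (", where, " ", paste(head(lines, 5L), collapse = ", "),
       if (sum(bad) > 5) ", ...", ")")
}

require_columns <- function(df, cols, path = NULL) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         if (!is.null(path)) paste0(" in ", path))
  df
}

#' Validate a construction-count table
#'
#' @param counts data frame with columns \code{verb}, \code{n_less},
#'   \code{n_more}, \code{n_other}.
#' @param path optional source path, used in error messages.
#' @return The validated data frame (counts coerced to integer-valued
#'   numerics).
#' @export
validate_counts <- function(counts, path = NULL) {
  require_columns(counts, c("verb", "n_less", "n_more", "n_other"), path)
  for (col in c("n_less", "n_more", "n_other")) {
    v <- counts[[col]]
    bad <- !is.finite(v) | v < 0 | v != floor(v)
    if (any(bad)) fail_rows(bad, paste0("non-integer or negative ", col), path)
  }
  dup <- duplicated(counts$verb)
  if (any(dup)) fail_rows(dup, "duplicate verb", path)
  counts
}

#' Validate a semantic-rating table
#'
#' @param ratings data frame with columns \code{rater}, \code{verb},
#'   \code{scale}, \code{value} (values in [0, 100]).
#' @param path optional source path for error messages.
#' @return The validated data frame.
#' @export
validate_ratings <- function(ratings, path = NULL) {
  require_columns(ratings, c("rater", "verb", "scale", "value"), path)
  bad <- !is.finite(ratings$value) | ratings$value < 0 | ratings$value > 100
  if (any(bad)) fail_rows(bad, "rating value outside [0, 100]", path)
  dup <- duplicated(ratings[c("rater", "verb", "scale")])
  if (any(dup)) fail_rows(dup, "duplicate (rater, verb, scale)", path)
  ratings
}

#' Validate a grammaticality-judgment table
#'
#' @param judgments data frame with columns \code{participant},
#'   \code{age_group}, \code{verb}, \code{sentence_type} (LESS/MORE),
#'   \code{rating} (integer 1-5).
#' @param path optional source path for error messages.
#' @return The validated data frame.
#' @export
validate_judgments <- function(judgments, path = NULL) {
  require_columns(judgments,
                  c("participant", "age_group", "verb", "sentence_type", "rating"),
                  path)
  r <- judgments$rating
  bad <- !is.finite(r) | r != floor(r) | r < 1 | r > 5
  if (any(bad)) fail_rows(bad, "rating outside 1-5", path)
  bad <- !judgments$sentence_type %in% c("LESS", "MORE")
  if (any(bad)) fail_rows(bad, "sentence_type not LESS/MORE", path)
  judgments
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, encoding = "UTF-8")
}

#' Read the package's TSV tables
#'
#' All tables are UTF-8, tab-separated with a header row (tabs rather than
#' commas: verb labels across languages may contain commas or quotes).
#' Schema violations are reported with file line numbers.
#'
#' @param path file path.
#' @return The validated data frame.
#' @export
read_counts <- function(path) validate_counts(read_tsv(path), path)

#' @rdname read_counts
#' @export
read_ratings <- function(path) validate_ratings(read_tsv(path), path)

#' @rdname read_counts
#' @export
read_judgments <- function(path) validate_judgments(read_tsv(path), path)

#' @rdname read_counts
#' @export
read_predictions <- function(path) {
  p <- require_columns(read_tsv(path),
                       c("run", "epoch", "verb", "act_less", "act_more", "act_other"),
                       path)
  s <- p$act_less + p$act_more + p$act_other
  bad <- !is.finite(s) | abs(s - 1) > 1e-6
  if (any(bad)) fail_rows(bad, "activations do not sum to 1", path)
  p
}

#' Write a TSV table
#'
#' @param df data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full pipeline on one configuration
#'
#' Executes the stages end to end — synthetic-data generation (unless real
#' tables are supplied), corpus predictors, semantic profiles, the full
#' ensemble simulation, the split-half simulation, and the per-epoch
#' evaluation curves — writing every table as TSV into \code{out_dir}
#' together with a JSON manifest (seed, configuration echo and md5 checksums
#' of every written file), so any output can be re-derived exactly.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a \code{\link{synth_spec}} used when tables are not supplied.
#' @param config a \code{\link{learner_config}}.
#' @param seed master seed for generation and training.
#' @param counts,ratings,judgments optional pre-loaded tables (or paths),
#'   overriding the synthetic generator stage.
#' @return Invisibly, a list with all in-memory artifacts (\code{counts},
#'   \code{profiles}, \code{predictors}, \code{fit}, \code{fit_split},
#'   \code{curve}, \code{curve_split}, \code{manifest}).
#' @export
run_pipeline <- function(out_dir, spec = synth_spec(),
                         config = learner_config(), seed = 1L,
                         counts = NULL, ratings = NULL, judgments = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  as_table <- function(x, reader) if (is.character(x)) reader(x) else x

  if (is.null(counts) || is.null(ratings) || is.null(judgments)) {
    synth <- synth_dataset(spec, seed = seed)
    if (is.null(counts)) counts <- synth$counts
    if (is.null(ratings)) ratings <- synth$ratings
    if (is.null(judgments)) judgments <- synth$judgments
  }
  counts <- validate_counts(as_table(counts, read_counts))
  ratings <- validate_ratings(as_table(ratings, read_ratings))
  judgments <- validate_judgments(as_table(judgments, read_judgments))

  profiles <- semantic_profiles(ratings)
  predictors <- construction_predictors(counts)
  config$n_verbs <- nrow(counts)
  fit <- causative_learner(counts, profiles, config, seed = seed)
  fit_split <- causative_learner(counts, profiles, config, seed = seed,
                                 split_half = TRUE)
  curve <- model_fit_curve(fit, judgments)
  curve_split <- model_fit_curve(fit_split, judgments)

  out <- function(name) file.path(out_dir, name)
  write_tsv(counts, out("counts.tsv"))
  write_tsv(ratings, out("ratings.tsv"))
  write_tsv(judgments, out("judgments.tsv"))
  write_tsv(profiles, out("profiles.tsv"))
  write_tsv(predictors, out("predictors.tsv"))
  write_tsv(fit$predictions, out("predictions.tsv"))
  write_tsv(fit_split$predictions, out("predictions_split.tsv"))
  write_tsv(as.data.frame(curve), out("evaluation.tsv"))
  write_tsv(as.data.frame(curve_split), out("evaluation_split.tsv"))

  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    seed = as.integer(seed),
    learner_config = unclass(config),
    synth_spec = unclass(spec),
    split_half_train_verbs = fit_split$train_verbs,
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(counts = counts, profiles = profiles, predictors = predictors,
                 fit = fit, fit_split = fit_split, curve = curve,
                 curve_split = curve_split, manifest = manifest))
}
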