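# Protein-centric benchmark: per-protein precision/recall at sliding score
# thresholds, with exact-term (m1) or root-propagated (m2) matching.

#' Confusion counts for one protein at one score threshold
#'
#' The predicted set at threshold `t` holds the terms with score strictly
#' greater than `t`. Under mode `"m1"` the predicted and true sets are
#' compared as-is; under `"m2"` both are first propagated to the root — every
#' ancestor (the namespace root included, unless `include_root = FALSE`) of a
#' predicted or true term joins its set before the set arithmetic. A
#' predicted term that is not exact but lies on the path of a true term is
#' thus not completely wrong: the shared ancestors count as true positives.
#' Ancestor sets are deduplicated (set semantics).
#'
#' @param predicted Data.frame with columns `term` and `score` (scores
#'   non-negative), or `NULL` for no predictions.
#' @param true_terms Character vector of benchmark GO ids.
#' @param threshold Score cutoff `t`; predictions with `score > t` are kept.
#' @param mode `"m1"` (exact) or `"m2"` (root-propagated).
#' @param ontology A `go_ontology`; required for mode `"m2"`.
#' @param include_root Keep the namespace roots in the propagated sets
#'   (default `TRUE`).
#' @return Named integer vector `c(tp =, fp =, fn =)` with
#'   `tp + fp = |predicted|` and `tp + fn = |true|` after the mode transform.
#' @export
confusion_at_threshold <- function(predicted, true_terms, threshold,
                                   mode = c("m1", "m2"), ontology = NULL,
                                   include_root = TRUE) {
  mode <- match.arg(mode)
  pred <- if (is.null(predicted) || nrow(predicted) == 0L) character(0)
          else unique(predicted$term[predicted$score > threshold])
  truth <- unique(true_terms)
  if (mode == "m2") {
    if (is.null(ontology)) stop("mode m2 requires the ontology")
    pred <- propagate_to_root(pred, ontology, include_root)
    truth <- propagate_to_root(truth, ontology, include_root)
  }
  c(tp = length(intersect(pred, truth)),
    fp = length(setdiff(pred, truth)),
    fn = length(setdiff(truth, pred)))
}

propagate_to_root <- function(terms, ontology, include_root = TRUE) {
  if (!length(terms)) return(character(0))
  terms <- resolve_term(ontology, terms)
  out <- unique(unlist(ontology$ancestors[terms], use.names = FALSE))
  if (!include_root) out <- setdiff(out, unname(ontology$roots))
  out
}

#' Precision/recall curve over a pool of benchmark proteins
#'
#' Sweeps `n_points` evenly spaced thresholds from 0 to the maximum observed
#' score. At each threshold, per-protein precision and recall are computed
#' with [confusion_at_threshold()] and averaged: precision over the proteins
#' that still have at least one prediction (a protein with no annotated term
#' at that threshold has no precision to calculate), recall over all `N`
#' proteins of the pool (missing predictions count as false negatives).
#'
#' @param records A list of benchmark records, each a list with elements
#'   `protein`, `true_terms` (non-empty character vector) and `predicted`
#'   (data.frame `term`, `score`).
#' @param mode `"m1"` or `"m2"`.
#' @param ontology A `go_ontology` (required for `"m2"`, and for restricting
#'   to a namespace).
#' @param n_points Number of thresholds in the sweep (default 100).
#' @param namespace Restrict truth and predictions to one namespace, or
#'   `"all"` (default) to pool the three branches.
#' @param include_root Passed to [confusion_at_threshold()].
#' @return A data.frame of class `pr_curve`: `threshold`, `precision`,
#'   `recall`, `n_scored` (proteins entering the precision average). Recall
#'   is non-increasing in the threshold.
#' @export
pr_curve <- function(records, mode = c("m1", "m2"), ontology = NULL,
                     n_points = 100, namespace = "all",
                     include_root = TRUE) {
  mode <- match.arg(mode)
  if (!length(records)) stop("no benchmark records")
  if (!identical(namespace, "all")) {
    if (is.null(ontology))
      stop("namespace restriction requires the ontology")
    records <- lapply(records, function(r) {
      keep_t <- ontology$namespace[resolve_term(ontology, r$true_terms)] ==
        namespace
      r$true_terms <- r$true_terms[keep_t]
      if (!is.null(r$predicted) && nrow(r$predicted)) {
        keep_p <- ontology$namespace[resolve_term(ontology,
                                                  r$predicted$term)] ==
          namespace
        r$predicted <- r$predicted[keep_p, , drop = FALSE]
      }
      r
    })
    records <- Filter(function(r) length(r$true_terms) > 0, records)
    if (!length(records))
      stop(sprintf("no benchmark record has true terms in namespace %s",
                   namespace))
  }
  scores <- unlist(lapply(records, function(r)
    if (is.null(r$predicted)) numeric(0) else r$predicted$score))
  t_max <- if (length(scores)) max(scores) else 0
  thresholds <- seq(0, t_max, length.out = max(n_points, 2L))

  res <- vapply(thresholds, function(t) {
    prs <- numeric(0)
    rcs <- numeric(length(records))
    for (i in seq_along(records)) {
      cm <- confusion_at_threshold(records[[i]]$predicted,
                                   records[[i]]$true_terms, t, mode,
                                   ontology, include_root)
      if (cm[["tp"]] + cm[["fp"]] > 0L)
        prs <- c(prs, cm[["tp"]] / (cm[["tp"]] + cm[["fp"]]))
      rcs[i] <- if (cm[["tp"]] + cm[["fn"]] > 0L)
        cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]) else NA_real_
    }
    c(precision = if (length(prs)) mean(prs) else NA_real_,
      recall = mean(rcs, na.rm = TRUE),
      n_scored = length(prs))
  }, numeric(3))

  out <- data.frame(threshold = thresholds,
                    precision = res["precision", ],
                    recall = res["recall", ],
                    n_scored = as.integer(res["n_scored", ]))
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Build benchmark records from prediction and truth tables
#'
#' Joins a predictions table (`protein`, `term`, `score`) with a truth table
#' (`protein`, `term`) into the record list consumed by [pr_curve()].
#' Proteins present in the truth but never predicted still enter the pool
#' (their recall is 0 until the threshold admits nothing); proteins predicted
#' but absent from the truth are dropped.
#'
#' @param predictions Data.frame with columns `protein`, `term`, `score`.
#' @param truth Data.frame with columns `protein`, `term`.
#' @return List of benchmark records.
#' @export
benchmark_records <- function(predictions, truth) {
  stopifnot(all(c("protein", "term") %in% names(truth)))
  lapply(unique(truth$protein), function(p) {
    pred <- predictions[predictions$protein == p, , drop = FALSE]
    list(protein = p,
         true_terms = unique(truth$term[truth$protein == p]),
         predicted = data.frame(term = pred$term, score = pred$score,
                                stringsAsFactors = FALSE))
  })
}

#' Read a predictions TSV (protein, GO id, score)
#' @param x Path or character vector of lines.
#' @return Data.frame `protein`, `term`, `score`.
#' @export
read_predictions_tsv <- function(x) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(protein = character(0), term = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  # tolerate a header row
  if (grepl("^protein\t", lines[1])) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short))
    stop(sprintf("predictions line %d has fewer than 3 columns", short[1]))
  sc <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(sc))
    stop(sprintf("non-numeric score on line %d", which(is.na(sc))[1]))
  data.frame(protein = vapply(fields, `[`, character(1), 1L),
             term = vapply(fields, `[`, character(1), 2L),
             score = sc, stringsAsFactors = FALSE)
}

#' Read a truth table: 2-column TSV (protein, GO id) or a GAF file
#' @param x Path or character vector of lines.
#' @return Data.frame `protein`, `term`.
#' @export
read_truth_table <- function(x) {
  lines <- read_text_lines(x)
  body <- lines[nzchar(lines) & !startsWith(lines, "!") &
                  !startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(protein = character(0), term = character(0),
                      stringsAsFactors = FALSE))
  ncol1 <- length(strsplit(body[1], "\t", fixed = TRUE)[[1]])
  if (ncol1 >= 9L) {
    gaf <- parse_gaf(lines)
    return(data.frame(protein = gaf$object, term = gaf$term,
                      stringsAsFactors = FALSE))
  }
  if (grepl("^protein\t", body[1])) body <- body[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(short))
    stop(sprintf("truth line %d has fewer than 2 columns", short[1]))
  data.frame(protein = vapply(fields, `[`, character(1), 1L),
             term = vapply(fields, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}
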