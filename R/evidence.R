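# Evidence weighting: turn BLAST/HMMER hit tables into per-protein
# weighted GO term sets.

#' Weight of a BLAST-style hit
#'
#' `w = -log10(evalue)`, so the weight reads as the e-value exponent: a hit at
#' 1e-50 contributes 50. E-values of 0 (as reported by search tools for very
#' strong hits) and anything below `floor` are clamped to `floor`, capping the
#' weight (180 by default).
#'
#' @param evalue Numeric vector of e-values, each `>= 0`.
#' @param floor Smallest admissible e-value; values below are clamped.
#' @return Numeric vector of positive weights, decreasing in e-value.
#' @export
blast_weight <- function(evalue, floor = 1e-180) {
  if (any(!is.finite(evalue)) || any(evalue < 0))
    stop("e-values must be finite and non-negative")
  -log10(pmax(evalue, floor))
}

#' Logistic reward for GO-term frequency within a domain model
#'
#' `f(x) = 1 / (1 + exp(-steepness * (x - midpoint)))`, strictly increasing
#' on `[0, 1]`. Applied to the frequency with which a GO term annotates the
#' proteins of a Pfam-style entry, it rewards terms that are consistently
#' present in the model and damps sparse, likely spurious ones.
#'
#' @param freq Numeric vector of frequencies in `[0, 1]`.
#' @param steepness Slope parameter of the logistic curve.
#' @param midpoint Frequency at which the reward equals 0.5.
#' @return Numeric vector in `(0, 1)`.
#' @export
logistic_reward <- function(freq, steepness = 10, midpoint = 0.5) {
  if (any(!is.finite(freq)) || any(freq < 0 | freq > 1))
    stop("frequencies must lie in [0, 1]")
  1 / (1 + exp(-steepness * (freq - midpoint)))
}

#' Weight of a HMMER-style hit for one GO term of its model
#'
#' The e-value exponent scaled by the logistic reward of the term's frequency
#' among the `n_total` proteins of the domain model:
#' `w = -log10(evalue) * f(n_with_term / n_total)`.
#'
#' @inheritParams blast_weight
#' @inheritParams logistic_reward
#' @param n_with_term Number of the model's proteins annotated with the term.
#' @param n_total Total number of proteins in the model (must be positive).
#' @return Numeric vector of non-negative weights.
#' @export
hmmer_weight <- function(evalue, n_with_term, n_total,
                         steepness = 10, midpoint = 0.5, floor = 1e-180) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_with_term < 0 | n_with_term > n_total))
    stop("n_with_term must lie in [0, n_total]")
  blast_weight(evalue, floor = floor) *
    logistic_reward(n_with_term / n_total, steepness, midpoint)
}

# "sp|P12345|NAME" -> "P12345"; bare accessions pass through
extract_accession <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L],
         character(1))
}

#' Parse a BLAST tabular hit file
#'
#' Accepts the standard 12-column `outfmt 6` layout (query, subject, identity,
#' ..., e-value in column 11) or a minimal 3-column dialect
#' (query, subject, e-value). Subject accessions in `db|ACC|name` form are
#' reduced to `ACC`. Rows with an e-value above `evalue_ceiling` are dropped.
#'
#' @param x Path to a TSV file or a character vector of its lines.
#' @param evalue_ceiling Largest e-value admitted; default `1e-3`.
#' @return A data.frame of hits: `query`, `subject`, `evalue`, `source`
#'   (`"blast"`).
#' @export
parse_blast_tabular <- function(x, evalue_ceiling = 1e-3) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits("blast"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  evcol <- ifelse(nf >= 12L, 11L, ifelse(nf == 3L, 3L, NA_integer_))
  if (anyNA(evcol))
    stop(sprintf("BLAST tabular line %d has %d columns (expected 3 or >= 12)",
                 which(is.na(evcol))[1], nf[which(is.na(evcol))[1]]))
  ev_chr <- mapply(function(f, i) f[i], fields, evcol)
  ev <- suppressWarnings(as.numeric(ev_chr))
  if (anyNA(ev))
    stop(sprintf("non-numeric e-value '%s' on line %d",
                 ev_chr[which(is.na(ev))[1]], which(is.na(ev))[1]))
  hits <- data.frame(query = vapply(fields, `[`, character(1), 1L),
                     subject = extract_accession(
                       vapply(fields, `[`, character(1), 2L)),
                     evalue = ev, source = "blast",
                     stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= evalue_ceiling, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Parse a HMMER tblout hit file
#'
#' Whitespace-delimited `tblout` layout: target name, target accession, query
#' name, query accession, full-sequence e-value, ... Lines starting with `#`
#' are comments. The model accession (with any trailing `.N` version removed)
#' identifies the hit; when the accession field is `-` the target name is used
#' instead. Duplicate (query, model) pairs keep the smallest e-value.
#'
#' @inheritParams parse_blast_tabular
#' @return A data.frame of hits: `query`, `subject` (model accession),
#'   `evalue`, `source` (`"hmmer"`).
#' @export
parse_hmmer_tabular <- function(x, evalue_ceiling = 1e-3) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits("hmmer"))
  fields <- strsplit(trimws(lines), "\\s+")
  short <- which(vapply(fields, length, integer(1)) < 5L)
  if (length(short))
    stop(sprintf("HMMER tblout line %d has fewer than 5 fields", short[1]))
  target <- vapply(fields, `[`, character(1), 1L)
  acc <- vapply(fields, `[`, character(1), 2L)
  model <- ifelse(acc == "-", target, sub("\\.\\d+$", "", acc))
  ev_chr <- vapply(fields, `[`, character(1), 5L)
  ev <- suppressWarnings(as.numeric(ev_chr))
  if (anyNA(ev))
    stop(sprintf("non-numeric e-value '%s' on line %d",
                 ev_chr[which(is.na(ev))[1]], which(is.na(ev))[1]))
  hits <- data.frame(query = vapply(fields, `[`, character(1), 3L),
                     subject = model, evalue = ev, source = "hmmer",
                     stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= evalue_ceiling, , drop = FALSE]
  if (nrow(hits)) {
    hits <- hits[order(hits$query, hits$subject, hits$evalue), , drop = FALSE]
    hits <- hits[!duplicated(hits[, c("query", "subject")]), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

empty_hits <- function(source) {
  data.frame(query = character(0), subject = character(0),
             evalue = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Parse a domain-model to GO-term frequency table
#'
#' Tab-separated columns: model accession, GO id, number of the model's
#' proteins annotated with the term, total number of proteins in the model.
#' This enriches a plain pfam2go-style mapping with per-term frequencies.
#'
#' @inheritParams parse_blast_tabular
#' @return A data.frame: `model`, `term`, `n_with_term`, `n_total`.
#' @export
parse_pfam_frequencies <- function(x) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(model = character(0), term = character(0),
                      n_with_term = integer(0), n_total = integer(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 4L)
  if (length(short))
    stop(sprintf("frequency table line %d has fewer than 4 columns", short[1]))
  df <- data.frame(model = vapply(fields, `[`, character(1), 1L),
                   term = vapply(fields, `[`, character(1), 2L),
                   n_with_term = as.integer(
                     vapply(fields, `[`, character(1), 3L)),
                   n_total = as.integer(vapply(fields, `[`, character(1), 4L)),
                   stringsAsFactors = FALSE)
  if (anyNA(df$n_with_term) || anyNA(df$n_total))
    stop("non-integer count in frequency table")
  if (any(df$n_total <= 0) || any(df$n_with_term < 0 |
                                  df$n_with_term > df$n_total))
    stop("counts must satisfy 0 <= n_with_term <= n_total, n_total > 0")
  df
}

#' Map hits to GO terms and merge into per-protein weighted term sets
#'
#' Each BLAST hit contributes its weight to every GO term annotated on its
#' subject in the annotation records; each HMMER hit contributes its
#' frequency-rewarded weight to every GO term mapped to its model. Multiple
#' contributions to the same (protein, term) pair are summed by default (a
#' term supported by convergent evidence accumulates weight); `"max"` keeps
#' the single strongest contribution instead. Subjects missing from the
#' annotation records, models missing from the frequency table and terms
#' missing from the ontology are skipped with a warning.
#'
#' @param blast_hits,hmmer_hits Hit data.frames from [parse_blast_tabular()] /
#'   [parse_hmmer_tabular()]; either may be `NULL`.
#' @param annotations Data.frame of annotation records (`object`, `term`),
#'   e.g. from [parse_gaf()]; maps BLAST subjects to GO terms.
#' @param pfam_freq Data.frame from [parse_pfam_frequencies()]; maps HMMER
#'   models to GO terms. Required when `hmmer_hits` is non-empty.
#' @param ontology A `go_ontology`.
#' @param config A [gosieve_config()] list (e-value floor, logistic
#'   parameters, aggregation rule, self-hit exclusion).
#' @return A data.frame of class `weighted_terms`: `protein`, `term`,
#'   `namespace`, `weight` — one row per distinct (protein, term), all
#'   weights positive.
#' @export
map_and_merge <- function(blast_hits = NULL, hmmer_hits = NULL,
                          annotations = NULL, pfam_freq = NULL,
                          ontology, config = gosieve_config()) {
  pieces <- list()

  if (!is.null(blast_hits) && nrow(blast_hits)) {
    if (is.null(annotations))
      stop("BLAST hits given but no annotation records to map subjects")
    if (isTRUE(config$exclude_self_hits))
      blast_hits <- blast_hits[blast_hits$subject != blast_hits$query, ,
                               drop = FALSE]
    ann <- unique(annotations[, c("object", "term")])
    known <- blast_hits$subject %in% ann$object
    if (any(!known))
      warning(sprintf("%d BLAST hit(s) with subjects absent from the %s",
                      sum(!known), "annotation records were skipped"))
    bh <- blast_hits[known, , drop = FALSE]
    if (nrow(bh)) {
      idx <- split(seq_len(nrow(ann)), ann$object)
      rows <- lapply(seq_len(nrow(bh)), function(i) {
        j <- idx[[bh$subject[i]]]
        data.frame(protein = bh$query[i], term = ann$term[j],
                   weight = blast_weight(bh$evalue[i],
                                         floor = config$evalue_floor),
                   stringsAsFactors = FALSE)
      })
      pieces <- c(pieces, rows)
    }
  }

  if (!is.null(hmmer_hits) && nrow(hmmer_hits)) {
    if (is.null(pfam_freq))
      stop("HMMER hits given but no model-to-term frequency table")
    known <- hmmer_hits$subject %in% pfam_freq$model
    if (any(!known))
      warning(sprintf("%d HMMER hit(s) with models absent from the %s",
                      sum(!known), "frequency table were skipped"))
    hh <- hmmer_hits[known, , drop = FALSE]
    if (nrow(hh)) {
      idx <- split(seq_len(nrow(pfam_freq)), pfam_freq$model)
      rows <- lapply(seq_len(nrow(hh)), function(i) {
        j <- idx[[hh$subject[i]]]
        data.frame(protein = hh$query[i], term = pfam_freq$term[j],
                   weight = hmmer_weight(hh$evalue[i],
                                         pfam_freq$n_with_term[j],
                                         pfam_freq$n_total[j],
                                         steepness = config$logistic_steepness,
                                         midpoint = config$logistic_midpoint,
                                         floor = config$evalue_floor),
                   stringsAsFactors = FALSE)
      })
      pieces <- c(pieces, rows)
    }
  }

  if (!length(pieces)) return(empty_weighted_terms())
  all_rows <- do.call(rbind, pieces)

  resolved <- resolve_term(ontology, all_rows$term, strict = FALSE)
  if (anyNA(resolved))
    warning(sprintf("dropping %d contribution(s) citing terms absent %s",
                    sum(is.na(resolved)), "from the ontology"))
  all_rows$term <- resolved
  all_rows <- all_rows[!is.na(all_rows$term) & all_rows$weight > 0, ,
                       drop = FALSE]
  aggregate_weighted(all_rows, ontology, config$aggregation)
}

#' Parse a pre-weighted GO term table (consensus input)
#'
#' Tab-separated columns: protein, GO id, positive weight. Lets externally
#' computed annotations (any method or database) enter the scoring engine
#' directly, bypassing the e-value weighting stage. Duplicate
#' (protein, term) rows are summed.
#'
#' @inheritParams parse_blast_tabular
#' @param ontology A `go_ontology`; terms absent from it are dropped with a
#'   warning (alt_ids resolve first).
#' @return A `weighted_terms` data.frame (`protein`, `term`, `namespace`,
#'   `weight`).
#' @export
parse_weighted_terms <- function(x, ontology) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_weighted_terms())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short))
    stop(sprintf("weighted-term line %d has fewer than 3 columns", short[1]))
  terms <- vapply(fields, `[`, character(1), 2L)
  bad_id <- which(!grepl("^GO:\\d{7}$", terms))
  if (length(bad_id))
    stop(sprintf("malformed GO id '%s' on line %d",
                 terms[bad_id[1]], bad_id[1]))
  w_chr <- vapply(fields, `[`, character(1), 3L)
  w <- suppressWarnings(as.numeric(w_chr))
  bad_w <- which(is.na(w) | w <= 0)
  if (length(bad_w))
    stop(sprintf("weight '%s' on line %d is not a positive number",
                 w_chr[bad_w[1]], bad_w[1]))
  df <- data.frame(protein = vapply(fields, `[`, character(1), 1L),
                   term = terms, weight = w, stringsAsFactors = FALSE)
  resolved <- resolve_term(ontology, df$term, strict = FALSE)
  if (anyNA(resolved))
    warning(sprintf("dropping %d row(s) citing terms absent from the %s",
                    sum(is.na(resolved)), "ontology"))
  df$term <- resolved
  df <- df[!is.na(df$term), , drop = FALSE]
  aggregate_weighted(df, ontology, "sum")
}

aggregate_weighted <- function(df, ontology, aggregation = c("sum", "max")) {
  aggregation <- match.arg(aggregation)
  if (!nrow(df)) return(empty_weighted_terms())
  fun <- if (aggregation == "sum") sum else max
  agg <- stats::aggregate(weight ~ protein + term, data = df, FUN = fun)
  agg$namespace <- unname(ontology$namespace[agg$term])
  agg <- agg[order(agg$protein, agg$namespace, agg$term),
             c("protein", "term", "namespace", "weight")]
  rownames(agg) <- NULL
  class(agg) <- c("weighted_terms", "data.frame")
  agg
}

empty_weighted_terms <- function() {
  structure(data.frame(protein = character(0), term = character(0),
                       namespace = character(0), weight = numeric(0),
                       stringsAsFactors = FALSE),
            class = c("weighted_terms", "data.frame"))
}
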