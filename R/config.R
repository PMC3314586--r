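# Run configuration shared by the evidence and scoring stages.

#' Default run configuration
#'
#' Collects every tunable of the pipeline in one list. Values can be
#' overridden by name; unknown names raise an error.
#'
#' @param ... Named overrides of the defaults below.
#' @return A named list of class `gosieve_config`:
#' \describe{
#'   \item{evalue_floor}{Smallest admissible e-value (`1e-180`); e-values of
#'     0 are clamped here, capping the hit weight at 180.}
#'   \item{evalue_ceiling}{Largest e-value a hit may have to enter the
#'     analysis (`1e-3`).}
#'   \item{logistic_steepness, logistic_midpoint}{Parameters of the
#'     frequency-reward curve for domain-model terms (10 and 0.5).}
#'   \item{aggregation}{How multiple contributions to one (protein, term)
#'     combine: `"sum"` (default) or `"max"`.}
#'   \item{exclude_self_hits}{Drop BLAST hits whose subject accession equals
#'     the query (needed when benchmark proteins stay in the databank).}
#'   \item{ic_base}{Log base for information content (natural log).}
#'   \item{unseen_epsilon}{IC surcharge for corpus-unseen terms.}
#'   \item{sim_threshold}{Lin similarity at or above which two terms join
#'     the same group (0.7).}
#'   \item{z_threshold, grs_threshold, ts_threshold}{Filter cutoffs on the
#'     Z-score (0), the Group Score (0.2) and the reported Total Score (0).}
#'   \item{sigma_source}{Population the Z-score standard deviation is taken
#'     over: cumulative weights of the whole slim (`"slim"`, default) or the
#'     input term weights (`"input"`).}
#'   \item{wbar_denominator}{Count dividing the root weight to give the mean
#'     weight: `"slim"` terms (default) or `"input"` terms.}
#'   \item{representatives_only}{Report only each group's top-scoring term?}
#'   \item{include_part_of}{Follow `part_of` edges when parsing the
#'     ontology.}
#'   \item{evidence_exclude}{Evidence codes excluded when reading a GAF
#'     (`NULL`: keep all, including IEA).}
#'   \item{corpus_count}{Count `"records"` or distinct `"pairs"` when
#'     building the annotation corpus.}
#' }
#' @export
gosieve_config <- function(...) {
  cfg <- list(
    evalue_floor = 1e-180,
    evalue_ceiling = 1e-3,
    logistic_steepness = 10,
    logistic_midpoint = 0.5,
    aggregation = "sum",
    exclude_self_hits = FALSE,
    ic_base = exp(1),
    unseen_epsilon = 1e-6,
    sim_threshold = 0.7,
    z_threshold = 0,
    grs_threshold = 0.2,
    ts_threshold = 0,
    sigma_source = "slim",
    wbar_denominator = "slim",
    representatives_only = FALSE,
    include_part_of = TRUE,
    evidence_exclude = NULL,
    corpus_count = "records"
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("configuration overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration option(s): ",
           paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$evalue_floor > 0, cfg$evalue_ceiling > 0,
            cfg$aggregation %in% c("sum", "max"),
            cfg$sigma_source %in% c("slim", "input"),
            cfg$wbar_denominator %in% c("slim", "input"),
            cfg$corpus_count %in% c("records", "pairs"))
  structure(cfg, class = c("gosieve_config", "list"))
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [gosieve_config()]; keys present in the file
#' override the defaults, everything else keeps its default.
#'
#' @param path Path to a YAML file.
#' @return A `gosieve_config` list.
#' @export
read_gosieve_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(gosieve_config())
  do.call(gosieve_config, vals)
}
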