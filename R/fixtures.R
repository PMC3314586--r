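# Synthetic fixtures: random toy ontologies, annotation corpora, hit tables
# and planted-truth benchmarks, so the full pipeline runs with no downloads.

#' Specification for a synthetic benchmark
#'
#' The defaults describe a small but structured study: three namespaces of
#' 15/15/10 terms, 10 target proteins each carrying one planted (true) term
#' per namespace, a background corpus of 120 annotation records giving the
#' information content some texture, signal hits at e-values 1e-60..1e-30
#' and decoy hits at 1e-8..1e-4 — at least three orders of magnitude apart,
#' so true and false evidence are unambiguous by construction. A quarter of
#' the planted terms are supported only by domain-model (HMMER-style)
#' evidence, emulating functions visible to profile searches but missed by
#' pairwise sequence similarity.
#'
#' @param seed Integer seed; all randomness in the generators flows from it.
#' @param n_terms Named integer vector: terms per namespace (root included).
#' @param max_parents Maximum parents drawn for a non-root term.
#' @param n_proteins Number of target proteins.
#' @param n_background Background annotation records in the corpus.
#' @param hit_noise Probability that a (protein, namespace) also receives a
#'   decoy hit, in `[0, 1]`.
#' @param evalue_signal,evalue_decoy `(min, max)` e-value ranges, sampled
#'   log-uniformly.
#' @param hmmer_fraction Probability that a planted term is covered by
#'   domain evidence instead of sequence-similarity evidence.
#' @param n_signal_hits Signal hits supporting each sequence-covered term.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1,
                         n_terms = c(molecular_function = 15,
                                     biological_process = 15,
                                     cellular_component = 10),
                         max_parents = 2,
                         n_proteins = 10,
                         n_background = 120,
                         hit_noise = 0.3,
                         evalue_signal = c(1e-60, 1e-30),
                         evalue_decoy = c(1e-8, 1e-4),
                         hmmer_fraction = 0.25,
                         n_signal_hits = 2) {
  stopifnot(length(n_terms) >= 1, all(n_terms >= 1), max_parents >= 1,
            n_proteins >= 1, n_background >= 0,
            hit_noise >= 0, hit_noise <= 1,
            all(evalue_signal > 0), all(evalue_decoy > 0),
            hmmer_fraction >= 0, hmmer_fraction <= 1, n_signal_hits >= 1)
  if (is.null(names(n_terms)))
    names(n_terms) <- c("molecular_function", "biological_process",
                        "cellular_component")[seq_along(n_terms)]
  structure(list(seed = as.integer(seed), n_terms = n_terms,
                 max_parents = max_parents, n_proteins = n_proteins,
                 n_background = n_background, hit_noise = hit_noise,
                 evalue_signal = sort(evalue_signal),
                 evalue_decoy = sort(evalue_decoy),
                 hmmer_fraction = hmmer_fraction,
                 n_signal_hits = n_signal_hits),
            class = "fixture_spec")
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Generate a random layered toy ontology
#'
#' One root per namespace; each later term draws 1..`max_parents` parents
#' uniformly from the terms already generated in its namespace, so the graph
#' is acyclic by construction. Identifiers are sequential `GO:0000001`-style
#' ids across namespaces. The OBO text is rendered first and the returned
#' graph is its parse, so text and graph agree by definition.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `obo` (character vector of OBO lines) and `ontology`
#'   (the parsed `go_ontology`).
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    lines <- c("format-version: 1.2", "ontology: toy")
    counter <- 0L
    for (ns in names(spec$n_terms)) {
      n <- spec$n_terms[[ns]]
      ids <- sprintf("GO:%07d", counter + seq_len(n))
      counter <- counter + n
      for (i in seq_len(n)) {
        lines <- c(lines, "", "[Term]",
                   paste0("id: ", ids[i]),
                   sprintf("name: %s term %d", ns, i),
                   paste0("namespace: ", ns))
        if (i > 1L) {
          k <- sample.int(min(spec$max_parents, i - 1L), 1L)
          pars <- sample(ids[seq_len(i - 1L)], k)
          lines <- c(lines, paste0("is_a: ", sort(pars)))
        }
      }
    }
    list(obo = lines, ontology = parse_obo(lines))
  })
}

aspect_letter <- c(molecular_function = "F", biological_process = "P",
                   cellular_component = "C")

#' Write annotation records as a GAF 2.2 file
#'
#' @param annotations Data.frame with columns `object`, `term` and optionally
#'   `evidence` (default `IEA`).
#' @param ontology A `go_ontology` (supplies the aspect column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, ontology, path) {
  ev <- if ("evidence" %in% names(annotations)) annotations$evidence
        else rep("IEA", nrow(annotations))
  ns <- ontology$namespace[resolve_term(ontology, annotations$term)]
  asp <- aspect_letter[ns]
  lines <- c("!gaf-version: 2.2",
             if (nrow(annotations))
               sprintf(paste0("DB\t%s\t%s\t\t%s\tREF:0000001\t%s\t\t%s\t",
                              "\t\tprotein\ttaxon:0000\t20120101\tDB\t\t"),
                       annotations$object, annotations$object,
                       annotations$term, ev, asp))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a planted-truth benchmark
#'
#' Plants one true GO term per namespace on each target protein and
#' fabricates the evidence a real run would see: a databank of annotated
#' proteins (GAF), sequence-similarity hits at signal e-values pointing at
#' databank proteins that carry the true terms, optional domain-model hits
#' whose model maps to the true term with high frequency, and — with
#' probability `hit_noise` per (protein, namespace) — a decoy hit at a much
#' weaker e-value pointing at an unrelated term. In `mode = "with"` the
#' targets themselves are additionally present in the databank, annotated
#' with their true terms, and each target gets an exact self-hit at the
#' e-value floor; `mode = "without"` leaves them out. The random draws are
#' identical in both modes (the self rows are appended afterwards), so the
#' two modes are directly comparable on the same seed.
#'
#' @param spec A [fixture_spec()].
#' @param ontology A `go_ontology` from [make_ontology()].
#' @param dir Output directory (created if missing); files written:
#'   `ontology.obo`, `corpus.gaf`, `blast.tsv`, `hmmer.tbl`,
#'   `pfam_freq.tsv`, `truth.tsv`.
#' @param mode `"without"` (targets absent from the databank) or `"with"`.
#' @param obo Optional OBO lines to write alongside (from [make_ontology()]).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (data.frame `protein`, `term`) and `channel` (data.frame recording
#'   whether each planted term is covered by `blast` or `hmmer` evidence).
#' @export
make_benchmark <- function(spec, ontology, dir,
                           mode = c("without", "with"), obo = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  namespaces <- names(spec$n_terms)
  targets <- sprintf("TGT%03d", seq_len(spec$n_proteins))

  res <- with_seed(spec$seed + 1L, {
    truth <- list(); gaf <- list(); blast <- list(); hmmer <- list()
    freq <- list(); channel <- list()
    db_counter <- 0L; pf_counter <- 0L

    candidates <- lapply(namespaces, function(ns) {
      ns_terms <- ontology$terms[ontology$namespace == ns]
      non_root <- setdiff(ns_terms, ontology$roots[[ns]])
      deep <- non_root[vapply(ontology$ancestors[non_root], length,
                              integer(1)) >= 3L]
      if (length(deep)) deep else non_root
    })
    names(candidates) <- namespaces

    for (p in targets) {
      for (ns in namespaces) {
        cand <- candidates[[ns]]
        if (!length(cand)) next
        true_term <- if (length(cand) == 1L) cand else sample(cand, 1L)
        truth[[length(truth) + 1L]] <- data.frame(protein = p,
                                                  term = true_term)
        use_hmmer <- stats::runif(1) < spec$hmmer_fraction
        channel[[length(channel) + 1L]] <-
          data.frame(protein = p, term = true_term, namespace = ns,
                     channel = if (use_hmmer) "hmmer" else "blast")

        if (use_hmmer) {
          pf_counter <- pf_counter + 1L
          model <- sprintf("PF%05d", pf_counter)
          freq[[length(freq) + 1L]] <-
            data.frame(model = model, term = true_term,
                       n_with_term = 95L, n_total = 100L)
          # a sparse off-path side term exercises the logistic damping
          side <- setdiff(candidates[[ns]],
                          c(ontology$ancestors[[true_term]],
                            ontology$descendants[[true_term]]))
          if (length(side))
            freq[[length(freq) + 1L]] <-
              data.frame(model = model,
                         term = if (length(side) == 1L) side
                                else sample(side, 1L),
                         n_with_term = 3L, n_total = 100L)
          hmmer[[length(hmmer) + 1L]] <-
            data.frame(query = p, model = model,
                       evalue = runif_log(1, spec$evalue_signal))
          # the term still needs corpus presence for its IC
          db_counter <- db_counter + 1L
          gaf[[length(gaf) + 1L]] <-
            data.frame(object = sprintf("DBK%04d", db_counter),
                       term = true_term)
        } else {
          for (h in seq_len(spec$n_signal_hits)) {
            db_counter <- db_counter + 1L
            db <- sprintf("DBK%04d", db_counter)
            gaf[[length(gaf) + 1L]] <- data.frame(object = db,
                                                  term = true_term)
            blast[[length(blast) + 1L]] <-
              data.frame(query = p, subject = db,
                         evalue = runif_log(1, spec$evalue_signal))
          }
        }

        if (stats::runif(1) < spec$hit_noise) {
          off_path <- setdiff(ontology$terms[ontology$namespace == ns],
                              c(ontology$ancestors[[true_term]],
                                ontology$descendants[[true_term]]))
          if (length(off_path)) {
            decoy_term <- if (length(off_path) == 1L) off_path
                          else sample(off_path, 1L)
            db_counter <- db_counter + 1L
            db <- sprintf("DBK%04d", db_counter)
            gaf[[length(gaf) + 1L]] <- data.frame(object = db,
                                                  term = decoy_term)
            blast[[length(blast) + 1L]] <-
              data.frame(query = p, subject = db,
                         evalue = runif_log(1, spec$evalue_decoy))
          }
        }
      }
    }

    if (spec$n_background > 0) {
      bg_terms <- sample(ontology$terms, spec$n_background, replace = TRUE)
      gaf[[length(gaf) + 1L]] <-
        data.frame(object = sprintf("BGD%04d", seq_len(spec$n_background)),
                   term = bg_terms)
    }

    list(truth = do.call(rbind, truth), gaf = do.call(rbind, gaf),
         blast = do.call(rbind, blast),
         hmmer = if (length(hmmer)) do.call(rbind, hmmer) else NULL,
         freq = if (length(freq)) do.call(rbind, freq) else NULL,
         channel = do.call(rbind, channel))
  })

  if (mode == "with") {
    res$gaf <- rbind(res$gaf,
                     data.frame(object = res$truth$protein,
                                term = res$truth$term))
    self <- unique(res$truth$protein)
    res$blast <- rbind(res$blast,
                       data.frame(query = self, subject = self,
                                  evalue = 1e-180))
  }

  paths <- c(obo = file.path(dir, "ontology.obo"),
             gaf = file.path(dir, "corpus.gaf"),
             blast = file.path(dir, "blast.tsv"),
             hmmer = file.path(dir, "hmmer.tbl"),
             pfam_freq = file.path(dir, "pfam_freq.tsv"),
             truth = file.path(dir, "truth.tsv"))
  if (!is.null(obo)) writeLines(obo, paths[["obo"]])
  write_gaf(res$gaf, ontology, paths[["gaf"]])
  writeLines(if (is.null(res$blast) || !nrow(res$blast)) character(0) else
    sprintf("%s\t%s\t50.0\t100\t0\t0\t1\t100\t1\t100\t%.3e\t200.0",
            res$blast$query, res$blast$subject, res$blast$evalue),
    paths[["blast"]])
  writeLines(c("# toy tblout",
               if (!is.null(res$hmmer))
                 sprintf("%s_name  %s.1  %s  -  %.3e  150.0  0.1",
                         res$hmmer$model, res$hmmer$model,
                         res$hmmer$query, res$hmmer$evalue)),
             paths[["hmmer"]])
  writeLines(if (is.null(res$freq)) character(0) else
    sprintf("%s\t%s\t%d\t%d", res$freq$model, res$freq$term,
            res$freq$n_with_term, res$freq$n_total),
    paths[["pfam_freq"]])
  writeLines(sprintf("%s\t%s", res$truth$protein, res$truth$term),
             paths[["truth"]])

  invisible(list(paths = paths, truth = res$truth, channel = res$channel))
}
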