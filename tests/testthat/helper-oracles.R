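# Brute-force reference implementations and tiny hand-built fixtures.
# The oracles deliberately avoid the package's precomputed closures: they
# work from the raw parent lists by exhaustive path enumeration.

# every upward simple path from t, as a list of node vectors
enumerate_paths <- function(parents, t) {
  ps <- parents[[t]]
  if (!length(ps)) return(list(t))
  out <- list()
  for (p in ps)
    for (path in enumerate_paths(parents, p))
      out[[length(out) + 1L]] <- c(t, path)
  out
}

oracle_ancestors <- function(parents, t) {
  sort(unique(unlist(enumerate_paths(parents, t))))
}

# cumulative corpus count of `a` = direct counts of every term whose
# ancestor set (by path enumeration) contains `a`
oracle_cumulative <- function(parents, direct, a) {
  sum(vapply(names(direct), function(t)
    if (a %in% oracle_ancestors(parents, t)) direct[[t]] else 0L,
    numeric(1)))
}

oracle_ic <- function(parents, direct, total, a, base = exp(1)) {
  cum <- oracle_cumulative(parents, direct, a)
  if (cum == 0) return(-log(1 / total) / log(base) + 1e-6)
  -log(cum / total) / log(base)
}

oracle_resnik <- function(parents, direct, total, t1, t2, base = exp(1)) {
  common <- intersect(oracle_ancestors(parents, t1),
                      oracle_ancestors(parents, t2))
  max(vapply(common, function(a)
    oracle_ic(parents, direct, total, a, base), numeric(1)))
}

oracle_lin <- function(parents, direct, total, t1, t2, base = exp(1)) {
  ic1 <- oracle_ic(parents, direct, total, t1, base)
  ic2 <- oracle_ic(parents, direct, total, t2, base)
  if (ic1 + ic2 == 0) return(if (t1 == t2) 1 else 0)
  2 * oracle_resnik(parents, direct, total, t1, t2, base) / (ic1 + ic2)
}

# cumulative slim weight by ancestor-membership sums
oracle_slim_W <- function(parents, input_w, g) {
  sum(vapply(names(input_w), function(t)
    if (g %in% oracle_ancestors(parents, t)) input_w[[t]] else 0,
    numeric(1)))
}

# single-linkage partition from a similarity matrix: boolean transitive
# closure of the thresholded adjacency, read off as canonical member sets
oracle_single_linkage <- function(simmat, threshold) {
  n <- nrow(simmat)
  reach <- (simmat >= threshold) | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  groups <- unique(lapply(seq_len(n),
                          function(i) sort(colnames(simmat)[reach[i, ]])))
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

oracle_confusion <- function(pred_terms, true_terms) {
  c(tp = length(intersect(pred_terms, true_terms)),
    fp = length(setdiff(pred_terms, true_terms)),
    fn = length(setdiff(true_terms, pred_terms)))
}

# ---- hand-built fixtures -------------------------------------------------

obo_header <- c("format-version: 1.2")

obo_term <- function(id, ns, parents = character(0), extra = character(0)) {
  c("", "[Term]", paste0("id: ", id), paste0("name: ", id),
    paste0("namespace: ", ns),
    if (length(parents)) paste0("is_a: ", parents), extra)
}

# root <- mid <- leaf, one namespace
chain_obo <- function(ns = "molecular_function") {
  c(obo_header,
    obo_term("GO:0000001", ns),
    obo_term("GO:0000002", ns, "GO:0000001"),
    obo_term("GO:0000003", ns, "GO:0000002"))
}

# leaf with two parents a, b, both under root
diamond_obo <- function(ns = "molecular_function") {
  c(obo_header,
    obo_term("GO:0000001", ns),
    obo_term("GO:0000002", ns, "GO:0000001"),
    obo_term("GO:0000003", ns, "GO:0000001"),
    obo_term("GO:0000004", ns, c("GO:0000002", "GO:0000003")))
}

# two sibling branches under the root, two levels deep:
#        root(1)
#        /     \
#      2         3
#     / \        |
#    4   5       6
two_branch_obo <- function(ns = "molecular_function") {
  c(obo_header,
    obo_term("GO:0000001", ns),
    obo_term("GO:0000002", ns, "GO:0000001"),
    obo_term("GO:0000003", ns, "GO:0000001"),
    obo_term("GO:0000004", ns, "GO:0000002"),
    obo_term("GO:0000005", ns, "GO:0000002"),
    obo_term("GO:0000006", ns, "GO:0000003"))
}

# a random single-namespace toy: ontology + corpus + weighted input terms
random_engine_fixture <- function(seed, n_terms = 10, n_inputs = 4,
                                  n_records = 40) {
  spec <- fixture_spec(seed = seed,
                       n_terms = c(molecular_function = n_terms),
                       max_parents = 3)
  ont <- make_ontology(spec)$ontology
  set.seed(seed + 10000L)
  recs <- sample(ont$terms, n_records, replace = TRUE)
  corpus <- annotation_corpus(recs, ont)
  inputs <- sample(ont$terms, min(n_inputs, length(ont$terms)))
  wts <- data.frame(term = inputs,
                    weight = round(stats::runif(length(inputs), 1, 50), 3),
                    stringsAsFactors = FALSE)
  list(ontology = ont, corpus = corpus, wts = wts,
       parents = ont$parents, direct = corpus$direct)
}

# run the full fixture benchmark and return the m1/m2 curves plus records
run_fixture_benchmark <- function(spec, mode = "without",
                                  use_hmmer = TRUE,
                                  config = gosieve_config(),
                                  n_points = 25) {
  ont <- make_ontology(spec)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  bm <- make_benchmark(spec, ont$ontology, dir, mode = mode, obo = ont$obo)
  ann <- suppressWarnings(annotate_files(
    bm$paths[["obo"]], bm$paths[["gaf"]],
    blast = bm$paths[["blast"]],
    hmmer = if (use_hmmer) bm$paths[["hmmer"]],
    pfam_freq = if (use_hmmer) bm$paths[["pfam_freq"]],
    config = config))
  truth <- read_truth_table(bm$paths[["truth"]])
  preds <- data.frame(protein = ann$protein, term = ann$term,
                      score = ann$ts, stringsAsFactors = FALSE)
  records <- benchmark_records(preds, truth)
  list(annotations = ann, truth = truth, records = records,
       ontology = ont$ontology, benchmark = bm,
       m1 = pr_curve(records, "m1", ont$ontology, n_points = n_points),
       m2 = pr_curve(records, "m2", ont$ontology, n_points = n_points))
}
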