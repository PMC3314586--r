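# GO-slim construction, grouping, filtering and Total Score.

# chain of 4 with a geometric corpus: IC(2)=log2, IC(3)=2log2, IC(4)=3log2
chain4_fixture <- function() {
  obo <- c(obo_header,
           obo_term("GO:0000001", "molecular_function"),
           obo_term("GO:0000002", "molecular_function", "GO:0000001"),
           obo_term("GO:0000003", "molecular_function", "GO:0000002"),
           obo_term("GO:0000004", "molecular_function", "GO:0000003"))
  ont <- parse_obo(obo)
  recs <- rep(c("GO:0000004", "GO:0000003", "GO:0000002", "GO:0000001"),
              c(2L, 2L, 4L, 8L))
  list(ontology = ont, corpus = annotation_corpus(recs, ont))
}

test_that("single-path slim carries the input weight everywhere", {
  ont <- parse_obo(chain_obo())
  slim <- build_goslim(data.frame(term = "GO:0000003", weight = 4), ont)
  expect_setequal(slim$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(unname(slim$W[slim$terms]), rep(4, 3))
  expect_equal(slim$sigma, 0)
  expect_equal(unname(slim$Z[slim$terms]), rep(0, 3))
  expect_equal(build_goslim(NULL, ont)$terms, character(0))
})

test_that("an internal node cumulates its retrieved children; a reconstructed
           ancestor of one retrieved node inherits exactly its weight", {
  # root(1) with children 2 and 4; B(5) under 2; C(6) under both 2 and 4.
  obo <- c(obo_header,
           obo_term("GO:0000001", "molecular_function"),
           obo_term("GO:0000002", "molecular_function", "GO:0000001"),
           obo_term("GO:0000004", "molecular_function", "GO:0000001"),
           obo_term("GO:0000005", "molecular_function", "GO:0000002"),
           obo_term("GO:0000006", "molecular_function",
                    c("GO:0000002", "GO:0000004")))
  ont <- parse_obo(obo)
  w_b <- 7; w_c <- 2
  slim <- build_goslim(data.frame(term = c("GO:0000005", "GO:0000006"),
                                  weight = c(w_b, w_c)), ont)
  expect_equal(unname(slim$W[["GO:0000002"]]), w_b + w_c)
  expect_equal(unname(slim$W[["GO:0000004"]]), w_c)
  expect_equal(unname(slim$W[[slim$root]]), w_b + w_c)
  # the reconstructed ancestor contributes no mass of its own
  expect_equal(unname(slim$w[["GO:0000004"]]), 0)
})

test_that("slim cumulative weights match the ancestor-membership oracle", {
  for (seed in 1:6) {
    fx <- random_engine_fixture(seed, n_terms = 12, n_inputs = 5)
    slim <- build_goslim(fx$wts, fx$ontology)
    input_w <- setNames(fx$wts$weight, fx$wts$term)
    expect_setequal(slim$terms,
                    unique(unlist(lapply(fx$wts$term, function(t)
                      oracle_ancestors(fx$parents, t)))))
    for (g in slim$terms)
      expect_equal(unname(slim$W[[g]]),
                   oracle_slim_W(fx$parents, input_w, g))
  }
})

test_that("internal confidence is the share of evidence through a node", {
  ont <- parse_obo(chain_obo())
  slim <- build_goslim(data.frame(term = "GO:0000003", weight = 4), ont)
  expect_equal(unname(internal_confidence(slim, slim$root)), 1)
  expect_equal(unname(internal_confidence(slim)), rep(1, 3))
  tb <- parse_obo(two_branch_obo())
  slim2 <- build_goslim(data.frame(term = c("GO:0000004", "GO:0000006"),
                                   weight = c(3, 1)), tb)
  expect_equal(unname(internal_confidence(slim2, "GO:0000002")), 0.75)
  expect_equal(unname(internal_confidence(slim2, "GO:0000003")), 0.25)
  expect_equal(unname(noncumulative_internal_confidence(slim2,
                                                        "GO:0000006")),
               0.25)
  # reconstructed ancestors were never retrieved, so their own weight is 0
  expect_equal(unname(noncumulative_internal_confidence(slim2,
                                                        "GO:0000002")), 0)
  expect_equal(
    unname(noncumulative_internal_confidence(slim2, "GO:0000004")), 0.75)
  expect_error(internal_confidence(slim2, "GO:0000099"), "not in slim")
})

test_that("similarity grouping follows single-linkage chaining", {
  fx <- chain4_fixture()
  wts <- data.frame(term = c("GO:0000002", "GO:0000003", "GO:0000004"),
                    weight = c(1, 1, 1))
  slim <- build_goslim(wts, fx$ontology)
  # pairwise Lin: (4,3)=0.8, (3,2)=2/3, (4,2)=0.5
  expect_equal(lin_similarity(fx$ontology, fx$corpus,
                              "GO:0000004", "GO:0000003"), 0.8)
  # at 0.6 the 4-3 and 3-2 links chain all three into one group
  g06 <- group_by_similarity(slim, fx$ontology, fx$corpus,
                             gosieve_config(sim_threshold = 0.6))
  expect_equal(unname(g06$membership), rep(1L, 3))
  # at 0.7 only 4-3 links; 2 stays alone
  g07 <- group_by_similarity(slim, fx$ontology, fx$corpus,
                             gosieve_config(sim_threshold = 0.7))
  expect_equal(length(unique(g07$membership)), 2L)
  expect_equal(g07$membership[["GO:0000003"]],
               g07$membership[["GO:0000004"]])
  # group scores are the summed (non-)cumulative internal confidences
  inc <- internal_confidence(slim, wts$term)
  expect_equal(g06$groups$grs, sum(inc))
  expect_equal(g06$groups$grs_nc, 1)  # input weights sum to W(root)
  # a lone input term forms a singleton group with GrS = InC
  s1 <- build_goslim(data.frame(term = "GO:0000004", weight = 2),
                     fx$ontology)
  gs <- group_by_similarity(s1, fx$ontology, fx$corpus)
  expect_equal(gs$groups$grs, unname(internal_confidence(s1, "GO:0000004")))
})

test_that("grouping matches the brute-force transitive-closure oracle", {
  for (seed in 1:6) {
    fx <- random_engine_fixture(seed, n_terms = 12, n_inputs = 5)
    slim <- build_goslim(fx$wts, fx$ontology)
    cfg <- gosieve_config(sim_threshold = 0.5)
    grouping <- group_by_similarity(slim, fx$ontology, fx$corpus, cfg)
    terms <- slim$input_terms
    simmat <- matrix(1, length(terms), length(terms),
                     dimnames = list(terms, terms))
    for (i in seq_along(terms))
      for (j in seq_along(terms))
        simmat[i, j] <- oracle_lin(fx$parents, fx$direct, fx$corpus$total,
                                   terms[i], terms[j])
    want <- oracle_single_linkage(simmat, 0.5)
    got <- lapply(sort(unique(grouping$membership)), function(k)
      sort(names(grouping$membership)[grouping$membership == k]))
    expect_equal(got, want)
  }
})

test_that("terms survive only when Z-score and Group Score both pass", {
  tb <- parse_obo(two_branch_obo())
  recs <- rep(c("GO:0000004", "GO:0000005", "GO:0000006", "GO:0000001"),
              c(2L, 1L, 3L, 2L))
  corpus <- annotation_corpus(recs, tb)
  slim <- build_goslim(data.frame(term = c("GO:0000004", "GO:0000006"),
                                  weight = c(10, 1)), tb)
  grouping <- group_by_similarity(slim, tb, corpus)
  # vacuous thresholds keep everything
  expect_setequal(filter_terms(slim, grouping, -Inf, 0),
                  c("GO:0000004", "GO:0000006"))
  # the heavy branch passes intermediate thresholds, the light one fails
  expect_equal(filter_terms(slim, grouping, 0, 0.2), "GO:0000004")
  expect_gte(slim$Z[["GO:0000004"]], 0)
  expect_lt(slim$Z[["GO:0000006"]], 0)
  # a single term judged by GrS alone (sigma = 0 so Z = 0)
  s1 <- build_goslim(data.frame(term = "GO:0000004", weight = 2), tb)
  g1 <- group_by_similarity(s1, tb, corpus)
  expect_equal(filter_terms(s1, g1, 0, 0.2), "GO:0000004")
  expect_equal(filter_terms(s1, g1, 1, 2), character(0))
})

test_that("Total Score is the exact product of its factors", {
  fx <- chain4_fixture()
  s1 <- build_goslim(data.frame(term = "GO:0000004", weight = 2),
                     fx$ontology)
  g1 <- group_by_similarity(s1, fx$ontology, fx$corpus)
  ts <- total_score(s1, g1, fx$ontology, fx$corpus, "GO:0000004")
  ic <- information_content(fx$corpus, fx$ontology, "GO:0000004")[[1]]
  # singleton group: InC_nc = GrS_nc, the ratio collapses to 1
  expect_equal(unname(ts), ic * 1 * 1 * 2)
  # the root is never informative: IC = 0 forces TS = 0
  sroot <- build_goslim(data.frame(term = "GO:0000001", weight = 5),
                        fx$ontology)
  groot <- group_by_similarity(sroot, fx$ontology, fx$corpus)
  expect_equal(unname(total_score(sroot, groot, fx$ontology, fx$corpus,
                                  "GO:0000001")), 0)
  # multi-term fixture: recompute the product by hand for every term
  wts <- data.frame(term = c("GO:0000002", "GO:0000004"), weight = c(3, 1))
  slim <- build_goslim(wts, fx$ontology)
  grouping <- group_by_similarity(slim, fx$ontology, fx$corpus,
                                  gosieve_config(sim_threshold = 0.4))
  ts2 <- total_score(slim, grouping, fx$ontology, fx$corpus, wts$term)
  inc_nc <- noncumulative_internal_confidence(slim, wts$term)
  grs_nc <- grouping$groups$grs_nc[grouping$membership[wts$term]]
  ics <- information_content(fx$corpus, fx$ontology, wts$term)
  expect_equal(unname(ts2),
               unname(ics * inc_nc * (inc_nc / grs_nc) * c(3, 1)))
})

test_that("annotate_proteins reports surviving terms, ranked and flagged", {
  fx <- chain4_fixture()
  expect_equal(nrow(annotate_proteins(NULL, fx$ontology, fx$corpus)), 0L)
  wts <- structure(data.frame(protein = "p1", term = "GO:0000004",
                              namespace = "molecular_function", weight = 50),
                   class = c("weighted_terms", "data.frame"))
  ann <- annotate_proteins(wts, fx$ontology, fx$corpus)
  expect_equal(ann$term, "GO:0000004")
  expect_true(ann$is_representative)
  expect_gt(ann$ts, 0)
  # the emitted row satisfies the score identity exactly
  expect_equal(ann$ts, ann$ic * ann$inc_nc * (ann$inc_nc / ann$grs_nc) *
                 ann$w)
})

test_that("conservation, monotonicity and scale equivariance hold on random
           fixtures", {
  for (seed in 1:25) {
    fx <- random_engine_fixture(seed)
    slim <- build_goslim(fx$wts, fx$ontology)
    # W(root) equals the input weight mass
    expect_equal(unname(slim$W[[slim$root]]), sum(fx$wts$weight))
    # W never decreases from child to parent within the slim
    for (t in slim$terms)
      for (p in intersect(fx$ontology$parents[[t]], slim$terms))
        expect_lte(slim$W[[t]], slim$W[[p]] + 1e-12)
    # rescaling weights by c > 0 leaves shares, Z and groups unchanged
    # and scales TS linearly
    c0 <- 3.7
    scaled <- transform(fx$wts, weight = weight * c0)
    slim_s <- build_goslim(scaled, fx$ontology)
    expect_equal(slim_s$Z, slim$Z)
    expect_equal(internal_confidence(slim_s), internal_confidence(slim))
    g <- group_by_similarity(slim, fx$ontology, fx$corpus)
    g_s <- group_by_similarity(slim_s, fx$ontology, fx$corpus)
    expect_equal(g_s$membership, g$membership)
    expect_equal(g_s$groups, g$groups)
    ts <- total_score(slim, g, fx$ontology, fx$corpus)
    ts_s <- total_score(slim_s, g_s, fx$ontology, fx$corpus)
    expect_equal(ts_s, c0 * ts)
  }
})

test_that("raising either filter threshold never adds a reported term", {
  for (seed in 1:10) {
    fx <- random_engine_fixture(seed)
    slim <- build_goslim(fx$wts, fx$ontology)
    grouping <- group_by_similarity(slim, fx$ontology, fx$corpus)
    base <- filter_terms(slim, grouping, -1, 0.05)
    expect_true(all(filter_terms(slim, grouping, 0, 0.05) %in% base))
    expect_true(all(filter_terms(slim, grouping, -1, 0.3) %in% base))
    expect_true(all(filter_terms(slim, grouping, 0, 0.3) %in% base))
  }
})
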