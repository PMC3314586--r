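# Core scoring engine: per-protein term subgraph ("GO-slim"), cumulative
# weights, Z-score / Group Score filtering, Lin-similarity grouping and
# Total Score ranking.

#' Build the per-protein GO-slim
#'
#' Reconstructs every path from the retrieved (input) terms up to the
#' namespace root; ontology nodes on none of these paths are discarded. Each
#' slim node `g` carries the cumulative weight `W(g)`: the sum of the input
#' weights of all retrieved terms that `g` subsumes (itself included).
#' Reconstructed ancestors contribute no mass of their own — an ancestor of a
#' single retrieved node simply inherits that node's weight — so `W(root)`
#' always equals the total input weight. Each node also gets a Z-score
#' `Z(g) = (W(g) - Wbar) / sigma` where `Wbar` is the root weight divided by
#' the number of slim nodes and `sigma` is the (population) standard
#' deviation of the slim's cumulative weights; when `sigma = 0` (e.g. a
#' single path with one input term) Z is defined as 0.
#'
#' @param wts A data.frame with columns `term` and `weight` (one protein,
#'   one namespace — [annotate_proteins()] does the splitting), or a
#'   `weighted_terms` subset.
#' @param ontology A `go_ontology`.
#' @param config A [gosieve_config()]; `sigma_source` and `wbar_denominator`
#'   control the Z-score population.
#' @return An object of class `go_slim`: `terms` (slim nodes), `input_terms`,
#'   `w` (input weight per node, 0 for reconstructed ancestors), `W`
#'   (cumulative weights), `Z`, `mean_weight`, `sigma`, `root`, `namespace`.
#'   Empty input yields an empty slim.
#' @export
build_goslim <- function(wts, ontology, config = gosieve_config()) {
  if (is.null(wts) || nrow(wts) == 0L) {
    return(structure(list(terms = character(0), input_terms = character(0),
                          w = numeric(0), W = numeric(0), Z = numeric(0),
                          mean_weight = NA_real_, sigma = NA_real_,
                          root = NA_character_, namespace = NA_character_),
                     class = "go_slim"))
  }
  terms <- resolve_term(ontology, wts$term)
  if (anyDuplicated(terms))
    stop("duplicate input terms in weighted set (aggregate first)")
  ns <- unique(ontology$namespace[terms])
  if (length(ns) != 1L)
    stop("input terms span several namespaces; split by namespace first")
  weights <- as.numeric(wts$weight)
  if (any(weights <= 0)) stop("input weights must be positive")
  names(weights) <- terms

  slim <- unique(unlist(ontology$ancestors[terms], use.names = FALSE))
  slim <- sort(slim)
  W <- numeric(length(slim))
  names(W) <- slim
  for (t in terms) {
    a <- ontology$ancestors[[t]]
    W[a] <- W[a] + weights[[t]]
  }
  w <- numeric(length(slim))
  names(w) <- slim
  w[terms] <- weights

  root <- ontology$roots[[ns]]
  denom <- switch(config$wbar_denominator,
                  slim = length(slim), input = length(terms))
  wbar <- W[[root]] / denom
  pop <- switch(config$sigma_source, slim = W, input = weights)
  sigma <- sqrt(mean((pop - mean(pop))^2))
  Z <- if (sigma > 0) (W - wbar) / sigma else setNames(rep(0, length(W)),
                                                       names(W))

  structure(list(terms = slim, input_terms = sort(terms), w = w, W = W,
                 Z = Z, mean_weight = wbar, sigma = sigma, root = root,
                 namespace = ns),
            class = "go_slim")
}

#' @export
print.go_slim <- function(x, ...) {
  cat(sprintf("go_slim (%s): %d nodes from %d input terms, W(root) = %g\n",
              x$namespace, length(x$terms), length(x$input_terms),
              if (length(x$W)) x$W[[x$root]] else 0))
  invisible(x)
}

#' Cumulative internal confidence
#'
#' `InC(g) = W(g) / W(root)`: the share of the protein's total evidence mass
#' that flows through node `g`. The root always scores 1.
#'
#' @param slim A `go_slim`.
#' @param terms Slim nodes to evaluate (default: all).
#' @return Named numeric vector in `[0, 1]`.
#' @export
internal_confidence <- function(slim, terms = slim$terms) {
  check_slim_terms(slim, terms)
  wroot <- slim$W[[slim$root]]
  if (wroot <= 0) stop("W(root) = 0; internal confidence undefined")
  slim$W[terms] / wroot
}

#' Non-cumulative internal confidence
#'
#' `InC_nc(g) = w(g) / W(root)`: only the node's own input weight, not the
#' mass accumulated from its descendants. Reconstructed ancestors that were
#' never retrieved have `w = 0` and hence `InC_nc = 0`; the non-cumulative
#' measures exist precisely so child-node scores introduce no bias.
#'
#' @inheritParams internal_confidence
#' @return Named numeric vector in `[0, 1]`.
#' @export
noncumulative_internal_confidence <- function(slim, terms = slim$terms) {
  check_slim_terms(slim, terms)
  wroot <- slim$W[[slim$root]]
  if (wroot <= 0) stop("W(root) = 0; internal confidence undefined")
  slim$w[terms] / wroot
}

check_slim_terms <- function(slim, terms) {
  missing <- setdiff(terms, slim$terms)
  if (length(missing))
    stop("term(s) not in slim: ", paste(missing, collapse = ", "))
}

#' Group retrieved terms by Lin semantic similarity
#'
#' Single-linkage threshold clustering of the slim's input terms: two terms
#' share a group iff they are connected by a chain of pairs whose Lin
#' similarity is at or above `sim_threshold`. Terms with a strong biological
#' relationship thus form one informative group. Each group carries a Group
#' Score `GrS` (sum of members' cumulative internal confidence) and its
#' non-cumulative counterpart `GrS_nc` (sum of members' `InC_nc`). Group ids
#' are assigned by the lexicographically smallest member, so the partition is
#' order-independent.
#'
#' @param slim A `go_slim`.
#' @param ontology A `go_ontology`.
#' @param corpus An `annotation_corpus` (for IC inside Lin similarity).
#' @param config A [gosieve_config()]; uses `sim_threshold`, `ic_base`,
#'   `unseen_epsilon`.
#' @return A list with `membership` (named integer vector over input terms)
#'   and `groups` (data.frame: `group`, `size`, `grs`, `grs_nc`).
#' @export
group_by_similarity <- function(slim, ontology, corpus,
                                config = gosieve_config()) {
  terms <- slim$input_terms
  n <- length(terms)
  if (n == 0L)
    return(list(membership = setNames(integer(0), character(0)),
                groups = data.frame(group = integer(0), size = integer(0),
                                    grs = numeric(0), grs_nc = numeric(0))))
  adj <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- lin_similarity(ontology, corpus, terms[i], terms[j],
                            base = config$ic_base,
                            unseen_epsilon = config$unseen_epsilon)
        adj[i, j] <- adj[j, i] <- (s >= config$sim_threshold)
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # deterministic ids: order components by their smallest member term id
  first <- tapply(terms, comp, min)
  relabel <- setNames(rank(first), names(first))
  membership <- setNames(as.integer(relabel[as.character(comp)]), terms)

  inc <- internal_confidence(slim, terms)
  inc_nc <- noncumulative_internal_confidence(slim, terms)
  ids <- sort(unique(membership))
  groups <- data.frame(
    group = ids,
    size = vapply(ids, function(k) sum(membership == k), integer(1)),
    grs = vapply(ids, function(k) sum(inc[membership == k]), numeric(1)),
    grs_nc = vapply(ids, function(k) sum(inc_nc[membership == k]),
                    numeric(1)))
  list(membership = membership, groups = groups)
}

#' Filter retrieved terms by Z-score and Group Score
#'
#' A term survives iff its Z-score and its group's Group Score both reach
#' their thresholds. This discards ontology branches whose nodes carry little
#' weight while keeping statistically supported paths to the root. An
#' all-filtered result is legal: the protein simply gets no annotation.
#'
#' @param slim A `go_slim`.
#' @param grouping Result of [group_by_similarity()].
#' @param z_threshold,grs_threshold Finite cutoffs; terms with
#'   `Z >= z_threshold` whose group has `GrS >= grs_threshold` survive.
#' @return Character vector of surviving input terms (sorted).
#' @export
filter_terms <- function(slim, grouping, z_threshold = 0,
                         grs_threshold = 0.2) {
  terms <- slim$input_terms
  if (!length(terms)) return(character(0))
  grs <- setNames(grouping$groups$grs, grouping$groups$group)
  ok_z <- slim$Z[terms] >= z_threshold
  ok_g <- grs[as.character(grouping$membership[terms])] >= grs_threshold
  sort(terms[ok_z & ok_g])
}

#' Total Score of surviving terms
#'
#' `TS(g) = IC(g) * InC_nc(g) * (InC_nc(g) / GrS_nc(group of g)) * w(g)`.
#' The score rewards hits that are both significant (large `w`) and specific
#' (large IC), scaled by how much of the protein's evidence the term itself
#' carries and by its share within its similarity group. Within a group the
#' member with the highest TS is the group's representative annotation.
#'
#' @param slim A `go_slim`.
#' @param grouping Result of [group_by_similarity()].
#' @param ontology A `go_ontology`.
#' @param corpus An `annotation_corpus`.
#' @param terms Input terms to score (typically the survivors of
#'   [filter_terms()]).
#' @param config A [gosieve_config()] (log base for IC).
#' @return Named numeric vector of non-negative scores.
#' @export
total_score <- function(slim, grouping, ontology, corpus,
                        terms = slim$input_terms,
                        config = gosieve_config()) {
  if (!length(terms)) return(setNames(numeric(0), character(0)))
  check_slim_terms(slim, terms)
  grs_nc <- setNames(grouping$groups$grs_nc, grouping$groups$group)[
    as.character(grouping$membership[terms])]
  if (any(grs_nc <= 0))
    stop("non-cumulative Group Score is 0 for a scored term")
  ic <- information_content(corpus, ontology, terms, base = config$ic_base,
                            unseen_epsilon = config$unseen_epsilon)
  inc_nc <- noncumulative_internal_confidence(slim, terms)
  ts <- ic * inc_nc * (inc_nc / grs_nc) * slim$w[terms]
  setNames(as.numeric(ts), terms)
}

#' Annotate proteins: the full scoring pipeline
#'
#' For every protein and namespace independently (molecular function,
#' biological process and cellular component never mix): build the GO-slim,
#' group the retrieved terms by Lin similarity, filter by Z-score and Group
#' Score, score the survivors and report those with Total Score at or above
#' `ts_threshold`. Only retrieved terms are reportable; reconstructed
#' ancestors shape the cumulative weights but never appear in the output.
#' Rows are ordered by protein, then TS (descending), IC (descending) and
#' term id, so output is reproducible byte for byte.
#'
#' @param wts A `weighted_terms` data.frame (`protein`, `term`, `weight`;
#'   `namespace` is recomputed from the ontology).
#' @param ontology A `go_ontology`.
#' @param corpus An `annotation_corpus`.
#' @param config A [gosieve_config()].
#' @return A data.frame with one row per reported annotation: `protein`,
#'   `term`, `namespace`, `ts`, `ic`, `inc`, `inc_nc`, `z`, `w`, `W`,
#'   `group`, `grs`, `grs_nc`, `is_representative`. With
#'   `representatives_only = TRUE` only each group's top-scoring member is
#'   kept.
#' @export
annotate_proteins <- function(wts, ontology, corpus,
                              config = gosieve_config()) {
  empty <- data.frame(protein = character(0), term = character(0),
                      namespace = character(0), ts = numeric(0),
                      ic = numeric(0), inc = numeric(0), inc_nc = numeric(0),
                      z = numeric(0), w = numeric(0), W = numeric(0),
                      group = integer(0), grs = numeric(0),
                      grs_nc = numeric(0), is_representative = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(wts) || nrow(wts) == 0L) return(empty)
  wts <- as.data.frame(wts)
  wts$term <- resolve_term(ontology, wts$term)
  wts$namespace <- unname(ontology$namespace[wts$term])

  out <- list()
  for (p in unique(wts$protein)) {
    for (ns in unique(wts$namespace[wts$protein == p])) {
      sub <- wts[wts$protein == p & wts$namespace == ns, , drop = FALSE]
      slim <- build_goslim(sub, ontology, config)
      grouping <- group_by_similarity(slim, ontology, corpus, config)
      survivors <- filter_terms(slim, grouping,
                                z_threshold = config$z_threshold,
                                grs_threshold = config$grs_threshold)
      if (!length(survivors)) next
      ts <- total_score(slim, grouping, ontology, corpus, survivors, config)
      keep <- ts >= config$ts_threshold
      survivors <- survivors[keep]
      if (!length(survivors)) next
      ts <- ts[survivors]
      ic <- information_content(corpus, ontology, survivors,
                                base = config$ic_base,
                                unseen_epsilon = config$unseen_epsilon)
      grp <- grouping$membership[survivors]
      gtab <- grouping$groups
      df <- data.frame(
        protein = p, term = survivors, namespace = ns,
        ts = as.numeric(ts), ic = as.numeric(ic),
        inc = as.numeric(internal_confidence(slim, survivors)),
        inc_nc = as.numeric(noncumulative_internal_confidence(slim,
                                                              survivors)),
        z = as.numeric(slim$Z[survivors]), w = as.numeric(slim$w[survivors]),
        W = as.numeric(slim$W[survivors]), group = as.integer(grp),
        grs = gtab$grs[match(grp, gtab$group)],
        grs_nc = gtab$grs_nc[match(grp, gtab$group)],
        stringsAsFactors = FALSE)
      # representative: the surviving member with max TS (ties: IC, term id)
      df <- df[order(-df$ts, -df$ic, df$term), , drop = FALSE]
      df$is_representative <- !duplicated(df$group)
      out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  if (isTRUE(config$representatives_only))
    res <- res[res$is_representative, , drop = FALSE]
  res <- res[order(res$protein, -res$ts, -res$ic, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write annotations to a TSV file
#'
#' Mirrors the batch-analysis output: one row per reported annotation with
#' Total Score, Information Content, Internal Confidence and friends.
#'
#' @param annotations Data.frame from [annotate_proteins()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
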