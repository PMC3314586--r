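# GO DAG handling: OBO parsing, ancestor closure, information content,
# Resnik shared IC and Lin semantic similarity.

#' Parse an OBO 1.2/1.4 flat file into a GO DAG
#'
#' Reads `[Term]` stanzas and builds a directed acyclic graph with child to
#' parent edges. `is_a` relationships are always kept; `part_of` relationships
#' are kept when `include_part_of = TRUE` (the convention used by annotation
#' propagation in GOA). All other relationship types are ignored. Obsolete
#' terms are dropped entirely, together with any edge that mentions them.
#' `alt_id` aliases are recorded and resolve to their primary identifier in
#' every query function.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @param include_part_of Keep `relationship: part_of` edges? Default `TRUE`.
#' @return An object of class `go_ontology` with elements `terms`, `parents`,
#'   `children`, `namespace`, `roots`, `alt`, `obsolete`, and precomputed
#'   `ancestors`/`descendants` closures (both reflexive).
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: GO:0000001", "name: root",
#'          "namespace: molecular_function", "",
#'          "[Term]", "id: GO:0000002", "name: leaf",
#'          "namespace: molecular_function", "is_a: GO:0000001 ! root")
#' ont <- parse_obo(obo)
#' go_ancestors(ont, "GO:0000002")
#' @export
parse_obo <- function(x, include_part_of = TRUE) {
  lines <- read_text_lines(x)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L)
    stop("no [Term] stanza found in OBO input")
  # other stanza types ([Typedef], header) delimit term stanzas too
  block_starts <- which(grepl("^\\[", lines))
  stanza_ends <- vapply(stanza_starts, function(s) {
    nxt <- block_starts[block_starts > s]
    if (length(nxt)) nxt[1] - 1L else length(lines)
  }, integer(1))

  ids <- character(0)
  nsv <- character(0)
  parent_list <- list()
  alt_map <- character(0)
  obsolete <- character(0)

  for (k in seq_along(stanza_starts)) {
    from <- stanza_starts[k] + 1L
    to <- stanza_ends[k]
    if (to < from) next
    body <- lines[from:to]
    body <- body[nzchar(body) & !grepl("^!", body)]
    m <- regexec("^([A-Za-z_]+):\\s*(.*)$", body)
    parsed <- regmatches(body, m)
    bad <- which(vapply(parsed, length, integer(1)) != 3L)
    if (length(bad)) {
      lineno <- from - 1L + match(body[bad[1]], lines[from:to])
      stop(sprintf("malformed OBO line %d: '%s'", lineno, body[bad[1]]))
    }
    keys <- vapply(parsed, `[`, character(1), 2L)
    vals <- trimws(vapply(parsed, `[`, character(1), 3L))
    # strip trailing OBO comments ("GO:0000001 ! root")
    vals <- sub("\\s*!.*$", "", vals)

    id <- vals[keys == "id"][1]
    if (is.na(id)) stop(sprintf("OBO [Term] stanza at line %d has no id",
                                stanza_starts[k]))
    if (any(keys == "is_obsolete" & tolower(vals) == "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    ns <- vals[keys == "namespace"][1]
    if (is.na(ns)) stop(sprintf("term %s has no namespace", id))

    pars <- vals[keys == "is_a"]
    if (include_part_of) {
      rel <- vals[keys == "relationship"]
      rel_part <- grep("^part_of\\s+", rel, value = TRUE)
      pars <- c(pars, sub("^part_of\\s+", "", rel_part))
    }
    alts <- vals[keys == "alt_id"]
    if (length(alts)) alt_map[alts] <- id

    ids <- c(ids, id)
    nsv <- c(nsv, ns)
    parent_list[[id]] <- unique(pars)
  }

  if (anyDuplicated(ids))
    stop("duplicate term id in OBO: ", ids[duplicated(ids)][1])
  names(nsv) <- ids

  # drop edges to obsolete or unknown parents, and cross-namespace edges
  parent_list <- lapply(ids, function(t) {
    p <- parent_list[[t]]
    p <- p[p %in% ids & !(p %in% obsolete)]
    keep <- nsv[p] == nsv[t]
    if (any(!keep))
      warning(sprintf("dropping %d cross-namespace parent(s) of %s",
                      sum(!keep), t))
    p[keep]
  })
  names(parent_list) <- ids

  roots <- character(0)
  for (ns in unique(nsv)) {
    ns_terms <- ids[nsv == ns]
    r <- ns_terms[vapply(parent_list[ns_terms], length, integer(1)) == 0L]
    if (length(r) != 1L)
      stop(sprintf("namespace %s has %d roots (expected exactly 1)",
                   ns, length(r)))
    roots[ns] <- r
  }

  children <- build_children(ids, parent_list)
  anc <- ancestor_closure(ids, parent_list)
  # acyclicity check: a term must never be its own proper ancestor
  for (t in ids) {
    # closure includes self; cycle => some parent's closure contains t
    for (p in parent_list[[t]]) {
      if (t %in% anc[[p]])
        stop(sprintf("cycle detected involving %s and %s", t, p))
    }
  }
  desc <- descendant_closure(ids, anc)

  structure(list(terms = ids, parents = parent_list, children = children,
                 namespace = nsv, roots = roots, alt = alt_map,
                 obsolete = unique(obsolete),
                 ancestors = anc, descendants = desc),
            class = "go_ontology")
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("go_ontology: %d terms, %d namespaces (%s), %d obsolete\n",
              length(x$terms), length(x$roots),
              paste(names(x$roots), collapse = ", "),
              length(x$obsolete)))
  invisible(x)
}

read_text_lines <- function(x) {
  if (!length(x)) return(character(0))
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    as.character(unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE))
  }
}

build_children <- function(ids, parent_list) {
  children <- lapply(ids, function(i) character(0))
  names(children) <- ids
  for (t in ids)
    for (p in parent_list[[t]])
      children[[p]] <- c(children[[p]], t)
  children
}

# Reflexive transitive closure child -> all ancestors, memoised recursion.
ancestor_closure <- function(ids, parent_list) {
  memo <- new.env(parent = emptyenv())
  walk <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    out <- t
    for (p in parent_list[[t]]) out <- c(out, walk(p))
    out <- unique(out)
    memo[[t]] <- out
    out
  }
  anc <- lapply(ids, walk)
  names(anc) <- ids
  anc
}

descendant_closure <- function(ids, anc) {
  desc <- lapply(ids, function(i) character(0))
  names(desc) <- ids
  for (t in ids)
    for (a in anc[[t]])
      desc[[a]] <- c(desc[[a]], t)
  desc
}

#' Resolve a term identifier to its primary id
#'
#' Maps `alt_id` aliases onto their primary term. Unknown identifiers raise an
#' error unless `strict = FALSE`, in which case `NA` is returned.
#'
#' @param ontology A `go_ontology`.
#' @param terms Character vector of GO identifiers.
#' @param strict Error on unknown ids (default) or return `NA`.
#' @return Character vector of primary identifiers.
#' @export
resolve_term <- function(ontology, terms, strict = TRUE) {
  out <- terms
  is_alt <- out %in% names(ontology$alt)
  out[is_alt] <- ontology$alt[out[is_alt]]
  unknown <- !(out %in% ontology$terms)
  if (any(unknown)) {
    if (strict)
      stop("unknown term(s): ", paste(unique(terms[unknown]), collapse = ", "))
    out[unknown] <- NA_character_
  }
  out
}

#' Ancestors of a term (reflexive)
#'
#' Returns every term reachable from `term` by following child-to-parent
#' edges, including `term` itself, so the set always contains the namespace
#' root. Reflexivity makes the shared-subsumer set of a term with itself
#' contain the term, which in turn makes Lin self-similarity equal 1.
#'
#' @param ontology A `go_ontology`.
#' @param term A single GO identifier (alt_ids are resolved).
#' @return Character vector of ancestor identifiers, `term` included.
#' @export
go_ancestors <- function(ontology, term) {
  t <- resolve_term(ontology, term)
  ontology$ancestors[[t]]
}

#' Descendants of a term (reflexive)
#' @inheritParams go_ancestors
#' @return Character vector of descendant identifiers, `term` included.
#' @export
go_descendants <- function(ontology, term) {
  t <- resolve_term(ontology, term)
  ontology$descendants[[t]]
}

#' Read a GAF 2.x annotation file
#'
#' Extracts the columns needed to build an annotation corpus: the annotated
#' object (column 2), the GO id (column 5), the evidence code (column 7) and
#' the aspect (column 9). Lines starting with `!` are comments.
#'
#' @param x Path to a GAF file or character vector of its lines.
#' @param evidence_exclude Character vector of evidence codes to drop
#'   (e.g. `"IEA"`); default `NULL` keeps every record.
#' @return A data.frame with columns `object`, `term`, `evidence`, `aspect`.
#' @export
parse_gaf <- function(x, evidence_exclude = NULL) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines))
    return(data.frame(object = character(0), term = character(0),
                      evidence = character(0), aspect = character(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 9L)
  if (length(short))
    stop(sprintf("GAF line %d has fewer than 9 columns", short[1]))
  df <- data.frame(object = vapply(fields, `[`, character(1), 2L),
                   term = vapply(fields, `[`, character(1), 5L),
                   evidence = vapply(fields, `[`, character(1), 7L),
                   aspect = vapply(fields, `[`, character(1), 9L),
                   stringsAsFactors = FALSE)
  if (!is.null(evidence_exclude))
    df <- df[!(df$evidence %in% evidence_exclude), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build an annotation corpus backing information content
#'
#' Counts how often each ontology term is cited by the annotation records and
#' cumulates those counts up the DAG: the cumulative count of a term is its
#' own count plus the counts of all its descendants, so the count never
#' decreases from child to parent. The corpus total is the number of counted
#' records, the denominator of the Resnik information content.
#'
#' @param annotations A data.frame from [parse_gaf()] (columns `object`,
#'   `term`), or a bare character vector of GO ids (one per record).
#' @param ontology A `go_ontology`.
#' @param count `"records"` counts every annotation record (default);
#'   `"pairs"` counts distinct (object, term) pairs once.
#' @return An object of class `annotation_corpus` with `direct`, `cumulative`
#'   (named integer vectors over all ontology terms) and `total`.
#' @export
annotation_corpus <- function(annotations, ontology,
                              count = c("records", "pairs")) {
  count <- match.arg(count)
  if (is.character(annotations))
    annotations <- data.frame(object = sprintf("rec%d",
                                               seq_along(annotations)),
                              term = annotations, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(annotations), all(c("term") %in% names(annotations)))
  if (count == "pairs" && "object" %in% names(annotations))
    annotations <- unique(annotations[, c("object", "term")])

  terms <- resolve_term(ontology, annotations$term, strict = FALSE)
  n_drop <- sum(is.na(terms))
  if (n_drop > 0)
    warning(sprintf("dropping %d annotation record(s) citing unknown terms",
                    n_drop))
  terms <- terms[!is.na(terms)]

  direct <- integer(length(ontology$terms))
  names(direct) <- ontology$terms
  if (length(terms)) {
    tab <- table(terms)
    direct[names(tab)] <- as.integer(tab)
  }
  cumulative <- integer(length(ontology$terms))
  names(cumulative) <- ontology$terms
  for (t in names(direct)[direct > 0L])
    cumulative[ontology$ancestors[[t]]] <-
      cumulative[ontology$ancestors[[t]]] + direct[[t]]

  structure(list(direct = direct, cumulative = cumulative,
                 total = sum(direct)),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation_corpus: %d records over %d annotated terms\n",
              x$total, sum(x$direct > 0)))
  invisible(x)
}

#' Resnik information content of ontology terms
#'
#' `IC(t) = -log(cumulative_count(t) / total)` in the chosen log base.
#' A term never seen in the corpus (cumulative count 0) is assigned the
#' maximum finite IC, `-log(1/total)` plus a small epsilon: unseen terms are
#' maximally informative but must stay numerically comparable with seen ones.
#'
#' @param corpus An `annotation_corpus`.
#' @param ontology A `go_ontology`.
#' @param terms Character vector of GO ids (default: all terms).
#' @param base Log base; natural log by default.
#' @param unseen_epsilon Added to the IC cap for unseen terms.
#' @return Named numeric vector of non-negative IC values.
#' @export
information_content <- function(corpus, ontology, terms = ontology$terms,
                                base = exp(1), unseen_epsilon = 1e-6) {
  if (corpus$total <= 0)
    stop("annotation corpus is empty (total = 0); IC undefined")
  terms <- resolve_term(ontology, terms)
  cum <- corpus$cumulative[terms]
  ic <- ifelse(cum > 0,
               -log(cum / corpus$total) / log(base),
               -log(1 / corpus$total) / log(base) + unseen_epsilon)
  names(ic) <- terms
  ic
}

#' Shared information content of the best common subsumer (Resnik)
#'
#' The maximum IC over the common ancestors of two terms of the same
#' namespace. The subsumer set is reflexive, so the shared IC of a term with
#' itself (or with any of its descendants) is its own IC.
#'
#' @inheritParams information_content
#' @param t1,t2 GO identifiers of the same namespace.
#' @return A single non-negative number.
#' @export
resnik_shared_ic <- function(ontology, corpus, t1, t2, base = exp(1),
                             unseen_epsilon = 1e-6) {
  t1 <- resolve_term(ontology, t1)
  t2 <- resolve_term(ontology, t2)
  if (ontology$namespace[[t1]] != ontology$namespace[[t2]])
    stop(sprintf("%s and %s belong to different namespaces", t1, t2))
  common <- intersect(ontology$ancestors[[t1]], ontology$ancestors[[t2]])
  max(information_content(corpus, ontology, common, base = base,
                          unseen_epsilon = unseen_epsilon))
}

#' Lin semantic similarity of two GO terms
#'
#' `sim(t1, t2) = 2 * IC(best common subsumer) / (IC(t1) + IC(t2))`, bounded
#' in `[0, 1]`. When both ICs are zero (root-like terms) the ratio is
#' undefined; identical terms then score 1 and distinct terms 0, so
#' uninformative roots never seed similarity groups.
#'
#' @inheritParams resnik_shared_ic
#' @return A number in `[0, 1]`, symmetric in its term arguments.
#' @export
lin_similarity <- function(ontology, corpus, t1, t2, base = exp(1),
                           unseen_epsilon = 1e-6) {
  t1 <- resolve_term(ontology, t1)
  t2 <- resolve_term(ontology, t2)
  if (ontology$namespace[[t1]] != ontology$namespace[[t2]])
    stop(sprintf("%s and %s belong to different namespaces", t1, t2))
  ics <- information_content(corpus, ontology, c(t1, t2), base = base,
                             unseen_epsilon = unseen_epsilon)
  denom <- sum(ics)
  if (denom == 0)
    return(if (t1 == t2) 1 else 0)
  shared <- resnik_shared_ic(ontology, corpus, t1, t2, base = base,
                             unseen_epsilon = unseen_epsilon)
  min(max(2 * shared / denom, 0), 1)
}
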