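#' Construct an ontology DAG from parent lists
#'
#' Builds the rooted directed acyclic graph of IS-A subsumption links that
#' underlies all ancestor and information-content logic. Ancestor closures
#' (every term plus all of its IS-A ancestors, including itself) are
#' precomputed at construction time.
#'
#' @param terms Character vector of unique term identifiers.
#' @param parents List, parallel to `terms`, of character vectors naming each
#'   term's direct IS-A parents. Roots have zero parents.
#' @param namespace Single string labelling the ontology aspect
#'   (e.g. `"biological_process"`).
#' @return An object of class `ontology_dag` with elements `terms`, `parents`
#'   and `children` (integer index lists), `roots` (integer indices),
#'   `closure` (integer index ancestor closures, each containing the term
#'   itself), `level` (edge distance from the nearest root) and `namespace`.
#' @examples
#' dag <- ontology_dag(c("r", "a", "b"), list(character(), "r", "r"))
#' ancestor_closure(dag, "a")
#' @export
ontology_dag <- function(terms, parents, namespace = "unknown") {
  terms <- as.character(terms)
  if (length(terms) == 0L) stop("empty ontology: no terms")
  if (anyDuplicated(terms)) stop("duplicated term identifiers")
  stopifnot(length(parents) == length(terms))
  n <- length(terms)
  pidx <- lapply(parents, function(p) {
    p <- unique(as.character(p))
    i <- match(p, terms)
    if (anyNA(i)) {
      warning("dropping reference(s) to unknown parent term(s): ",
              paste(p[is.na(i)], collapse = ", "))
      i <- i[!is.na(i)]
    }
    sort(i)
  })

  ord <- topological_order(terms, pidx)

  children <- rep(list(integer()), n)
  for (t in seq_len(n)) {
    for (p in pidx[[t]]) children[[p]] <- c(children[[p]], t)
  }
  roots <- which(lengths(pidx) == 0L)
  if (length(roots) == 0L) stop("ontology has no root term")

  closure <- vector("list", n)
  level <- integer(n)
  for (t in ord) { # parents precede children, so closures compose
    ps <- pidx[[t]]
    if (length(ps) == 0L) {
      closure[[t]] <- t
      level[t] <- 0L
    } else {
      closure[[t]] <- sort(unique(c(t, unlist(closure[ps], use.names = FALSE))))
      level[t] <- min(level[ps]) + 1L
    }
  }

  structure(
    list(terms = terms, parents = pidx, children = children, roots = roots,
         closure = closure, level = level, namespace = namespace),
    class = "ontology_dag"
  )
}

# Kahn's algorithm over the parent lists; errors naming one cycle edge.
topological_order <- function(terms, pidx) {
  n <- length(terms)
  outdeg <- lengths(pidx) # number of unvisited parents
  kids <- rep(list(integer()), n)
  for (t in seq_len(n)) for (p in pidx[[t]]) kids[[p]] <- c(kids[[p]], t)
  queue <- which(outdeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, t)
    for (k in kids[[t]]) {
      outdeg[k] <- outdeg[k] - 1L
      if (outdeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    stuck <- which(outdeg > 0L)[1L]
    bad_parent <- pidx[[stuck]][1L]
    stop(sprintf("cycle detected in IS-A graph involving edge %s -> %s",
                 terms[stuck], terms[bad_parent]))
  }
  ord
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d IS-A edges, %d root(s), namespace '%s'\n",
              length(x$terms), sum(lengths(x$parents)), length(x$roots),
              x$namespace))
  invisible(x)
}

n_terms <- function(dag) length(dag$terms)

term_index <- function(dag, terms) {
  i <- match(terms, dag$terms)
  if (anyNA(i)) {
    stop("unknown term(s): ", paste(terms[is.na(i)], collapse = ", "))
  }
  i
}

#' Ancestor closure of a term set
#'
#' Returns the given terms together with all of their IS-A ancestors. The
#' operation is idempotent and monotone: `closure(closure(S)) == closure(S)`
#' and `S`\eqn{\subseteq}`T` implies `closure(S)`\eqn{\subseteq}`closure(T)`.
#'
#' @param dag An [ontology_dag()].
#' @param terms Character vector of term identifiers present in `dag`.
#' @return Sorted character vector of term identifiers.
#' @export
ancestor_closure <- function(dag, terms) {
  idx <- term_index(dag, terms)
  dag$terms[sort(unique(unlist(dag$closure[idx], use.names = FALSE)))]
}

#' Parse an OBO 1.2 ontology, keeping only IS-A links
#'
#' Reads `[Term]` stanzas; obsolete terms are excluded, and only `is_a:`
#' lines contribute edges. Other relationship types (e.g. `part_of`,
#' `regulates` on `relationship:` lines) are ignored, so the resulting graph
#' encodes pure subsumption.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines.
#' @param namespace Optional aspect filter: keep only terms whose
#'   `namespace:` matches (e.g. `"biological_process"`). Default keeps all.
#' @return An [ontology_dag()].
#' @export
parse_obo <- function(file, namespace = NULL) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("empty ontology: no [Term] stanzas found")
  bounds <- c(starts[-1L] - 1L, length(lines))

  ids <- character(0); pars <- list(); spaces <- character(0)
  for (s in seq_along(starts)) {
    chunk <- lines[starts[s]:bounds[s]]
    stanza_end <- which(grepl("^\\[", chunk))[-1L]
    if (length(stanza_end)) chunk <- chunk[seq_len(stanza_end[1L] - 1L)]
    if (any(grepl("^is_obsolete: *true", chunk))) next
    id <- sub("^id: *", "", grep("^id:", chunk, value = TRUE))
    if (length(id) != 1L) next
    isa <- sub("^is_a: *", "", grep("^is_a:", chunk, value = TRUE))
    isa <- trimws(sub("!.*$", "", isa)) # strip trailing '! name' comments
    isa <- isa[nzchar(isa)]
    ns <- sub("^namespace: *", "", grep("^namespace:", chunk, value = TRUE))
    ids <- c(ids, id)
    pars <- c(pars, list(isa))
    spaces <- c(spaces, if (length(ns)) ns[1L] else NA_character_)
  }
  if (!is.null(namespace)) {
    keep <- !is.na(spaces) & spaces == namespace
    ids <- ids[keep]; pars <- pars[keep]
  }
  if (length(ids) == 0L) stop("empty ontology: no usable terms after filtering")
  ns_label <- if (!is.null(namespace)) {
    namespace
  } else if (length(unique(stats::na.omit(spaces))) == 1L) {
    unique(stats::na.omit(spaces))
  } else "mixed"
  ontology_dag(ids, pars, ns_label)
}

#' Parse a GAF 2.x annotation file into a gene -> term-set corpus
#'
#' Rows with a `NOT` qualifier are dropped, duplicates collapsed, and the
#' aspect column (P/F/C) filtered. Annotations to terms absent from the DAG
#' are dropped with a warning, as are malformed rows (fewer than 15 columns).
#'
#' @param file Path to a GAF file, or a character vector of GAF lines.
#' @param dag The [ontology_dag()] the annotations must refer to.
#' @param aspect One of `"P"`, `"F"`, `"C"` (GAF column 9).
#' @param evidence_exclude Optional character vector of evidence codes
#'   (GAF column 7) to drop, e.g. `"IEA"`. Default keeps all evidence.
#' @param key `"id"` to key genes by DB object ID (column 2, the default) or
#'   `"symbol"` for the DB object symbol (column 3).
#' @return An object of class `annotation_corpus`: a list with `annotations`
#'   (named list of character term-id vectors, one per gene) and `aspect`.
#' @export
parse_gaf <- function(file, dag, aspect = c("P", "F", "C"),
                      evidence_exclude = NULL, key = c("id", "symbol")) {
  aspect <- match.arg(aspect)
  key <- match.arg(key)
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  data_rows <- which(!startsWith(lines, "!") & nzchar(lines))
  fields <- strsplit(lines[data_rows], "\t", fixed = TRUE)
  ok <- lengths(fields) >= 15L
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " malformed GAF row(s) at line(s): ",
            paste(utils::head(data_rows[!ok], 10L), collapse = ", "))
    fields <- fields[ok]
  }
  if (length(fields) == 0L) stop("no annotation rows retained from GAF input")
  col <- function(j) vapply(fields, `[[`, "", j)
  qualifier <- col(4L)
  keep <- !grepl("(^|\\|)NOT(\\||$)", qualifier) & col(9L) == aspect
  if (!is.null(evidence_exclude)) keep <- keep & !(col(7L) %in% evidence_exclude)
  gene <- if (key == "id") col(2L) else col(3L)
  term <- col(5L)
  gene <- gene[keep]; term <- term[keep]

  known <- term %in% dag$terms
  if (any(!known)) {
    warning("dropping ", sum(!known), " annotation(s) to term(s) absent from the DAG: ",
            paste(unique(term[!known]), collapse = ", "))
    gene <- gene[known]; term <- term[known]
  }
  if (length(gene) == 0L) stop("no annotation rows retained from GAF input")
  ann <- lapply(split(term, gene), function(ts) sort(unique(ts)))
  annotation_corpus(ann, aspect)
}

#' Construct an annotation corpus
#'
#' @param annotations Named list: gene identifier -> character vector of
#'   directly annotated term identifiers (deduplicated, each non-empty).
#' @param aspect Aspect label, one of `"P"`, `"F"`, `"C"`.
#' @return An object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(annotations, aspect = "P") {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))
  if (any(lengths(annotations) == 0L)) stop("gene(s) with empty annotation set")
  structure(list(annotations = annotations, aspect = aspect),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  L <- lengths(x$annotations)
  cat(sprintf("annotation_corpus: %d genes, aspect %s, annotation length %d-%d (mean %.2f)\n",
              length(L), x$aspect, min(L), max(L), mean(L)))
  invisible(x)
}

#' Annotation lengths of a corpus
#'
#' The annotation length of a gene is its number of directly annotated terms
#' — the covariate whose effect on similarity scores this package audits and
#' removes.
#'
#' @param corpus An [annotation_corpus()].
#' @return Named integer vector of per-gene annotation lengths.
#' @export
annotation_length <- function(corpus) {
  lengths(corpus$annotations)
}

#' Information content of every term
#'
#' A gene counts toward term `c` when the ancestor closure of its direct
#' annotations contains `c`, so term counts are cumulative up the DAG:
#' `p(parent) >= p(child)`. `IC(c) = -log p(c)` with the natural logarithm
#' (the base cancels in the Lin/Relevance/GIC/VSM ratios and only rescales
#' Resnik). Terms covering zero genes get `NA` information content and are
#' excluded from null-model sampling pools.
#'
#' @param dag An [ontology_dag()].
#' @param corpus An [annotation_corpus()] whose terms all exist in `dag`.
#' @return An object of class `ic_table`: list with `ic` and `p` (named
#'   numeric vectors over all DAG terms, `NA` where undefined) and
#'   `total_genes`.
#' @export
compute_ic <- function(dag, corpus) {
  if (length(corpus$annotations) == 0L) stop("empty corpus")
  counts <- integer(n_terms(dag))
  for (ts in corpus$annotations) {
    idx <- term_index(dag, ts)
    covered <- unique(unlist(dag$closure[idx], use.names = FALSE))
    counts[covered] <- counts[covered] + 1L
  }
  total <- length(corpus$annotations)
  p <- counts / total
  p[counts == 0L] <- NA_real_
  ic <- -log(p)
  names(p) <- names(ic) <- dag$terms
  structure(list(ic = ic, p = p, total_genes = total), class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  def <- sum(!is.na(x$ic))
  cat(sprintf("ic_table: %d/%d terms with defined IC over %d genes; IC range [%.3f, %.3f]\n",
              def, length(x$ic), x$total_genes,
              min(x$ic, na.rm = TRUE), max(x$ic, na.rm = TRUE)))
  invisible(x)
}

#' Write / read a DAG as a TSV edge list
#'
#' `write_dag_edges()` writes one `child<TAB>parent` row per IS-A edge plus
#' `term<TAB>.` rows for isolated roots; `read_dag_edges()` reconstructs an
#' isomorphic [ontology_dag()].
#'
#' @param dag An [ontology_dag()].
#' @param file Path to write to / read from.
#' @param namespace Namespace label for the reconstructed DAG.
#' @return `read_dag_edges()` returns an [ontology_dag()];
#'   `write_dag_edges()` returns `file` invisibly.
#' @export
write_dag_edges <- function(dag, file) {
  child <- character(0); parent <- character(0)
  for (t in seq_along(dag$terms)) {
    ps <- dag$parents[[t]]
    if (length(ps) == 0L) {
      child <- c(child, dag$terms[t]); parent <- c(parent, ".")
    } else {
      child <- c(child, rep(dag$terms[t], length(ps)))
      parent <- c(parent, dag$terms[ps])
    }
  }
  utils::write.table(data.frame(child = child, parent = parent),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dag_edges
#' @export
read_dag_edges <- function(file, namespace = "unknown") {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          colClasses = "character")
  terms <- unique(c(df$child, df$parent[df$parent != "."]))
  parents <- lapply(terms, function(t) {
    p <- df$parent[df$child == t]
    p[p != "."]
  })
  ontology_dag(terms, parents, namespace)
}
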