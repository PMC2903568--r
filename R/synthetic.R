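#' Specification for synthetic ontologies and corpora
#'
#' Captures the conditions the randomized audits run under: a single-root
#' layered DAG with occasional multiple parentage, genes with geometric
#' annotation-length distributions, an optional "well-studied" subpopulation
#' with longer annotations (the annotation-bias phenomenon the package
#' audits), and optional planted functional categories tied to disjoint
#' subgraphs.
#'
#' @param n_terms Total number of terms including the root (default 500).
#' @param depth Number of levels below the root (default 6).
#' @param multi_parent_p Probability that a non-root term receives one extra
#'   parent from a shallower level (default 0.2).
#' @param n_genes Number of genes (default 2000).
#' @param mean_length Mean annotation length; lengths are
#'   `1 + Geometric(1/mean_length)` (default 3).
#' @param max_length Cap on annotation lengths (default 10, matching the
#'   observation that almost all real proteins have at most 10 annotations).
#' @param biased_fraction Fraction of genes in the long-annotation
#'   subpopulation (default 0.15).
#' @param length_multiplier Annotation-length multiplier for the biased
#'   subpopulation, and the between-category multiplier when category
#'   lengths are confounded (default 3).
#' @param depth_decay Per-level factor by which a term's chance of being
#'   drawn as a direct annotation shrinks (default 0.45); deeper terms are
#'   rarer annotations, giving the information content the strongly
#'   right-skewed spread seen in real annotation corpora.
#' @param n_categories Number of planted categories (default 2; used only by
#'   [generate_labeled_categories()]).
#' @param category_purity Fraction of a category gene's annotations drawn
#'   from its own subgraph (default 0.8); the rest are background noise.
#' @param confound_lengths If `TRUE`, tie annotation length to category
#'   (successive categories get `length_multiplier` times longer
#'   annotations), reproducing the failure mode of raw scores.
#' @param seed Integer seed; all generation is deterministic given the spec.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_terms = 500, depth = 6, multi_parent_p = 0.2,
                           n_genes = 2000, mean_length = 3, max_length = 10,
                           biased_fraction = 0.15, length_multiplier = 3,
                           depth_decay = 0.45, n_categories = 2,
                           category_purity = 0.8, confound_lengths = FALSE,
                           seed = 1) {
  stopifnot(n_terms >= 1, depth >= 1, n_genes >= 1, mean_length >= 1,
            multi_parent_p >= 0, multi_parent_p <= 1,
            biased_fraction >= 0, biased_fraction <= 1,
            length_multiplier >= 1, depth_decay > 0,
            category_purity >= 0, category_purity <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic single-root layered DAG
#'
#' Terms are placed on levels `0..depth` with geometrically growing level
#' sizes; each non-root term takes one uniform parent from the previous
#' level, plus, with probability `multi_parent_p`, one extra parent from
#' any strictly shallower level. The construction is acyclic by layering
#' and single-rooted by design (so term-overlap scores are always at least
#' 1).
#'
#' @param spec A [synthetic_spec()].
#' @return An [ontology_dag()] with terms `T0001`, `T0002`, ...
#' @export
generate_dag <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_terms
    ids <- sprintf("T%04d", seq_len(n))
    if (n == 1L) {
      ontology_dag(ids, list(character()), "synthetic")
    } else {
      build_layered_dag(spec, n, ids)
    }
  })
}

build_layered_dag <- function(spec, n, ids) {
  depth <- min(spec$depth, n - 1L)
    # geometric level sizes, scaled to sum to n - 1 non-root terms
    raw <- 2^seq_len(depth)
    sizes <- pmax(1L, round(raw / sum(raw) * (n - 1L)))
    while (sum(sizes) != n - 1L) { # adjust rounding drift on deepest levels
      i <- which.max(sizes)
      sizes[i] <- sizes[i] + sign(n - 1L - sum(sizes))
    }
    level <- rep.int(seq_len(depth), sizes)
    parents <- vector("list", n)
    parents[[1L]] <- character()
    for (t in 2:n) {
      lv <- level[t - 1L]
      prev <- if (lv == 1L) 1L else which(level == lv - 1L) + 1L
      p <- if (length(prev) == 1L) prev else sample(prev, 1L)
      if (lv > 1L && stats::runif(1) < spec$multi_parent_p) {
        shallower <- c(1L, which(level < lv - 1L) + 1L)
        extra <- if (length(shallower) == 1L) shallower else sample(shallower, 1L)
        p <- unique(c(p, extra))
      }
      parents[[t]] <- ids[p]
    }
    ontology_dag(ids, parents, "synthetic")
}

# Per-term sampling weights: deeper terms are rarer direct annotations.
annotation_weights <- function(dag, depth_decay) {
  depth_decay^dag$level
}

sample_lengths <- function(n, mean_length, max_length) {
  L <- 1L + stats::rgeom(n, prob = 1 / mean_length)
  pmin(L, max_length)
}

#' Generate a synthetic annotation corpus
#'
#' Every gene draws an annotation length from a geometric distribution
#' (multiplied for the biased, "well-studied" subpopulation) and then draws
#' that many distinct terms with depth-decaying weights, so specific terms
#' are annotated rarely and the information content has realistic spread.
#'
#' @param spec A [synthetic_spec()].
#' @param dag A DAG from [generate_dag()] (or any [ontology_dag()] with
#'   levels).
#' @return An [annotation_corpus()] with genes `G0001`, `G0002`, ...; the
#'   biased genes are recorded in attribute `"biased"`.
#' @export
generate_corpus <- function(spec, dag) {
  with_seed(if (is.null(spec$seed)) NULL else spec$seed + 1L, {
    n <- spec$n_genes
    genes <- sprintf("G%04d", seq_len(n))
    biased <- stats::runif(n) < spec$biased_fraction
    L <- sample_lengths(n, spec$mean_length, spec$max_length)
    L[biased] <- pmin(round(L[biased] * spec$length_multiplier),
                      spec$max_length * spec$length_multiplier)
    w <- annotation_weights(dag, spec$depth_decay)
    nt <- n_terms(dag)
    ann <- lapply(seq_len(n), function(g) {
      k <- min(L[g], nt)
      dag$terms[sample.int(nt, k, prob = w)]
    })
    names(ann) <- genes
    corpus <- annotation_corpus(ann, "P")
    attr(corpus, "biased") <- genes[biased]
    corpus
  })
}

#' Generate a corpus with planted functional categories
#'
#' Assigns each category a disjoint subgraph (the descendants of a distinct
#' level-1 anchor term); category genes draw a `category_purity` share of
#' their annotations from their subgraph and the rest from the whole
#' ontology. With `confound_lengths = TRUE`, successive categories get
#' `length_multiplier`-fold longer annotations, deliberately entangling
#' annotation length with category membership — the regime in which raw
#' similarity scores cluster genes by annotation length rather than by
#' function.
#'
#' @param spec A [synthetic_spec()] with `n_categories >= 2`.
#' @param dag A DAG from [generate_dag()].
#' @return List with `corpus` (an [annotation_corpus()]) and `categories`
#'   (named character vector gene -> category label `C1`, `C2`, ...).
#' @export
generate_labeled_categories <- function(spec, dag) {
  stopifnot(spec$n_categories >= 2L)
  with_seed(if (is.null(spec$seed)) NULL else spec$seed + 2L, {
    level1 <- which(dag$level == 1L)
    if (length(level1) < spec$n_categories) {
      stop("not enough level-1 terms to anchor ", spec$n_categories,
           " disjoint category subgraphs")
    }
    anchors <- sample(level1, spec$n_categories)
    nt <- n_terms(dag)
    in_closure_of <- function(a) {
      which(vapply(dag$closure, function(cl) a %in% cl, TRUE))
    }
    subgraphs <- lapply(anchors, in_closure_of)
    # enforce disjointness: terms under several anchors go to the first
    seen <- integer(0)
    subgraphs <- lapply(subgraphs, function(s) {
      s <- setdiff(s, seen)
      seen <<- c(seen, s)
      s
    })
    if (any(lengths(subgraphs) < 3L)) {
      stop("category subgraph with fewer than 3 terms; use a larger DAG")
    }
    w <- annotation_weights(dag, spec$depth_decay)
    n <- spec$n_genes
    genes <- sprintf("G%04d", seq_len(n))
    category <- rep_len(seq_len(spec$n_categories), n)
    mean_len <- if (spec$confound_lengths) {
      spec$mean_length * spec$length_multiplier^(category - 1L)
    } else {
      rep(spec$mean_length, n)
    }
    ann <- lapply(seq_len(n), function(g) {
      L <- min(1L + stats::rgeom(1L, prob = 1 / mean_len[g]),
               spec$max_length * spec$length_multiplier)
      sub <- subgraphs[[category[g]]]
      k_in <- min(max(1L, round(spec$category_purity * L)), length(sub))
      k_out <- min(L - k_in, nt - length(sub))
      own <- sub[sample.int(length(sub), k_in,
                            prob = w[sub])]
      noise <- if (k_out > 0L) {
        outside <- setdiff(seq_len(nt), sub)
        outside[sample.int(length(outside), k_out, prob = w[outside])]
      } else integer(0)
      dag$terms[c(own, noise)]
    })
    names(ann) <- genes
    categories <- stats::setNames(paste0("C", category), genes)
    list(corpus = annotation_corpus(ann, "P"), categories = categories)
  })
}

#' Write a DAG as a minimal OBO 1.2 file
#'
#' @param dag An [ontology_dag()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_obo <- function(dag, file) {
  out <- c("format-version: 1.2", "")
  for (t in seq_along(dag$terms)) {
    ps <- dag$parents[[t]]
    out <- c(out, "[Term]",
             paste0("id: ", dag$terms[t]),
             paste0("name: term ", dag$terms[t]),
             paste0("namespace: ", dag$namespace),
             if (length(ps)) paste0("is_a: ", dag$terms[ps]),
             "")
  }
  writeLines(out, file)
  invisible(file)
}

#' Write an annotation corpus as a minimal GAF 2.2 file
#'
#' @param corpus An [annotation_corpus()].
#' @param file Output path.
#' @param db Database label for column 1.
#' @return `file`, invisibly.
#' @export
write_gaf <- function(corpus, file, db = "SYNTH") {
  genes <- names(corpus$annotations)
  rows <- unlist(lapply(genes, function(g) {
    vapply(corpus$annotations[[g]], function(term) {
      paste(db, g, g, "", term, "SYNTH:0", "IEA", "", corpus$aspect,
            paste("synthetic gene", g), "", "protein", "taxon:0000",
            "20260101", db, sep = "\t")
    }, "")
  }), use.names = FALSE)
  writeLines(c("!gaf-version: 2.2", rows), file)
  invisible(file)
}
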