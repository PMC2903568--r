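#' The 14 protein-pair similarity measures
#'
#' Eight combined measures (four term measures under AVG and BMA combination)
#' and six groupwise measures.
#' @export
group_measures <- c("resnik_avg", "resnik_bma", "lin_avg", "lin_bma",
                    "rs_avg", "rs_bma", "jiang_avg", "jiang_bma",
                    "to", "nto", "dice", "kappa", "gic", "vsm")

#' Term group of a protein
#'
#' A protein's direct annotations together with their ancestor closure. The
#' group size (`length`) is the protein's annotation length; the closure is
#' the term set used by the groupwise overlap measures.
#'
#' @param dag An [ontology_dag()].
#' @param terms Character vector of directly annotated term identifiers.
#' @return List of class `term_group` with `direct`, `closed` and `length`.
#' @export
term_group <- function(dag, terms) {
  terms <- sort(unique(as.character(terms)))
  if (length(terms) == 0L) stop("empty term group")
  structure(list(direct = terms, closed = ancestor_closure(dag, terms),
                 length = length(terms)),
            class = "term_group")
}

as_term_group <- function(dag, g) {
  if (inherits(g, "term_group")) g else term_group(dag, g)
}

#' Precomputed similarity engine
#'
#' Caches the structures every measure needs — ancestor closures as a sparse
#' incidence matrix, the IC vector, and the full term-by-term MICA table —
#' so that scoring many protein or term-group pairs is a matter of indexed
#' lookups. Intended for ontologies up to a few thousand terms (the MICA
#' table is dense, `n_terms^2`).
#'
#' @param dag An [ontology_dag()].
#' @param ic An [compute_ic()] table for `dag`.
#' @return Object of class `similarity_engine`.
#' @export
similarity_engine <- function(dag, ic) {
  n <- n_terms(dag)
  icv <- unname(ic$ic)
  pv <- unname(ic$p)
  # closure incidence: C[t, a] = 1 iff a is an ancestor-or-self of t
  cl <- dag$closure
  Cmat <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lengths(cl)),
    j = unlist(cl, use.names = FALSE),
    x = 1, dims = c(n, n)
  )
  # descendant sets (inverse closure), needed for the MICA fill
  desc <- lapply(seq_len(n), function(a) integer(0))
  inv_i <- unlist(cl, use.names = FALSE)
  inv_t <- rep.int(seq_len(n), lengths(cl))
  desc <- split(inv_t, factor(inv_i, levels = seq_len(n)))

  # Fill the MICA index matrix ancestor-by-ancestor in decreasing IC order
  # (ties by lexicographically smallest term id); the first writer wins, so
  # every pair records its maximal-IC common ancestor.
  defined <- which(!is.na(icv))
  ord <- defined[order(-icv[defined], dag$terms[defined])]
  micaIdx <- matrix(NA_integer_, n, n)
  for (a in ord) {
    d <- desc[[a]]
    if (length(d) < 1L) next
    sub <- micaIdx[d, d, drop = FALSE]
    nas <- is.na(sub)
    if (any(nas)) {
      sub[nas] <- a
      micaIdx[d, d] <- sub
    }
  }
  micaIC <- matrix(0, n, n)
  filled <- !is.na(micaIdx)
  micaIC[filled] <- icv[micaIdx[filled]]
  micaP <- matrix(0, n, n)
  micaP[filled] <- pv[micaIdx[filled]]

  structure(list(dag = dag, ic = ic, icv = icv, pv = pv,
                 ic0 = ifelse(is.na(icv), 0, icv),
                 Cmat = Cmat, micaIdx = micaIdx, micaIC = micaIC,
                 micaP = micaP, pool = which(!is.na(icv))),
            class = "similarity_engine")
}

#' @export
print.similarity_engine <- function(x, ...) {
  cat(sprintf("similarity_engine: %d terms (%d with defined IC)\n",
              n_terms(x$dag), length(x$pool)))
  invisible(x)
}

# ---- pairwise-combination measures ------------------------------------------

pair_score_matrix <- function(measure, dag, ic, direct1, direct2) {
  vapply(direct2, function(tn) {
    vapply(direct1, function(tm) term_pair_score(measure, dag, ic, tm, tn)$value,
           0)
  }, numeric(length(direct1)))
}

avg_matrix <- function(S) mean(S)

bma_matrix <- function(S, alternative = FALSE) {
  S <- matrix(S, nrow = NROW(S))
  rmax <- apply(S, 1L, max)
  cmax <- apply(S, 2L, max)
  if (alternative) {
    (sum(rmax) + sum(cmax)) / (length(rmax) + length(cmax))
  } else {
    (mean(rmax) + mean(cmax)) / 2
  }
}

#' Average combination of term-pair scores
#'
#' The arithmetic mean of the term-pair similarity over all pairs formed
#' from the two proteins' direct annotations.
#'
#' @param measure One of `"resnik"`, `"lin"`, `"rs"`, `"jiang"`.
#' @param dag,ic Ontology and IC table.
#' @param group1,group2 [term_group()] objects (or character term vectors).
#' @return Numeric score.
#' @export
combine_avg <- function(measure, dag, ic, group1, group2) {
  g1 <- as_term_group(dag, group1); g2 <- as_term_group(dag, group2)
  avg_matrix(pair_score_matrix(measure, dag, ic, g1$direct, g2$direct))
}

#' Best-match-average combination of term-pair scores
#'
#' For each term of one protein, take its best match among the other
#' protein's terms; the score is the symmetric average of the two
#' directional best-match means. `alternative = TRUE` uses the pooled form
#' `(sum of row maxima + sum of column maxima) / (L1 + L2)` instead.
#'
#' @inheritParams combine_avg
#' @param alternative Use the pooled best-match convention.
#' @return Numeric score.
#' @export
combine_bma <- function(measure, dag, ic, group1, group2, alternative = FALSE) {
  g1 <- as_term_group(dag, group1); g2 <- as_term_group(dag, group2)
  S <- pair_score_matrix(measure, dag, ic, g1$direct, g2$direct)
  bma_matrix(matrix(S, nrow = g1$length), alternative)
}

# ---- groupwise measures -----------------------------------------------------

#' Term overlap (TO) of two proteins
#'
#' The number of terms shared by the two ancestor-closed annotation sets.
#' Under a single-root ontology every pair shares at least the root, so
#' `TO >= 1`.
#'
#' @param dag An [ontology_dag()].
#' @param group1,group2 [term_group()] objects (or character term vectors).
#' @return Integer count.
#' @export
to_score <- function(dag, group1, group2) {
  g1 <- as_term_group(dag, group1); g2 <- as_term_group(dag, group2)
  length(intersect(g1$closed, g2$closed))
}

#' Normalized term overlap and Dice scores
#'
#' `nto` divides the term overlap by the smaller set size, `dice` by the
#' average set size. By default the denominators use the ancestor-closed set
#' sizes (consistent with the closed-set numerator, which keeps both scores
#' in `(0, 1]` on a single-root ontology); `denominator = "direct"` uses the
#' raw annotation lengths instead.
#'
#' @param variant `"nto"` or `"dice"`.
#' @param dag An [ontology_dag()].
#' @param group1,group2 [term_group()] objects (or character term vectors).
#' @param denominator `"closed"` (default) or `"direct"`.
#' @return Numeric score.
#' @export
overlap_score <- function(variant = c("nto", "dice"), dag, group1, group2,
                          denominator = c("closed", "direct")) {
  variant <- match.arg(variant)
  denominator <- match.arg(denominator)
  g1 <- as_term_group(dag, group1); g2 <- as_term_group(dag, group2)
  to <- length(intersect(g1$closed, g2$closed))
  s1 <- if (denominator == "closed") length(g1$closed) else g1$length
  s2 <- if (denominator == "closed") length(g2$closed) else g2$length
  switch(variant,
         nto = to / min(s1, s2),
         dice = 2 * to / (s1 + s2))
}

#' Cohen's kappa between two annotation vectors
#'
#' Both closed annotation sets are encoded as binary indicator vectors over
#' the whole term universe of the loaded aspect; kappa is the chance-
#' corrected agreement `(O - E) / (1 - E)` of the two vectors. Negative
#' values (below-chance agreement) are clamped to 0; the degenerate case of
#' two all-ones vectors is defined as 1.
#'
#' @param dag An [ontology_dag()] (its full term set is the universe).
#' @param group1,group2 [term_group()] objects (or character term vectors).
#' @return Numeric score in `[0, 1]`.
#' @export
kappa_score <- function(dag, group1, group2) {
  g1 <- as_term_group(dag, group1); g2 <- as_term_group(dag, group2)
  N <- n_terms(dag)
  a1 <- length(g1$closed); a2 <- length(g2$closed)
  both <- length(intersect(g1$closed, g2$closed))
  O <- (both + N - a1 - a2 + both) / N
  p1 <- a1 / N; p2 <- a2 / N
  E <- p1 * p2 + (1 - p1) * (1 - p2)
  if (E == 1) return(1) # identical degenerate marginals (incl. all-ones)
  max(0, (O - E) / (1 - E))
}

#' IC-weighted set measures: GIC and VSM
#'
#' `gic` is the information-content-weighted Jaccard index of the two closed
#' sets; `vsm` is the cosine similarity of IC-weighted indicator vectors over
#' the term universe (so the dot product accumulates `IC(k)^2` over shared
#' terms). Both are 0 when every shared term has zero IC.
#'
#' @param variant `"gic"` or `"vsm"`.
#' @param dag An [ontology_dag()].
#' @param ic An [compute_ic()] table.
#' @param group1,group2 [term_group()] objects (or character term vectors).
#' @return Numeric score in `[0, 1]`.
#' @export
weighted_set_score <- function(variant = c("gic", "vsm"), dag, ic,
                               group1, group2) {
  variant <- match.arg(variant)
  g1 <- as_term_group(dag, group1); g2 <- as_term_group(dag, group2)
  w <- ic$ic
  w[is.na(w)] <- 0
  inter <- intersect(g1$closed, g2$closed)
  if (variant == "gic") {
    den <- sum(w[union(g1$closed, g2$closed)])
    if (den == 0) return(0)
    sum(w[inter]) / den
  } else {
    den <- sqrt(sum(w[g1$closed]^2) * sum(w[g2$closed]^2))
    if (den == 0) return(0)
    sum(w[inter]^2) / den
  }
}

# ---- dispatcher -------------------------------------------------------------

split_measure <- function(measure) {
  parts <- strsplit(measure, "_", fixed = TRUE)[[1L]]
  list(term = parts[1L], combiner = if (length(parts) > 1L) parts[2L] else NA)
}

#' Protein-pair similarity under any of the 14 measures
#'
#' Builds the two proteins' term groups from their direct annotations and
#' dispatches to the requested measure. All measures are symmetric in the
#' two genes.
#'
#' @param measure One of [group_measures].
#' @param dag An [ontology_dag()].
#' @param ic An [compute_ic()] table.
#' @param corpus An [annotation_corpus()].
#' @param gene1,gene2 Gene identifiers present in `corpus`.
#' @return List of class `group_score` with `measure`, `value` and `lengths`
#'   (the two annotation lengths, sorted).
#' @export
protein_similarity <- function(measure = group_measures, dag, ic, corpus,
                               gene1, gene2) {
  measure <- match.arg(measure)
  for (g in c(gene1, gene2)) {
    if (!g %in% names(corpus$annotations)) stop("unknown gene: ", g)
  }
  g1 <- term_group(dag, corpus$annotations[[gene1]])
  g2 <- term_group(dag, corpus$annotations[[gene2]])
  value <- group_pair_score(measure, dag, ic, g1, g2)
  structure(list(measure = measure, value = value,
                 lengths = sort(c(g1$length, g2$length))),
            class = "group_score")
}

#' @export
print.group_score <- function(x, ...) {
  cat(sprintf("%s = %.6g (annotation lengths %d, %d)\n",
              x$measure, x$value, x$lengths[1L], x$lengths[2L]))
  invisible(x)
}

# Single-pair reference path shared by protein_similarity and tests.
group_pair_score <- function(measure, dag, ic, g1, g2) {
  m <- split_measure(measure)
  if (!is.na(m$combiner)) {
    if (m$combiner == "avg") combine_avg(m$term, dag, ic, g1, g2)
    else combine_bma(m$term, dag, ic, g1, g2)
  } else {
    switch(measure,
           to = to_score(dag, g1, g2),
           nto = overlap_score("nto", dag, g1, g2),
           dice = overlap_score("dice", dag, g1, g2),
           kappa = kappa_score(dag, g1, g2),
           gic = weighted_set_score("gic", dag, ic, g1, g2),
           vsm = weighted_set_score("vsm", dag, ic, g1, g2))
  }
}

# ---- vectorized batch scorer ------------------------------------------------

#' Score many group pairs at once
#'
#' The workhorse behind the null model and protein-matrix computation: scores
#' every row of two group matrices under any subset of the 14 measures using
#' the engine's precomputed MICA table and sparse closure incidence. All
#' pairs in one call share the two group sizes; [score_pairs()] buckets
#' variable-length input by length combination.
#'
#' @param engine A [similarity_engine()].
#' @param G1,G2 Integer matrices (`n_pairs` x `L1`, `n_pairs` x `L2`) of term
#'   indices into `engine$dag$terms`.
#' @param measures Character vector, subset of [group_measures].
#' @return Numeric matrix `n_pairs` x `length(measures)`.
#' @keywords internal
score_pairs_fixed <- function(engine, G1, G2, measures = group_measures) {
  G1 <- matrix(as.integer(G1), nrow = NROW(G1))
  G2 <- matrix(as.integer(G2), nrow = NROW(G2))
  m <- nrow(G1)
  stopifnot(nrow(G2) == m)
  L1 <- ncol(G1); L2 <- ncol(G2)
  out <- matrix(NA_real_, m, length(measures),
                dimnames = list(NULL, measures))

  pairwise <- measures[measures %in% paste0(rep(term_measures, each = 2),
                                            c("_avg", "_bma"))]
  if (length(pairwise)) {
    ii <- c(G1[, rep(seq_len(L1), times = L2), drop = FALSE])
    jj <- c(G2[, rep(seq_len(L2), each = L1), drop = FALSE])
    micaic <- engine$micaIC[cbind(ii, jj)]
    icsum <- engine$icv[ii] + engine$icv[jj]
    base_scores <- list()
    need <- unique(vapply(pairwise, function(x) split_measure(x)$term, ""))
    if ("resnik" %in% need) base_scores$resnik <- micaic
    if (any(c("lin", "rs") %in% need)) {
      lin <- ifelse(icsum > 0, 2 * micaic / icsum, 0)
      base_scores$lin <- lin
      if ("rs" %in% need) {
        base_scores$rs <- lin * (1 - engine$micaP[cbind(ii, jj)])
      }
    }
    if ("jiang" %in% need) base_scores$jiang <- 1 / (1 + icsum - 2 * micaic)

    for (meas in pairwise) {
      sm <- split_measure(meas)
      X <- matrix(base_scores[[sm$term]], nrow = m) # m x (L1*L2), col = (i,j)
      if (sm$combiner == "avg") {
        out[, meas] <- rowMeans(X)
      } else {
        M1 <- X[, seq_len(L1), drop = FALSE] # best match over j, for each i
        if (L2 > 1L) for (j in 2:L2) {
          M1 <- pmax(M1, X[, (j - 1L) * L1 + seq_len(L1), drop = FALSE])
        }
        M2 <- matrix(NA_real_, m, L2) # best match over i, for each j
        for (j in seq_len(L2)) {
          blk <- X[, (j - 1L) * L1 + seq_len(L1), drop = FALSE]
          M2[, j] <- do.call(pmax, lapply(seq_len(L1), function(i) blk[, i]))
        }
        out[, meas] <- (rowMeans(M1) + rowMeans(M2)) / 2
      }
    }
  }

  groupwise <- setdiff(measures, pairwise)
  if (length(groupwise)) {
    n <- n_terms(engine$dag)
    Z1 <- Matrix::sparseMatrix(i = rep(seq_len(m), times = L1), j = c(G1),
                               x = 1, dims = c(m, n))
    Z2 <- Matrix::sparseMatrix(i = rep(seq_len(m), times = L2), j = c(G2),
                               x = 1, dims = c(m, n))
    B1 <- (Z1 %*% engine$Cmat) > 0 # closure indicator per pair row
    B2 <- (Z2 %*% engine$Cmat) > 0
    Binter <- B1 & B2
    a1 <- Matrix::rowSums(B1); a2 <- Matrix::rowSums(B2)
    both <- Matrix::rowSums(Binter)
    if ("to" %in% groupwise) out[, "to"] <- both
    if ("nto" %in% groupwise) out[, "nto"] <- both / pmin(a1, a2)
    if ("dice" %in% groupwise) out[, "dice"] <- 2 * both / (a1 + a2)
    if ("kappa" %in% groupwise) {
      O <- (2 * both + n - a1 - a2) / n
      p1 <- a1 / n; p2 <- a2 / n
      E <- p1 * p2 + (1 - p1) * (1 - p2)
      k <- ifelse(E == 1, 1, pmax(0, (O - E) / (1 - E)))
      out[, "kappa"] <- k
    }
    if ("gic" %in% groupwise) {
      num <- as.vector(Binter %*% engine$ic0)
      den <- as.vector(B1 %*% engine$ic0) + as.vector(B2 %*% engine$ic0) - num
      out[, "gic"] <- ifelse(den > 0, num / den, 0)
    }
    if ("vsm" %in% groupwise) {
      ic2 <- engine$ic0^2
      num <- as.vector(Binter %*% ic2)
      den <- sqrt(as.vector(B1 %*% ic2) * as.vector(B2 %*% ic2))
      out[, "vsm"] <- ifelse(den > 0, num / den, 0)
    }
  }
  out
}

#' Score a list of term-group pairs
#'
#' Buckets pairs by their `(L1, L2)` length combination and dispatches each
#' bucket to the fixed-size batch scorer.
#'
#' @param engine A [similarity_engine()].
#' @param groups1,groups2 Parallel lists of character term-id vectors (direct
#'   annotations).
#' @param measures Subset of [group_measures].
#' @return Numeric matrix `length(groups1)` x `length(measures)`.
#' @export
score_pairs <- function(engine, groups1, groups2, measures = group_measures) {
  stopifnot(length(groups1) == length(groups2))
  idx1 <- lapply(groups1, function(g) term_index(engine$dag, g))
  idx2 <- lapply(groups2, function(g) term_index(engine$dag, g))
  L1 <- lengths(idx1); L2 <- lengths(idx2)
  out <- matrix(NA_real_, length(groups1), length(measures),
                dimnames = list(NULL, measures))
  for (key in unique(paste(L1, L2))) {
    rows <- which(paste(L1, L2) == key)
    G1 <- do.call(rbind, idx1[rows])
    G2 <- do.call(rbind, idx2[rows])
    out[rows, ] <- score_pairs_fixed(engine, G1, G2, measures)
  }
  out
}

#' All-pairs protein similarity matrix
#'
#' @param engine A [similarity_engine()].
#' @param corpus An [annotation_corpus()].
#' @param measure One of [group_measures].
#' @param genes Genes to score (default: all genes in the corpus).
#' @return A symmetric numeric matrix with the genes as dimnames; the
#'   diagonal holds each gene's self-similarity. Annotation lengths are
#'   attached as attribute `"lengths"`.
#' @export
protein_similarity_matrix <- function(engine, corpus,
                                      measure = group_measures,
                                      genes = names(corpus$annotations)) {
  measure <- match.arg(measure)
  miss <- setdiff(genes, names(corpus$annotations))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  ann <- corpus$annotations[genes]
  ng <- length(genes)
  pairs <- which(upper.tri(matrix(0, ng, ng), diag = TRUE), arr.ind = TRUE)
  scores <- score_pairs(engine, ann[pairs[, 1L]], ann[pairs[, 2L]], measure)
  S <- matrix(0, ng, ng, dimnames = list(genes, genes))
  S[pairs] <- scores[, 1L]
  S[pairs[, c(2L, 1L)]] <- scores[, 1L]
  attr(S, "lengths") <- lengths(ann)
  S
}
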