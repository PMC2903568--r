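# Run code with a locally seeded RNG, restoring caller state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample a random term group
#'
#' Uniform sample without replacement of `size` distinct terms from the
#' pool of terms with defined information content. Groups may contain
#' ancestor-descendant pairs, mirroring uniform selection over the pool.
#'
#' @param dag An [ontology_dag()].
#' @param ic An [compute_ic()] table (defines the sampling pool).
#' @param size Number of terms to draw.
#' @return Character vector of `size` term identifiers.
#' @export
sample_term_group <- function(dag, ic, size) {
  pool <- which(!is.na(ic$ic))
  if (size > length(pool)) {
    stop("group size ", size, " exceeds sampling pool of ", length(pool),
         " IC-defined terms")
  }
  dag$terms[pool[sample.int(length(pool), size)]]
}

#' Null distributions of similarity scores for random term-group pairs
#'
#' The randomized experiment underlying both the bias audit and the
#' normalization: for each group-length combination, draw `n_pairs`
#' independent pairs of uniform random term groups and score each pair
#' under every requested measure. The same sampled pairs are scored by all
#' measures. `grid = "equal"` fills only the equal-size cells `(L, L)` used
#' by the bias audit; `grid = "lower"` fills every combination `L1 <= L2`,
#' as needed to normalize arbitrary protein pairs.
#'
#' @param engine A [similarity_engine()].
#' @param sizes Integer vector of group sizes (annotation lengths),
#'   default `1:10`.
#' @param n_pairs Pairs sampled per cell, default 10000.
#' @param measures Subset of [group_measures].
#' @param grid `"equal"` or `"lower"`.
#' @param seed Optional integer seed; fixed seeds give bit-identical score
#'   vectors across runs.
#' @return Object of class `null_samples`: list with `cells` (named list,
#'   key `"L1,L2"`, each holding `L1`, `L2` and a `n_pairs` x measures score
#'   matrix) plus the call parameters.
#' @export
build_null <- function(engine, sizes = 1:10, n_pairs = 10000,
                       measures = group_measures, grid = c("equal", "lower"),
                       seed = NULL) {
  grid <- match.arg(grid)
  measures <- match.arg(measures, group_measures, several.ok = TRUE)
  sizes <- sort(unique(as.integer(sizes)))
  pool <- engine$pool
  if (max(sizes) > length(pool)) {
    stop("largest group size exceeds the IC-defined sampling pool")
  }
  combos <- if (grid == "equal") {
    cbind(sizes, sizes)
  } else {
    eg <- expand.grid(L1 = sizes, L2 = sizes)
    as.matrix(eg[eg$L1 <= eg$L2, , drop = FALSE])
  }
  with_seed(seed, {
    cells <- vector("list", nrow(combos))
    names(cells) <- paste0(combos[, 1L], ",", combos[, 2L])
    for (r in seq_len(nrow(combos))) {
      L1 <- combos[r, 1L]; L2 <- combos[r, 2L]
      G1 <- t(matrix(vapply(seq_len(n_pairs),
                            function(.) pool[sample.int(length(pool), L1)],
                            integer(L1)), nrow = L1))
      G2 <- t(matrix(vapply(seq_len(n_pairs),
                            function(.) pool[sample.int(length(pool), L2)],
                            integer(L2)), nrow = L2))
      cells[[r]] <- list(L1 = L1, L2 = L2,
                         scores = score_pairs_fixed(engine, G1, G2, measures))
    }
    structure(list(cells = cells, sizes = sizes, n_pairs = n_pairs,
                   measures = measures, grid = grid, seed = seed),
              class = "null_samples")
  })
}

#' @export
print.null_samples <- function(x, ...) {
  cat(sprintf("null_samples: %d cells (%s grid, sizes %d-%d), %d pairs/cell, %d measure(s)\n",
              length(x$cells), x$grid, min(x$sizes), max(x$sizes),
              x$n_pairs, length(x$measures)))
  invisible(x)
}

#' Extract one null cell's scores
#'
#' @param null A [build_null()] result.
#' @param measure One measure name.
#' @param L1,L2 The length combination (order-free).
#' @return Numeric vector of `n_pairs` scores.
#' @export
null_cell <- function(null, measure, L1, L2) {
  lo <- min(L1, L2); hi <- max(L1, L2)
  key <- paste0(lo, ",", hi)
  if (!key %in% names(null$cells)) stop("no null cell for lengths (", key, ")")
  null$cells[[key]]$scores[, measure]
}

# Spearman rank correlation of a trend, with the degenerate all-tied case
# reported as r = 0, p = 1 (warning) instead of NA.
spearman_trend <- function(sizes, values) {
  if (length(unique(values)) == 1L) {
    warning("all values tied; Spearman correlation undefined, reporting r = 0")
    return(list(r = 0, p = 1))
  }
  ct <- suppressWarnings(
    stats::cor.test(sizes, values, method = "spearman",
                    exact = !anyDuplicated(values))
  )
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Annotation-length bias audit of raw scores
#'
#' For each measure, takes the per-size median (and SD) of the equal-size
#' null cells and reports the Spearman rank correlation of the medians
#' against the group sizes. A strong positive correlation is the signature
#' of annotation-length bias: random, biologically meaningless term groups
#' score higher merely because they are larger.
#'
#' @param null A [build_null()] result (equal-size cells required).
#' @param measures Measures to audit (default: all in `null`).
#' @return Object of class `bias_report`: a data.frame with one row per
#'   measure (`measure`, `spearman_r`, `p_value`) and a `profiles`
#'   attribute holding the per-size medians and SDs.
#' @export
bias_report <- function(null, measures = null$measures) {
  equal <- Filter(function(cell) cell$L1 == cell$L2, null$cells)
  if (length(equal) < 3L) stop("need equal-size cells for at least 3 sizes")
  sizes <- vapply(equal, `[[`, 0L, "L1")
  prof <- do.call(rbind, lapply(measures, function(meas) {
    data.frame(measure = meas, size = sizes,
               median = vapply(equal, function(cl) stats::median(cl$scores[, meas]), 0),
               sd = vapply(equal, function(cl) stats::sd(cl$scores[, meas]), 0),
               row.names = NULL)
  }))
  summ <- do.call(rbind, lapply(measures, function(meas) {
    pr <- prof[prof$measure == meas, ]
    st <- spearman_trend(pr$size, pr$median)
    data.frame(measure = meas, spearman_r = st$r, p_value = st$p,
               row.names = NULL)
  }))
  structure(summ, profiles = prof, class = c("bias_report", "data.frame"))
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Annotation-length bias audit (per-size median vs size):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
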