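#' Raw and normalized similarity scores for protein pairs
#'
#' Scores each requested gene pair under one measure, records the pair's
#' annotation-length combination, and (when a null table is supplied) the
#' normalized score.
#'
#' @param engine A [similarity_engine()].
#' @param corpus An [annotation_corpus()].
#' @param pairs Two-column character matrix or data.frame of gene pairs.
#' @param measure One of [group_measures].
#' @param table Optional [fit_null_table()] result for the same measure;
#'   adds a `nss` column.
#' @return data.frame with `gene1`, `gene2`, `L1`, `L2`, `raw` and, when a
#'   table is given, `nss`.
#' @export
score_report <- function(engine, corpus, pairs, measure = group_measures,
                         table = NULL) {
  measure <- match.arg(measure)
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  g1 <- as.character(pairs[, 1L]); g2 <- as.character(pairs[, 2L])
  miss <- setdiff(c(g1, g2), names(corpus$annotations))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  a1 <- corpus$annotations[g1]; a2 <- corpus$annotations[g2]
  raw <- score_pairs(engine, a1, a2, measure)[, 1L]
  out <- data.frame(gene1 = g1, gene2 = g2,
                    L1 = pmin(lengths(a1), lengths(a2)),
                    L2 = pmax(lengths(a1), lengths(a2)),
                    raw = raw, row.names = NULL)
  if (!is.null(table)) {
    if (!identical(attr(table, "measure"), measure)) {
      stop("null table was fitted for measure '", attr(table, "measure"),
           "', not '", measure, "'")
    }
    out$nss <- normalize_score(out$raw, out$L1, out$L2, table)
  }
  out
}
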