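#' Most informative common ancestor (MICA) of two terms
#'
#' The shared IS-A ancestor with maximal information content. Ties are broken
#' deterministically by the lexicographically smallest term identifier. When
#' the two terms share no ancestor with defined IC (possible in multi-root
#' ontologies), the MICA is `NA` with IC 0.
#'
#' @param dag An [ontology_dag()].
#' @param ic An [compute_ic()] table.
#' @param m,n Term identifiers.
#' @return List with `term` (identifier or `NA`) and `ic` (its information
#'   content, 0 for the empty case).
#' @export
mica <- function(dag, ic, m, n) {
  im <- term_index(dag, m); jn <- term_index(dag, n)
  common <- intersect(dag$closure[[im]], dag$closure[[jn]])
  vals <- ic$ic[common]
  common <- common[!is.na(vals)]; vals <- vals[!is.na(vals)]
  if (length(common) == 0L) return(list(term = NA_character_, ic = 0))
  best <- max(vals)
  cand <- dag$terms[common[vals == best]]
  list(term = min(cand), ic = best)
}

term_measures <- c("resnik", "lin", "rs", "jiang")

#' Information-content similarity of a term pair
#'
#' The four IC-based term measures, each driven by the information content of
#' the most informative common ancestor (MICA):
#' \describe{
#'   \item{resnik}{`IC(mica)`, range `>= 0`.}
#'   \item{lin}{`2 IC(mica) / (IC(m) + IC(n))`, with the 0/0 case (both terms
#'     of zero IC) defined as 0; range `[0, 1]`.}
#'   \item{rs}{Relevance: `lin * (1 - p(mica))`, down-weighting promiscuous
#'     ancestors; range `[0, 1)`.}
#'   \item{jiang}{`1 / (1 + IC(m) + IC(n) - 2 IC(mica))`, a similarity mapping
#'     of the Jiang-Conrath IC distance with range `(0, 1]`.}
#' }
#' All are symmetric in `m` and `n`.
#'
#' @param measure One of `"resnik"`, `"lin"`, `"rs"`, `"jiang"`.
#' @param dag An [ontology_dag()].
#' @param ic An [compute_ic()] table; both terms must have defined IC.
#' @param m,n Term identifiers.
#' @return List of class `term_pair_score` with `measure`, `value` and
#'   `mica` (the ancestor realizing the score, or `NA`).
#' @export
term_pair_score <- function(measure = term_measures, dag, ic, m, n) {
  measure <- match.arg(measure)
  icm <- ic$ic[[term_index(dag, m)]]
  icn <- ic$ic[[term_index(dag, n)]]
  if (is.na(icm) || is.na(icn)) {
    stop("undefined information content for term(s): ",
         paste(c(m, n)[is.na(c(icm, icn))], collapse = ", "))
  }
  mi <- mica(dag, ic, m, n)
  value <- switch(measure,
    resnik = mi$ic,
    lin = if (icm + icn > 0) 2 * mi$ic / (icm + icn) else 0,
    rs = {
      lin <- if (icm + icn > 0) 2 * mi$ic / (icm + icn) else 0
      pm <- if (is.na(mi$term)) 0 else ic$p[[mi$term]]
      lin * (1 - pm)
    },
    jiang = 1 / (1 + icm + icn - 2 * mi$ic)
  )
  structure(list(measure = measure, value = value, mica = mi$term),
            class = "term_pair_score")
}

#' @export
print.term_pair_score <- function(x, ...) {
  cat(sprintf("%s = %.6g (mica: %s)\n", x$measure, x$value,
              if (is.na(x$mica)) "<none>" else x$mica))
  invisible(x)
}
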