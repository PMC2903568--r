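# Independent naive implementations of every measure, written with explicit
# loops and repeated parent walks (no use of the package's cached closures
# or batch scorer). These serve as the oracle in equivalence tests.

naive_ancestors <- function(dag, term) {
  # walk parent links with a worklist until closure stabilizes
  res <- term
  work <- term
  while (length(work)) {
    t <- work[[1L]]; work <- work[-1L]
    ps <- dag$terms[dag$parents[[match(t, dag$terms)]]]
    new <- setdiff(ps, res)
    res <- c(res, new)
    work <- c(work, new)
  }
  sort(res)
}

naive_closure <- function(dag, terms) {
  sort(unique(unlist(lapply(terms, naive_ancestors, dag = dag))))
}

naive_mica <- function(dag, ic, m, n) {
  common <- intersect(naive_ancestors(dag, m), naive_ancestors(dag, n))
  common <- common[!is.na(ic$ic[common])]
  if (length(common) == 0L) return(list(term = NA_character_, ic = 0))
  best_ic <- -Inf; best_term <- NA_character_
  for (a in sort(common)) { # sorted: first max hit is the smallest id
    if (ic$ic[[a]] > best_ic) {
      best_ic <- ic$ic[[a]]; best_term <- a
    }
  }
  list(term = best_term, ic = best_ic)
}

naive_term_score <- function(measure, dag, ic, m, n) {
  mi <- naive_mica(dag, ic, m, n)
  icm <- ic$ic[[m]]; icn <- ic$ic[[n]]
  if (measure == "resnik") return(mi$ic)
  if (measure == "lin") {
    return(if (icm + icn > 0) 2 * mi$ic / (icm + icn) else 0)
  }
  if (measure == "rs") {
    lin <- if (icm + icn > 0) 2 * mi$ic / (icm + icn) else 0
    pm <- if (is.na(mi$term)) 0 else ic$p[[mi$term]]
    return(lin * (1 - pm))
  }
  1 / (1 + icm + icn - 2 * mi$ic)
}

naive_group_score <- function(measure, dag, ic, terms1, terms2) {
  cl1 <- naive_closure(dag, terms1)
  cl2 <- naive_closure(dag, terms2)
  if (measure %in% c("to", "nto", "dice")) {
    to <- 0
    for (t in cl1) if (t %in% cl2) to <- to + 1
    return(switch(measure,
                  to = to,
                  nto = to / min(length(cl1), length(cl2)),
                  dice = 2 * to / (length(cl1) + length(cl2))))
  }
  if (measure == "kappa") {
    v1 <- dag$terms %in% cl1
    v2 <- dag$terms %in% cl2
    O <- mean(v1 == v2)
    E <- mean(v1) * mean(v2) + mean(!v1) * mean(!v2)
    if (E == 1) return(1)
    return(max(0, (O - E) / (1 - E)))
  }
  if (measure %in% c("gic", "vsm")) {
    w <- ifelse(is.na(ic$ic), 0, ic$ic)
    names(w) <- names(ic$ic)
    if (measure == "gic") {
      den <- sum(w[unique(c(cl1, cl2))])
      if (den == 0) return(0)
      return(sum(w[intersect(cl1, cl2)]) / den)
    }
    v1 <- ifelse(dag$terms %in% cl1, w[dag$terms], 0)
    v2 <- ifelse(dag$terms %in% cl2, w[dag$terms], 0)
    den <- sqrt(sum(v1^2) * sum(v2^2))
    if (den == 0) return(0)
    return(sum(v1 * v2) / den)
  }
  # combined measures: explicit double loop
  parts <- strsplit(measure, "_")[[1L]]
  S <- matrix(0, length(terms1), length(terms2))
  for (i in seq_along(terms1)) {
    for (j in seq_along(terms2)) {
      S[i, j] <- naive_term_score(parts[1L], dag, ic, terms1[i], terms2[j])
    }
  }
  if (parts[2L] == "avg") {
    mean(S)
  } else {
    (mean(apply(S, 1L, max)) + mean(apply(S, 2L, max))) / 2
  }
}
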