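# Shared fixtures: tiny hand-built ontologies and corpora.

# Diamond: d is_a b, d is_a c, b is_a r, c is_a r.
diamond_dag <- function() {
  ontology_dag(c("r", "b", "c", "d"),
               list(character(), "r", "r", c("b", "c")))
}

# Chain a -> b -> root.
chain_dag <- function() {
  ontology_dag(c("root", "b", "a"), list(character(), "root", "b"))
}

# Fixture with hand-computable ICs over 8 genes:
#   m (1 gene), n (2 genes), a = parent of both (4 genes), root (8 genes)
#   IC: m = ln 8, n = ln 4, a = ln 2, root = 0.
ic_fixture <- function() {
  dag <- ontology_dag(c("root", "a", "m", "n"),
                      list(character(), "root", "a", "a"))
  corpus <- annotation_corpus(list(
    g1 = "m", g2 = "n", g3 = "n", g4 = "a",
    g5 = "root", g6 = "root", g7 = "root", g8 = "root"
  ))
  list(dag = dag, corpus = corpus, ic = compute_ic(dag, corpus))
}

# Forge a term_group with an explicit closed set (for formula-level tests).
forged_group <- function(direct, closed) {
  structure(list(direct = direct, closed = closed, length = length(direct)),
            class = "term_group")
}

# Forge a bare DAG shell whose only used field is the term universe.
forged_universe <- function(terms) {
  structure(list(terms = terms), class = "ontology_dag")
}

forged_ic <- function(ic_values) {
  structure(list(ic = ic_values, p = exp(-ic_values),
                 total_genes = NA_integer_), class = "ic_table")
}

# Small random scenario used by property tests.
small_scenario <- function(seed, n_terms = 60, n_genes = 150) {
  spec <- synthetic_spec(n_terms = n_terms, depth = 4, n_genes = n_genes,
                         seed = seed)
  dag <- generate_dag(spec)
  corpus <- generate_corpus(spec, dag)
  ic <- compute_ic(dag, corpus)
  list(spec = spec, dag = dag, corpus = corpus, ic = ic,
       engine = similarity_engine(dag, ic))
}

nine_normalizable <- c("resnik_avg", "resnik_bma", "lin_avg", "lin_bma",
                       "rs_avg", "rs_bma", "jiang_avg", "dice", "kappa")
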