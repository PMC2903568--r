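test_that("parse_obo keeps IS-A structure and drops obsolete terms and part_of", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: child A",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: child B",
    "namespace: biological_process", "is_a: GO:0000001",
    "relationship: part_of GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: gone", "is_obsolete: true",
    "is_a: GO:0000001", ""
  )
  dag <- parse_obo(obo)
  expect_s3_class(dag, "ontology_dag")
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(sum(lengths(dag$parents)), 2L)  # part_of ignored
  expect_equal(dag$terms[dag$roots], "GO:0000001")
  expect_false("GO:0000004" %in% dag$terms)
})

test_that("parse_obo rejects cyclic and empty input", {
  cyc <- c("[Term]", "id: A", "is_a: B", "",
           "[Term]", "id: B", "is_a: A", "")
  expect_error(parse_obo(cyc), "cycle")
  expect_error(parse_obo(c("format-version: 1.2", "")), "empty")
})

test_that("parse_gaf filters aspect, NOT qualifiers, duplicates and evidence", {
  dag <- diamond_dag()
  gaf_row <- function(gene, term, qual = "", ev = "EXP", aspect = "P") {
    paste("DB", gene, gene, qual, term, "REF:1", ev, "", aspect, "name", "",
          "protein", "taxon:9606", "20080801", "DB", sep = "\t")
  }
  gaf <- c("!gaf-version: 2.1",
           gaf_row("g1", "d"),
           gaf_row("g1", "d"),                 # duplicate
           gaf_row("g1", "b", qual = "NOT"),   # negated
           gaf_row("g2", "b"),
           gaf_row("g2", "c", ev = "IEA"),
           gaf_row("g3", "d", aspect = "F"))   # wrong aspect
  corpus <- parse_gaf(gaf, dag, aspect = "P")
  expect_equal(sort(names(corpus$annotations)), c("g1", "g2"))
  expect_equal(corpus$annotations$g1, "d")
  expect_equal(corpus$annotations$g2, c("b", "c"))

  no_iea <- parse_gaf(gaf, dag, aspect = "P", evidence_exclude = "IEA")
  expect_equal(no_iea$annotations$g2, "b")

  expect_warning(
    parse_gaf(c("!x", gaf_row("g1", "d"), "bad\trow"), dag, aspect = "P"),
    "malformed"
  )
  expect_warning(
    parse_gaf(c(gaf_row("g1", "d"), gaf_row("g1", "zzz")), dag, aspect = "P"),
    "absent from the DAG"
  )
  expect_error(parse_gaf(gaf_row("g3", "d", aspect = "F"), dag, aspect = "P"),
               "no annotation rows")
})

test_that("ancestor closure matches transitive parent lookup and is monotone", {
  dag <- chain_dag()
  expect_equal(ancestor_closure(dag, "root"), "root")
  expect_equal(sort(ancestor_closure(dag, "a")), c("a", "b", "root"))
  expect_equal(sort(ancestor_closure(diamond_dag(), "d")),
               c("b", "c", "d", "r"))
  expect_error(ancestor_closure(dag, "nope"), "nope")

  # idempotence + monotonicity + naive-oracle agreement on random DAGs
  for (seed in 1:5) {
    sc <- small_scenario(seed, n_terms = 40, n_genes = 30)
    set.seed(seed)
    S <- sample(sc$dag$terms, 3)
    T2 <- unique(c(S, sample(sc$dag$terms, 3)))
    cS <- ancestor_closure(sc$dag, S)
    expect_equal(cS, naive_closure(sc$dag, S))
    expect_equal(ancestor_closure(sc$dag, cS), cS)
    expect_true(all(cS %in% ancestor_closure(sc$dag, T2)))
  }
})

test_that("information content counts cumulative gene coverage", {
  fx <- ic_fixture()
  ic <- fx$ic
  expect_equal(ic$total_genes, 8)
  expect_equal(unname(ic$p[c("root", "a", "n", "m")]), c(1, 0.5, 0.25, 0.125))
  expect_equal(unname(ic$ic[["root"]]), 0)
  expect_equal(unname(ic$ic[["m"]]), log(8))

  # anti-monotone along every IS-A edge of random DAGs; zero-count terms NA
  for (seed in 1:5) {
    sc <- small_scenario(seed)
    for (t in seq_along(sc$dag$terms)) {
      for (p in sc$dag$parents[[t]]) {
        ict <- sc$ic$ic[[t]]; icp <- sc$ic$ic[[p]]
        if (!is.na(ict)) {
          expect_false(is.na(icp))
          expect_lte(icp, ict)
        }
      }
    }
  }
})

test_that("edge-list round trip reproduces the DAG", {
  sc <- small_scenario(3, n_terms = 30, n_genes = 20)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dag_edges(sc$dag, f)
  back <- read_dag_edges(f, namespace = sc$dag$namespace)
  expect_setequal(back$terms, sc$dag$terms)
  for (t in sc$dag$terms) {
    expect_setequal(back$terms[back$parents[[match(t, back$terms)]]],
                    sc$dag$terms[sc$dag$parents[[match(t, sc$dag$terms)]]])
  }
})

test_that("OBO and GAF writers round-trip through the parsers", {
  sc <- small_scenario(4, n_terms = 25, n_genes = 15)
  fo <- withr::local_tempfile(fileext = ".obo")
  fg <- withr::local_tempfile(fileext = ".gaf")
  write_obo(sc$dag, fo)
  write_gaf(sc$corpus, fg)
  dag2 <- parse_obo(fo)
  expect_setequal(dag2$terms, sc$dag$terms)
  expect_equal(sum(lengths(dag2$parents)), sum(lengths(sc$dag$parents)))
  corpus2 <- parse_gaf(fg, dag2, aspect = "P")
  expect_equal(corpus2$annotations[names(sc$corpus$annotations)],
               sc$corpus$annotations)
})
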