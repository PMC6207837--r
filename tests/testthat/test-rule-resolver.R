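test_that("of-phrase candidates come from the annotated relations", {
  o <- part_of_ontology(c("base", "leaf"),
                        part_of = data.frame(child = "base", parent = "leaf"))
  st <- toy_statement("of1", c("base", "of", "the", "leaves"),
                      heads = c(0L, 3L), names = c("base", "leaves"),
                      relations = data.frame(kind = "of_phrase",
                                             dependent = "e1", governor = "e2",
                                             trigger = "of"))
  expect_identical(candidates_for(st, "e1", "of_phrase", rule_config(), o),
                   "e2")
  # no relations and an empty (unlicensed) window -> no candidates
  st2 <- toy_statement("of2", c("apex", "rounded"), heads = 0L, names = "apex")
  expect_identical(candidates_for(st2, "e1", "of_phrase", rule_config(),
                                  part_of_ontology()), character())
  expect_identical(candidates_for(st2, "e1", "window", rule_config(),
                                  part_of_ontology()), character())
})

test_that("window candidates sort closest-first, preceding preferred on ties", {
  cfg <- rule_config(ontology_required = FALSE)
  set.seed(123)
  for (rep in 1:500) {
    k <- sample(3:7, 1L)
    heads <- sort(sample(0:19, k))
    names <- c("apex", paste0("organ", letters[seq_len(k - 1L)]))[sample.int(k)]
    nss_at <- which(names == "apex")
    words <- rep("pad", 20L)
    words[heads + 1L] <- names
    st <- toy_statement(paste0("w", rep), words, heads, names)
    nid <- st$entities$id[st$entities$name == "apex"]
    got <- candidates_for(st, nid, "window", cfg)
    others <- st$entities[st$entities$id != nid, ]
    d <- others$head_token - st$entities$head_token[st$entities$id == nid]
    want <- others$id[order(abs(d), d)]
    expect_identical(got, want)
  }
})

test_that("window spans are bounded by sentence distance", {
  words <- c("apex", ";", "a1", ";", "a2", ";", "a3", ";", "a4")
  sidx <- c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L)
  st <- toy_statement("sent", words, heads = c(0L, 2L, 4L, 6L, 8L),
                      names = c("apex", "organa", "organb", "organc", "organd"),
                      sentence_index = sidx)
  cfg <- rule_config(ontology_required = FALSE, window_size = 3L)
  got <- candidates_for(st, "e1", "window", cfg)
  # the entity four sentence boundaries away is out of range
  expect_identical(got, c("e2", "e3", "e4"))
  cfg1 <- rule_config(ontology_required = FALSE, window_size = 1L)
  expect_identical(candidates_for(st, "e1", "window", cfg1), "e2")
})

test_that("rule priority is respected and every anchor passed the ontology", {
  # of-phrase target and a much closer possession/window competitor
  o <- part_of_ontology(c("apex", "leaf", "stem"),
                        part_of = data.frame(child = c("apex", "apex"),
                                             parent = c("leaf", "stem")))
  st <- toy_statement("prio", c("stem", "has", "apex", "of", "the", "leaf"),
                      heads = c(0L, 2L, 5L), names = c("stem", "apex", "leaf"),
                      relations = data.frame(
                        kind = c("possession", "of_phrase"),
                        dependent = c("e2", "e2"), governor = c("e1", "e3"),
                        trigger = c("has", "of")))
  res <- resolve_statement(st, o)
  expect_identical(res$anchor_name, "leaf")
  expect_identical(res$detail, "of_phrase")

  # remove the of-phrase licence: possession wins
  o2 <- part_of_ontology(c("apex", "stem"),
                         part_of = data.frame(child = "apex", parent = "stem"))
  res2 <- resolve_statement(st, o2)
  expect_identical(res2$anchor_name, "stem")
  expect_identical(res2$detail, "possession")
})

test_that("an NSS with no licensed candidate is left unresolved", {
  st <- toy_statement("null1", c("leaf", "broad", "apex"),
                      heads = c(0L, 2L), names = c("leaf", "apex"))
  res <- resolve_statement(st, part_of_ontology())
  expect_identical(nrow(res), 1L)
  expect_true(is.na(res$anchor_name))
})

test_that("chained NSS terms resolve recursively with compound names", {
  we <- we_fixture()
  res <- resolve_statement(we$statements[[2L]], we$ontology)
  got <- setNames(res$anchor_name, res$nss_name)
  expect_identical(got[["edge"]], "abdomen upper margin")
  expect_identical(got[["upper margin"]], "abdomen")
  # the chained NSS is resolved once, not revisited
  expect_identical(nrow(res), 2L)
})

test_that("cyclic NSS chains leave both members unresolved with a warning", {
  o <- part_of_ontology(c("edge", "margin"),
                        part_of = data.frame(child = c("edge", "margin"),
                                             parent = c("margin", "edge")))
  st <- toy_statement("cyc", c("edge", "near", "margin"),
                      heads = c(0L, 2L), names = c("edge", "margin"))
  expect_warning(res <- resolve_statement(st, o), "chain")
  expect_true(all(is.na(res$anchor_name)))
})

test_that("the ontology_only variant uses only the window rule", {
  cfg <- rule_config(variant = "ontology_only")
  expect_identical(cfg$rule_order, "window")
  # an of-phrase pointing at an unlicensed governor is ignored; the licensed
  # window candidate is found instead
  o <- part_of_ontology(c("apex", "leaf"),
                        part_of = data.frame(child = "apex", parent = "leaf"))
  st <- toy_statement("vo", c("leaf", "with", "apex", "of", "stem"),
                      heads = c(0L, 2L, 4L), names = c("leaf", "apex", "stem"),
                      relations = data.frame(kind = "of_phrase",
                                             dependent = "e2", governor = "e3",
                                             trigger = "of"))
  res <- resolve_statement(st, o, cfg)
  expect_identical(res$anchor_name, "leaf")
  expect_identical(res$detail, "window")
})

test_that("rule resolution equals the brute-force cascade oracle", {
  co <- generate_corpus(generator_config(n_statements = 200L, seed = 31L))
  res <- resolve_corpus(co$statements, co$ontology)
  for (st in co$statements) {
    want <- oracle_rule_resolve(st, co$ontology)
    sub <- res[res$statement_id == st$id, ]
    got <- setNames(sub$anchor_name, sub$nss_id)
    expect_identical(got[names(want)], want)
  }
})

test_that("corpus resolution is deterministic and compositional", {
  co <- generate_corpus(generator_config(n_statements = 40L, seed = 5L))
  r1 <- resolve_corpus(co$statements, co$ontology)
  r2 <- resolve_corpus(co$statements, co$ontology)
  expect_identical(r1, r2)
  per <- do.call(rbind, lapply(co$statements, resolve_statement,
                               onto = co$ontology, config = rule_config()))
  rownames(per) <- NULL
  expect_identical(r1, per)
  expect_identical(nrow(resolve_corpus(list(), co$ontology)), 0L)
})
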