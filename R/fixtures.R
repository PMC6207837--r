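# Deterministic synthetic corpus generator. Emits annotated statements in
# the telegraphic style of morphological descriptions ("<organ> with <adj>
# <nss> near the <organ>"), a matching soft part-of ontology, gold anchors,
# and a provenance log naming the signal that determines each gold anchor.
#
# The generator first fixes, per NSS term, the set of organs it may be part
# of (the "licensed" set); the emitted ontology is exactly this assignment
# (some pairs expressed through a compound subclass term to exercise the
# subclass closure) plus the NSS-to-NSS edges used by chain statements.
# Statement templates then plant one decisive signal each:
#   of         "o2 adj , nss of the o adj ."       gold by the of-phrase
#   possession "o with adj adj nss near the o2 ."  gold by the possession word
#   window     "o2 adj ; nss adj ; o adj ."        gold by proximity + ontology
#   chain      "o has a adj n1 at its n2 ."        two NSS, compound gold
#   distractor gold organ absent from the statement and unlicensed: no
#              method can recover it, the ontology-constrained rule engine
#              abstains
# Noise replaces a statement's gold organ with one whose pair is absent from
# the ontology, so the rule engine abstains there too.

.default_organs <- c("leaf", "stem", "petal", "leaflet", "rhachis", "petiole",
                     "sepal", "seed", "fruit", "stipule", "elytron", "abdomen",
                     "thorax", "pronotum", "femur", "antenna", "mandible",
                     "tarsus")

.default_gen_nss <- c("apex", "base", "margin", "edge", "side", "surface",
                      "tip", "face", "end", "band", "line", "pore", "groove",
                      "notch", "wall", "zone")

.default_adjectives <- c("rounded", "acute", "obtuse", "smooth", "glabrous",
                         "pubescent", "serrate", "entire", "narrow", "broad",
                         "thin", "dense", "punctate", "striate")

#' Generator configuration
#'
#' @param n_statements Number of statements to generate.
#' @param seed Integer seed; fixes all randomness end-to-end.
#' @param organ_vocabulary Candidate anchor organ names (plant and insect
#'   organs by default).
#' @param nss_vocabulary NSS terms used in statements; must be members of
#'   the packaged lexicon.
#' @param mix Named proportions over statement categories `of`,
#'   `possession`, `window`, `chain`, `distractor`; must sum to 1.
#' @param noise Probability that a statement's gold pair is withheld from
#'   the emitted ontology (the gold anchor is then replaced by an unlicensed
#'   organ, so ontology-constrained resolution abstains).
#' @param licensed_per_nss Organs licensed per NSS term (default 3).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_statements = 100L, seed = 1L,
                             organ_vocabulary = .default_organs,
                             nss_vocabulary = .default_gen_nss,
                             mix = c(of = 0.35, possession = 0.25,
                                     window = 0.25, chain = 0.15,
                                     distractor = 0),
                             noise = 0, licensed_per_nss = 3L) {
  stopifnot(length(organ_vocabulary) > 0L, length(nss_vocabulary) > 0L)
  need <- c("of", "possession", "window", "chain", "distractor")
  if (!all(need %in% names(mix))) {
    mix <- stats::setNames(mix[need], need)
    mix[is.na(mix)] <- 0
  }
  mix <- mix[need]
  if (abs(sum(mix) - 1) > 1e-8) stop("mix proportions must sum to 1")
  stopifnot(noise >= 0, noise <= 1)
  structure(
    list(n_statements = as.integer(n_statements), seed = as.integer(seed),
         organ_vocabulary = tolower(organ_vocabulary),
         nss_vocabulary = tolower(nss_vocabulary), mix = mix, noise = noise,
         licensed_per_nss = as.integer(licensed_per_nss)),
    class = "generator_config"
  )
}

# Fixed licensing assignment: per NSS term its licensed organs, an encoding
# choice (direct edge vs compound subclass term), and chain partners.
build_assignment <- function(config) {
  organs <- config$organ_vocabulary
  nssv <- config$nss_vocabulary
  licensed <- lapply(stats::setNames(nssv, nssv), function(n) {
    sort(sample(organs, min(config$licensed_per_nss, length(organs))))
  })
  part_of <- list(); subclass_of <- list()
  for (n in nssv) {
    for (o in licensed[[n]]) {
      if (stats::runif(1) < 0.25) {
        compound <- paste(o, n)
        subclass_of[[length(subclass_of) + 1L]] <-
          data.frame(sub = compound, super = n, stringsAsFactors = FALSE)
        part_of[[length(part_of) + 1L]] <-
          data.frame(child = compound, parent = o, stringsAsFactors = FALSE)
      } else {
        part_of[[length(part_of) + 1L]] <-
          data.frame(child = n, parent = o, stringsAsFactors = FALSE)
      }
    }
  }
  # chain partners: n1 part-of n2, with some organ licensed for n2 but not n1
  chains <- list()
  if (length(nssv) >= 2L) {
    for (i in seq_len(min(5L, length(nssv) %/% 2L))) {
      pair <- sample(nssv, 2L)
      pool <- setdiff(licensed[[pair[2L]]], licensed[[pair[1L]]])
      if (length(pool) == 0L) next
      chains[[length(chains) + 1L]] <- list(n1 = pair[1L], n2 = pair[2L],
                                            organs = pool)
      part_of[[length(part_of) + 1L]] <-
        data.frame(child = pair[1L], parent = pair[2L], stringsAsFactors = FALSE)
    }
  }
  po <- do.call(rbind, part_of)
  sc <- do.call(rbind, subclass_of)
  # term set = edge endpoints, so the CSV edge-list round trip is exact
  terms <- unique(c(po$child, po$parent, sc$sub, sc$super))
  list(licensed = licensed, chains = chains,
       ontology = part_of_ontology(terms, po, sc))
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

make_tokens <- function(words, sentence_index) {
  data.frame(index = seq_along(words) - 1L, text = words,
             sentence_index = as.integer(sentence_index),
             stringsAsFactors = FALSE)
}

ent <- function(id, head, start, end, name) {
  data.frame(id = id, head_token = head, start = start, end = end,
             name = name, stringsAsFactors = FALSE)
}

# One statement for a category; returns list(statement, signal, noised).
gen_statement <- function(sid, category, assign, config, lexicon) {
  organs <- config$organ_vocabulary
  adj <- function() sample1(.default_adjectives)
  noised <- category %in% c("of", "possession", "window") &&
    stats::runif(1) < config$noise
  pick_gold_organ <- function(n) {
    if (noised) sample1(setdiff(organs, assign$licensed[[n]]))
    else sample1(assign$licensed[[n]])
  }
  if (category == "chain" && length(assign$chains) == 0L) category <- "window"

  if (category == "of") {
    n <- sample1(config$nss_vocabulary)
    o <- pick_gold_organ(n)
    o2 <- sample1(setdiff(organs, c(assign$licensed[[n]], o)))
    a <- sample1(1:2)
    words <- c(o2, replicate(a, adj()), ",", n, "of", "the", o, adj(), ".")
    nh <- a + 2L
    entities <- rbind(ent("e1", 0L, 0L, 1L, o2),
                      ent("e2", nh, nh, nh + 1L, n),
                      ent("e3", nh + 3L, nh + 3L, nh + 4L, o))
    relations <- data.frame(kind = "of_phrase", dependent = "e2",
                            governor = "e3", trigger = "of",
                            stringsAsFactors = FALSE)
    st <- statement(sid, make_tokens(words, 0L), entities, relations,
                    gold = c(e2 = o), lexicon = lexicon)
    return(list(statement = st, signal = "of", noised = noised))
  }
  if (category == "possession") {
    n <- sample1(config$nss_vocabulary)
    o <- pick_gold_organ(n)
    o2 <- sample1(setdiff(organs, c(assign$licensed[[n]], o)))
    words <- c(o, "with", adj(), adj(), n, "near", "the", o2, ".")
    entities <- rbind(ent("e1", 0L, 0L, 1L, o),
                      ent("e2", 4L, 4L, 5L, n),
                      ent("e3", 7L, 7L, 8L, o2))
    relations <- data.frame(kind = "possession", dependent = "e2",
                            governor = "e1", trigger = "with",
                            stringsAsFactors = FALSE)
    st <- statement(sid, make_tokens(words, 0L), entities, relations,
                    gold = c(e2 = o), lexicon = lexicon)
    return(list(statement = st, signal = "possession", noised = noised))
  }
  if (category == "window") {
    n <- sample1(config$nss_vocabulary)
    o <- pick_gold_organ(n)
    o2 <- sample1(setdiff(organs, c(assign$licensed[[n]], o)))
    words <- c(o2, adj(), ";", n, adj(), ";", o, adj(), ".")
    sidx <- c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L)
    entities <- rbind(ent("e1", 0L, 0L, 1L, o2),
                      ent("e2", 3L, 3L, 4L, n),
                      ent("e3", 6L, 6L, 7L, o))
    st <- statement(sid, make_tokens(words, sidx), entities, NULL,
                    gold = c(e2 = o), lexicon = lexicon)
    return(list(statement = st, signal = "window", noised = noised))
  }
  if (category == "chain") {
    ch <- assign$chains[[sample1(seq_along(assign$chains))]]
    o <- sample1(ch$organs)
    words <- c(o, "has", "a", adj(), ch$n1, "at", "its", ch$n2, ".")
    entities <- rbind(ent("e1", 0L, 0L, 1L, o),
                      ent("e2", 4L, 4L, 5L, ch$n1),
                      ent("e3", 7L, 7L, 8L, ch$n2))
    relations <- data.frame(kind = "possession", dependent = "e2",
                            governor = "e1", trigger = "has",
                            stringsAsFactors = FALSE)
    gold <- c(e2 = paste(o, ch$n2), e3 = o)
    st <- statement(sid, make_tokens(words, 0L), entities, relations,
                    gold = gold, lexicon = lexicon)
    return(list(statement = st, signal = "chain", noised = FALSE))
  }
  # distractor: gold organ neither mentioned nor licensed
  n <- sample1(config$nss_vocabulary)
  o_hidden <- sample1(setdiff(organs, assign$licensed[[n]]))
  o2 <- sample1(setdiff(organs, c(assign$licensed[[n]], o_hidden)))
  words <- c(o2, adj(), ";", n, adj(), ".")
  sidx <- c(0L, 0L, 0L, 1L, 1L, 1L)
  entities <- rbind(ent("e1", 0L, 0L, 1L, o2),
                    ent("e2", 3L, 3L, 4L, n))
  st <- statement(sid, make_tokens(words, sidx), entities, NULL,
                  gold = c(e2 = o_hidden), lexicon = lexicon)
  list(statement = st, signal = "none", noised = FALSE)
}

#' Generate a synthetic annotated corpus
#'
#' Produces `config$n_statements` statements with gold anchors, the matching
#' soft part-of ontology, and a provenance log recording which signal
#' determines each statement's gold anchor. Every gold anchor is licensed by
#' the emitted ontology and recoverable by the rule engine unless the
#' statement was noised or drawn from the `distractor` category. Identical
#' configurations (including seed) give byte-identical outputs.
#'
#' @param config A [generator_config()].
#' @return List with `statements` (list of `nss_statement`), `ontology`
#'   (a `part_of_ontology`) and `provenance` (data frame with columns
#'   `statement_id`, `signal`, `noised`).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_statements == 0L) {
    return(list(statements = list(), ontology = part_of_ontology(),
                provenance = data.frame(statement_id = character(),
                                        signal = character(), noised = logical(),
                                        stringsAsFactors = FALSE)))
  }
  set.seed(config$seed)
  lexicon <- nss_lexicon()
  bad <- setdiff(config$nss_vocabulary, lexicon)
  if (length(bad) > 0L) {
    stop("nss_vocabulary terms not in lexicon: ", paste(bad, collapse = ", "))
  }
  assign <- build_assignment(config)
  categories <- sample(names(config$mix), config$n_statements,
                       replace = TRUE, prob = config$mix)
  out <- lapply(seq_len(config$n_statements), function(i) {
    gen_statement(sprintf("s%04d", i), categories[i], assign, config, lexicon)
  })
  list(
    statements = lapply(out, `[[`, "statement"),
    ontology = assign$ontology,
    provenance = data.frame(
      statement_id = vapply(out, function(x) x$statement$id, character(1L)),
      signal = vapply(out, `[[`, character(1L), "signal"),
      noised = vapply(out, `[[`, logical(1L), "noised"),
      stringsAsFactors = FALSE)
  )
}

#' The two in-text worked examples
#'
#' Returns the two classic statements used throughout the documentation --
#' the leaflet statement ("Leaflets articulated, inserted near the edges of
#' the rhachis ...") whose six NSS mentions anchor to rhachis, leaflets and
#' epidermal, and the recursion statement ("abdomen has a thin edge at its
#' upper margin") whose chained NSS terms yield the compound anchor "abdomen
#' upper margin" -- together with a minimal licensing ontology and the
#' lexicon under which their NSS flags hold (the packaged default plus
#' "axis", needed for "long axes").
#'
#' @return List with `statements` (two `nss_statement`s), `ontology`, and
#'   `lexicon`.
#' @export
worked_examples <- function() {
  lexicon <- c(nss_lexicon(), "axis")
  onto <- part_of_ontology(
    terms = c("edge", "rhachis", "side", "leaflet", "surface", "cell",
              "epidermal", "axis", "margin", "abdomen"),
    part_of = data.frame(
      child = c("edge", "side", "surface", "cell", "axis", "edge", "margin"),
      parent = c("rhachis", "leaflet", "leaflet", "epidermal", "leaflet",
                 "margin", "abdomen"),
      stringsAsFactors = FALSE)
  )
  w1 <- c("Leaflets", "articulated", ",", "inserted", "near", "the", "edges",
          "of", "the", "rhachis", "towards", "the", "adaxial", "side", ",",
          "lacking", "a", "differently", "coloured", "basal", "gland", ";",
          "stomata", "on", "lower", "surface", "only", "or", "on", "both",
          "surfaces", ";", "epidermal", "cells", "elongated", "parallel",
          "to", "long", "axes", "of", "leaflets", ".")
  s1idx <- c(rep(0L, 22), rep(1L, 10), rep(2L, 10))
  e1 <- rbind(
    ent("e1", 0L, 0L, 1L, "leaflets"),
    ent("e2", 6L, 6L, 7L, "edges"),
    ent("e3", 9L, 9L, 10L, "rhachis"),
    ent("e4", 13L, 12L, 14L, "adaxial side"),
    ent("e5", 20L, 20L, 21L, "gland"),
    ent("e6", 22L, 22L, 23L, "stomata"),
    ent("e7", 25L, 24L, 26L, "lower surface"),
    ent("e8", 30L, 30L, 31L, "surfaces"),
    ent("e9", 32L, 32L, 33L, "epidermal"),
    ent("e10", 33L, 33L, 34L, "cells"),
    ent("e11", 38L, 37L, 39L, "long axes"),
    ent("e12", 40L, 40L, 41L, "leaflets")
  )
  r1 <- data.frame(
    kind = c("of_phrase", "of_phrase"),
    dependent = c("e2", "e11"), governor = c("e3", "e12"),
    trigger = c("of", "of"), stringsAsFactors = FALSE)
  g1 <- c(e2 = "rhachis", e4 = "leaflets", e7 = "leaflets", e8 = "leaflets",
          e10 = "epidermal", e11 = "leaflets")
  st1 <- statement("leaflet-example", make_tokens(w1, s1idx), e1, r1, g1,
                   lexicon = lexicon)

  w2 <- c("abdomen", "has", "a", "thin", "edge", "at", "its", "upper",
          "margin", ".")
  e2df <- rbind(
    ent("e1", 0L, 0L, 1L, "abdomen"),
    ent("e2", 4L, 4L, 5L, "edge"),
    ent("e3", 8L, 7L, 9L, "upper margin")
  )
  r2 <- data.frame(kind = "possession", dependent = "e2", governor = "e1",
                   trigger = "has", stringsAsFactors = FALSE)
  g2 <- c(e2 = "abdomen upper margin", e3 = "abdomen")
  st2 <- statement("recursion-example", make_tokens(w2, 0L), e2df, r2, g2,
                   lexicon = lexicon)

  list(statements = list(st1, st2), ontology = onto, lexicon = lexicon)
}
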