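# Annotated statements: tokens, entity mentions, syntactic relations, gold
# anchors. A statement is the unit of resolution: a sentence (or short span)
# that contains at least one NSS term and its candidate anchor(s).

#' Construct an annotated statement
#'
#' A statement bundles a tokenized text segment with pre-annotated entity
#' mentions (biological structures), syntactic relations (of-phrases and
#' possession phrases) and an optional gold map from NSS mention ids to their
#' annotated anchor names. Entities are kept in document order -- the queue
#' order that the rule engine iterates.
#'
#' @param id Statement id (string).
#' @param tokens Data frame with columns `index` (0-based, contiguous),
#'   `text`, and `sentence_index` (0-based, non-decreasing).
#' @param entities Data frame with columns `id`, `head_token`, `start`, `end`
#'   (token span, end exclusive), `name` (canonical lowercased term),
#'   `is_nss`, `is_subject`. May have zero rows.
#' @param relations Data frame with columns `kind` (`"of_phrase"` or
#'   `"possession"`), `dependent` (NSS-side mention id), `governor`
#'   (candidate-anchor-side mention id), `trigger` (surface string).
#' @param gold Optional named character vector: NSS mention id -> gold anchor
#'   name (compound names allowed, e.g. `"abdomen upper margin"`).
#' @param lexicon NSS lexicon used to check/derive the `is_nss` flags; when
#'   `entities$is_nss` is absent it is computed from this lexicon.
#' @return An object of class `nss_statement`.
#' @export
statement <- function(id, tokens, entities, relations = NULL, gold = NULL,
                      lexicon = nss_lexicon()) {
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  if (is.null(relations) || (is.data.frame(relations) && nrow(relations) == 0L)) {
    relations <- empty_relations()
  } else {
    relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  }
  flags_supplied <- nrow(entities) > 0L && !is.null(entities$is_nss)
  if (nrow(entities) > 0L) {
    entities$name <- tolower(entities$name)
    if (is.null(entities$is_nss)) {
      entities$is_nss <- is_nss_term(entities$name, lexicon)
    }
    entities <- entities[order(entities$head_token), , drop = FALSE]
    rownames(entities) <- NULL
    if (is.null(entities$is_subject)) {
      entities$is_subject <- seq_len(nrow(entities)) == 1L
    }
  } else {
    entities <- empty_entities()
  }
  for (col in c("index", "sentence_index")) tokens[[col]] <- as.integer(tokens[[col]])
  if (nrow(entities) > 0L) {
    for (col in c("head_token", "start", "end")) entities[[col]] <- as.integer(entities[[col]])
  }
  if (!is.null(gold)) {
    gold <- vapply(gold, as.character, character(1L))
  }
  st <- structure(
    list(id = as.character(id), tokens = tokens, entities = entities,
         relations = relations, gold = gold),
    class = "nss_statement"
  )
  # explicit flags record the producer's active lexicon and are trusted;
  # flags derived here must agree with the lexicon they came from
  validate_statement(st, lexicon = if (flags_supplied) NULL else lexicon)
  st
}

empty_entities <- function() {
  data.frame(id = character(), head_token = integer(), start = integer(),
             end = integer(), name = character(), is_nss = logical(),
             is_subject = logical(), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(kind = character(), dependent = character(),
             governor = character(), trigger = character(),
             stringsAsFactors = FALSE)
}

#' Validate a statement's invariants
#'
#' Checks token index contiguity, non-decreasing sentence indices, unique
#' mention ids, head-in-span, the single-subject rule, agreement of `is_nss`
#' with the active lexicon, relation endpoint validity, and that gold keys
#' refer to NSS mentions. Errors name the statement id and offending field.
#'
#' @param st An `nss_statement`.
#' @param lexicon Active NSS lexicon; `NULL` skips the lexicon-agreement check
#'   (used when a fixture carries a statement-specific lexicon).
#' @return Invisibly, `st`.
#' @export
validate_statement <- function(st, lexicon = NULL) {
  tk <- st$tokens
  en <- st$entities
  rl <- st$relations
  fail <- function(field, msg) {
    stop(sprintf("statement '%s', field '%s': %s", st$id, field, msg), call. = FALSE)
  }
  if (nrow(tk) > 0L) {
    if (!identical(tk$index, seq_len(nrow(tk)) - 1L)) {
      fail("tokens", "indices must be 0-based and contiguous")
    }
    if (is.unsorted(tk$sentence_index)) {
      fail("tokens", "sentence_index must be non-decreasing")
    }
  }
  if (nrow(en) > 0L) {
    if (anyDuplicated(en$id)) fail("entities", "duplicate mention ids")
    if (any(en$head_token < en$start | en$head_token >= en$end)) {
      fail("entities", "head_token must lie within [start, end)")
    }
    if (any(en$end > nrow(tk)) || any(en$start < 0L)) {
      fail("entities", "span outside token range")
    }
    if (sum(en$is_subject) != 1L) fail("entities", "exactly one subject required")
    if (!en$is_subject[1L]) fail("entities", "subject must be the first entity")
    if (is.unsorted(en$head_token)) {
      fail("entities", "entities must be ordered by head_token")
    }
    if (!is.null(lexicon)) {
      expect_nss <- is_nss_term(en$name, lexicon)
      if (!identical(unname(en$is_nss), unname(expect_nss))) {
        fail("entities", "is_nss flags disagree with active lexicon")
      }
    }
  }
  if (nrow(rl) > 0L) {
    if (!all(rl$kind %in% c("of_phrase", "possession"))) {
      fail("relations", "kind must be of_phrase or possession")
    }
    if (any(rl$dependent == rl$governor)) {
      fail("relations", "dependent and governor must differ")
    }
    unknown <- setdiff(c(rl$dependent, rl$governor), en$id)
    if (length(unknown) > 0L) {
      fail("relations", paste("unknown mention id(s):", paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(st$gold) && length(st$gold) > 0L) {
    bad <- setdiff(names(st$gold), en$id[en$is_nss])
    if (length(bad) > 0L) {
      fail("gold", paste("keys must be NSS mention ids; offending:",
                         paste(bad, collapse = ", ")))
    }
  }
  invisible(st)
}

#' @export
print.nss_statement <- function(x, ...) {
  cat(sprintf("<nss_statement '%s': %d tokens, %d entities (%d NSS), %d relations%s>\n",
              x$id, nrow(x$tokens), nrow(x$entities), sum(x$entities$is_nss),
              nrow(x$relations),
              if (!is.null(x$gold)) sprintf(", %d gold", length(x$gold)) else ""))
  cat(" ", paste(x$tokens$text, collapse = " "), "\n")
  invisible(x)
}

#' NSS mentions of a statement
#'
#' Returns exactly the entity mentions flagged as non-specific structures, in
#' queue (document) order -- the order in which the rule engine resolves them.
#'
#' @param st An `nss_statement`.
#' @return Data frame of entity rows with `is_nss = TRUE`.
#' @export
nss_mentions <- function(st) {
  stopifnot(inherits(st, "nss_statement"))
  out <- st$entities[st$entities$is_nss, , drop = FALSE]
  rownames(out) <- NULL
  out
}

entity_row <- function(st, id) {
  i <- match(id, st$entities$id)
  if (is.na(i)) stop("unknown mention id '", id, "' in statement '", st$id, "'")
  st$entities[i, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Readers / writers. JSON is the canonical on-disk format; a minimal XML
# dialect is supported for interoperability with annotation-tool exports.

statement_to_list <- function(st) {
  out <- list(
    id = st$id,
    tokens = lapply(seq_len(nrow(st$tokens)), function(i) {
      list(index = st$tokens$index[i], text = st$tokens$text[i],
           sentence_index = st$tokens$sentence_index[i])
    }),
    entities = lapply(seq_len(nrow(st$entities)), function(i) {
      e <- st$entities[i, ]
      list(id = e$id, head_token = e$head_token, start = e$start, end = e$end,
           name = e$name, is_nss = e$is_nss, is_subject = e$is_subject)
    }),
    relations = lapply(seq_len(nrow(st$relations)), function(i) {
      r <- st$relations[i, ]
      list(kind = r$kind, dependent = r$dependent, governor = r$governor,
           trigger = r$trigger)
    })
  )
  if (!is.null(st$gold)) out$gold <- as.list(st$gold)
  out
}

statement_from_list <- function(x, lexicon) {
  req <- function(item, field) {
    if (is.null(item[[field]])) {
      stop(sprintf("statement '%s', field '%s': missing", x$id %||% "<no id>", field),
           call. = FALSE)
    }
    item[[field]]
  }
  if (is.null(x$id)) stop("statement without id", call. = FALSE)
  tokens <- do.call(rbind, lapply(x$tokens, function(t) {
    data.frame(index = as.integer(req(t, "index")), text = as.character(req(t, "text")),
               sentence_index = as.integer(req(t, "sentence_index")),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tokens)) {
    tokens <- data.frame(index = integer(), text = character(),
                         sentence_index = integer(), stringsAsFactors = FALSE)
  }
  entities <- do.call(rbind, lapply(x$entities, function(e) {
    data.frame(id = as.character(req(e, "id")),
               head_token = as.integer(req(e, "head_token")),
               start = as.integer(req(e, "start")), end = as.integer(req(e, "end")),
               name = as.character(req(e, "name")),
               is_nss = if (is.null(e$is_nss)) NA else as.logical(e$is_nss),
               is_subject = if (is.null(e$is_subject)) NA else as.logical(e$is_subject),
               stringsAsFactors = FALSE)
  }))
  if (is.null(entities)) entities <- empty_entities()
  if (nrow(entities) > 0L && anyDuplicated(entities$id)) {
    stop(sprintf("statement '%s', field 'entities': duplicate mention ids", x$id),
         call. = FALSE)
  }
  if (nrow(entities) > 0L && anyNA(entities$is_nss)) entities$is_nss <- NULL
  if (nrow(entities) > 0L && !is.null(entities$is_subject) && anyNA(entities$is_subject)) {
    entities$is_subject <- NULL
  }
  relations <- do.call(rbind, lapply(x$relations, function(r) {
    data.frame(kind = as.character(req(r, "kind")),
               dependent = as.character(req(r, "dependent")),
               governor = as.character(req(r, "governor")),
               trigger = as.character(req(r, "trigger")), stringsAsFactors = FALSE)
  }))
  gold <- if (!is.null(x$gold) && length(x$gold) > 0L) {
    unlist(x$gold)
  } else NULL
  statement(x$id, tokens, entities, relations, gold, lexicon = lexicon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read annotated statements
#'
#' @param path Input file path.
#' @param format `"json"` (canonical) or `"xml"` (minimal annotation-export
#'   dialect).
#' @param lexicon NSS lexicon governing the `is_nss` flags.
#' @return List of `nss_statement` objects.
#' @export
read_statements <- function(path, format = c("json", "xml"),
                            lexicon = nss_lexicon()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$statements)) stop("not a statements document: ", path)
    lapply(doc$statements, statement_from_list, lexicon = lexicon)
  } else {
    read_statements_xml(path, lexicon)
  }
}

#' Write annotated statements
#'
#' Inverse of [read_statements()]: `read_statements(write_statements(x))`
#' reproduces `x` exactly.
#'
#' @param statements List of `nss_statement` objects.
#' @param path Output file path.
#' @param format `"json"` or `"xml"`.
#' @return Invisibly, `path`.
#' @export
write_statements <- function(statements, path, format = c("json", "xml")) {
  format <- match.arg(format)
  stopifnot(all(vapply(statements, inherits, logical(1L), "nss_statement")))
  if (format == "json") {
    doc <- list(statements = lapply(statements, statement_to_list))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    write_statements_xml(statements, path)
  }
  invisible(path)
}

read_statements_xml <- function(path, lexicon) {
  doc <- xml2::read_xml(path)
  lapply(xml2::xml_find_all(doc, ".//statement"), function(node) {
    toks <- xml2::xml_find_all(node, "./token")
    ents <- xml2::xml_find_all(node, "./entity")
    rels <- xml2::xml_find_all(node, "./relation")
    golds <- xml2::xml_find_all(node, "./gold")
    x <- list(
      id = xml2::xml_attr(node, "id"),
      tokens = lapply(toks, function(t) list(
        index = xml2::xml_attr(t, "i"), text = xml2::xml_text(t),
        sentence_index = xml2::xml_attr(t, "s"))),
      entities = lapply(ents, function(e) list(
        id = xml2::xml_attr(e, "id"), head_token = xml2::xml_attr(e, "head"),
        start = xml2::xml_attr(e, "start"), end = xml2::xml_attr(e, "end"),
        name = xml2::xml_attr(e, "name"),
        is_nss = as.logical(xml2::xml_attr(e, "nss")),
        is_subject = as.logical(xml2::xml_attr(e, "subject")))),
      relations = lapply(rels, function(r) list(
        kind = xml2::xml_attr(r, "kind"), dependent = xml2::xml_attr(r, "dependent"),
        governor = xml2::xml_attr(r, "governor"), trigger = xml2::xml_attr(r, "trigger")))
    )
    if (length(golds) > 0L) {
      g <- vapply(golds, function(n) xml2::xml_attr(n, "anchor"), character(1L))
      names(g) <- vapply(golds, function(n) xml2::xml_attr(n, "nss"), character(1L))
      x$gold <- as.list(g)
    }
    statement_from_list(x, lexicon)
  })
}

write_statements_xml <- function(statements, path) {
  doc <- xml2::xml_new_root("statements")
  for (st in statements) {
    node <- xml2::xml_add_child(doc, "statement", id = st$id)
    for (i in seq_len(nrow(st$tokens))) {
      xml2::xml_add_child(node, "token", st$tokens$text[i],
                          i = as.character(st$tokens$index[i]),
                          s = as.character(st$tokens$sentence_index[i]))
    }
    for (i in seq_len(nrow(st$entities))) {
      e <- st$entities[i, ]
      xml2::xml_add_child(node, "entity", id = e$id,
                          head = as.character(e$head_token),
                          start = as.character(e$start), end = as.character(e$end),
                          name = e$name, nss = tolower(as.character(e$is_nss)),
                          subject = tolower(as.character(e$is_subject)))
    }
    for (i in seq_len(nrow(st$relations))) {
      r <- st$relations[i, ]
      xml2::xml_add_child(node, "relation", kind = r$kind, dependent = r$dependent,
                          governor = r$governor, trigger = r$trigger)
    }
    if (!is.null(st$gold)) {
      for (nm in names(st$gold)) {
        xml2::xml_add_child(node, "gold", nss = nm, anchor = unname(st$gold[[nm]]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
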