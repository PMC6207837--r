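# Ontology-constrained syntactic rule engine. Rules are tried in decreasing
# order of confidence -- of-phrase, then possession words, then the sentence
# window -- and every candidate must additionally pass the soft part-of
# ontology check. A candidate that is itself an NSS triggers recursive
# resolution and compound anchor naming ("abdomen upper margin").

#' Rule engine configuration
#'
#' @param rule_order Rules in decreasing confidence order. Default
#'   `c("of_phrase", "possession", "window")`.
#' @param window_size Maximum number of sentence boundaries between an NSS
#'   and a window candidate, symmetric before/after (default 3).
#' @param possession_lexicon Trigger words accepted for the possession rule.
#' @param ontology_required When `TRUE` (default) every candidate must pass
#'   [may_be_part_of()] before it can anchor an NSS.
#' @param variant `"all_rules"` or `"ontology_only"`; the latter keeps only
#'   the window rule, i.e. resolution by the ontology and proximity alone.
#' @param candidate_order Tie order for window candidates: `"proximity"`
#'   (closest first, preceding preferred on ties; default) or `"document"`.
#' @param transitive_part_of Chain part_of edges transitively in ontology
#'   queries (default `FALSE`).
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(rule_order = c("of_phrase", "possession", "window"),
                        window_size = 3L,
                        possession_lexicon = c("with", "contain", "contains",
                                               "containing", "have", "has",
                                               "having"),
                        ontology_required = TRUE,
                        variant = c("all_rules", "ontology_only"),
                        candidate_order = c("proximity", "document"),
                        transitive_part_of = FALSE) {
  variant <- match.arg(variant)
  candidate_order <- match.arg(candidate_order)
  if (variant == "ontology_only") rule_order <- "window"
  stopifnot(length(rule_order) >= 1L,
            all(rule_order %in% c("of_phrase", "possession", "window")),
            window_size >= 1L)
  structure(
    list(rule_order = rule_order, window_size = as.integer(window_size),
         possession_lexicon = tolower(possession_lexicon),
         ontology_required = isTRUE(ontology_required), variant = variant,
         candidate_order = candidate_order,
         transitive_part_of = isTRUE(transitive_part_of)),
    class = "rule_config"
  )
}

sentence_of <- function(st, token_index) {
  st$tokens$sentence_index[token_index + 1L]
}

# Window candidates for a mention: all other entities within `window_size`
# sentence boundaries, ordered per config (no ontology filter here).
window_candidates <- function(st, mention_id, config) {
  en <- st$entities
  me <- entity_row(st, mention_id)
  others <- en[en$id != mention_id, , drop = FALSE]
  if (nrow(others) == 0L) return(character())
  sdist <- abs(sentence_of(st, others$head_token) - sentence_of(st, me$head_token))
  others <- others[sdist <= config$window_size, , drop = FALSE]
  if (nrow(others) == 0L) return(character())
  if (config$candidate_order == "proximity") {
    delta <- others$head_token - me$head_token
    # closest first; on equal distance the preceding entity wins
    ord <- order(abs(delta), delta)
    others <- others[ord, , drop = FALSE]
  }
  others$id
}

#' Candidate anchors for an NSS mention under one rule
#'
#' * `of_phrase`: governors of of-phrase relations whose dependent is the
#'   mention ("base of the leaves" yields `leaves`).
#' * `possession`: governors of possession relations whose trigger is in the
#'   possession lexicon ("abdomen has a thin edge" yields `abdomen`).
#' * `window`: every other entity within `window_size` sentence boundaries,
#'   closest first with preceding preferred on ties.
#'
#' When `config$ontology_required` is `TRUE` candidates failing the
#' [may_be_part_of()] check are removed.
#'
#' @param st An `nss_statement`.
#' @param mention_id Id of an NSS mention of `st`.
#' @param rule One of `"of_phrase"`, `"possession"`, `"window"`.
#' @param config A [rule_config()].
#' @param onto A `part_of_ontology` (used for the soft-constraint filter).
#' @return Character vector of candidate mention ids, in preference order.
#' @export
candidates_for <- function(st, mention_id, rule, config = rule_config(),
                           onto = NULL) {
  me <- entity_row(st, mention_id)
  if (!me$is_nss) stop("mention '", mention_id, "' is not an NSS mention")
  ids <- switch(
    rule,
    of_phrase = {
      rl <- st$relations
      rl$governor[rl$kind == "of_phrase" & rl$dependent == mention_id]
    },
    possession = {
      rl <- st$relations
      rl$governor[rl$kind == "possession" & rl$dependent == mention_id &
                    tolower(rl$trigger) %in% config$possession_lexicon]
    },
    window = window_candidates(st, mention_id, config),
    stop("unknown rule: ", rule)
  )
  ids <- ids[ids != mention_id]
  if (config$ontology_required && length(ids) > 0L) {
    if (is.null(onto)) stop("ontology required but not supplied")
    keep <- vapply(ids, function(cid) {
      may_be_part_of(onto, me$name, entity_row(st, cid)$name,
                     transitive = config$transitive_part_of)
    }, logical(1L))
    ids <- ids[keep]
  }
  unname(ids)
}

empty_resolutions <- function() {
  data.frame(statement_id = character(), nss_id = character(),
             nss_name = character(), anchor_id = character(),
             anchor_name = character(), method = character(),
             detail = character(), stringsAsFactors = FALSE)
}

resolution_row <- function(st, nss_id, anchor_id, anchor_name, method, detail) {
  data.frame(statement_id = st$id, nss_id = nss_id,
             nss_name = entity_row(st, nss_id)$name,
             anchor_id = anchor_id %||% NA_character_,
             anchor_name = anchor_name %||% NA_character_,
             method = method, detail = detail %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Resolve the NSS mentions of one statement with the rule engine
#'
#' Implements the confidence-ordered rule cascade with recursion. NSS
#' mentions are processed in queue (document) order. For each, rules are
#' tried in `config$rule_order`; the first candidate that satisfies the rule
#' and the ontology constraint wins. If the winning candidate is itself an
#' unresolved NSS, it is pushed onto a to-be-resolved stack and the cascade
#' re-runs for it; when a non-NSS anchor is finally found the stack unwinds,
#' assigning each popped NSS the accumulated compound anchor name (outermost
#' organ first: resolving *edge* -> *upper margin* -> *abdomen* yields
#' anchor names `"abdomen"` for *upper margin* and `"abdomen upper margin"`
#' for *edge*). An NSS resolved as part of such a chain is removed from the
#' work list. Cyclic chains leave every member unresolved, with a warning.
#' Unresolved mentions get an `NA` anchor.
#'
#' @param st An `nss_statement`.
#' @param onto A `part_of_ontology`.
#' @param config A [rule_config()].
#' @return Data frame of resolutions, one row per NSS mention in document
#'   order, with columns `statement_id`, `nss_id`, `nss_name`, `anchor_id`,
#'   `anchor_name`, `method` (`"rule"`) and `detail` (the rule that fired).
#' @export
resolve_statement <- function(st, onto, config = rule_config()) {
  stopifnot(inherits(st, "nss_statement"), inherits(onto, "part_of_ontology"))
  nss <- nss_mentions(st)
  out <- list()
  if (nrow(nss) == 0L) return(empty_resolutions())
  remaining <- nss$id
  anchors <- list()  # nss_id -> list(anchor_id, anchor_name, rule)

  full_name <- function(id) {
    # name used when a resolved NSS serves as someone else's anchor:
    # its own compound anchor name followed by its surface name
    if (!is.null(anchors[[id]]) && !is.na(anchors[[id]]$anchor_name)) {
      paste(anchors[[id]]$anchor_name, entity_row(st, id)$name)
    } else {
      entity_row(st, id)$name
    }
  }

  resolve_chain <- function(start_id) {
    stack <- start_id          # bottom -> top; top is the NSS being worked on
    direct <- list()           # nss_id -> chosen candidate id
    rules <- list()            # nss_id -> rule that fired
    repeat {
      current <- stack[length(stack)]
      found <- NULL
      for (rule in config$rule_order) {
        cands <- candidates_for(st, current, rule, config, onto)
        cands <- cands[!(cands %in% stack)]  # cycle guard
        if (length(cands) > 0L) {
          found <- list(id = cands[[1L]], rule = rule)
          break
        }
      }
      if (is.null(found)) {
        if (length(stack) > 1L) {
          warning(sprintf("statement '%s': unresolvable NSS chain [%s]",
                          st$id, paste(stack, collapse = " -> ")))
        }
        for (id in stack) {
          anchors[[id]] <<- list(anchor_id = NA_character_,
                                 anchor_name = NA_character_,
                                 rule = NA_character_)
          remaining <<- setdiff(remaining, id)
        }
        return(invisible())
      }
      direct[[current]] <- found$id
      rules[[current]] <- found$rule
      if (found$id %in% remaining) {
        # candidate is an unresolved NSS: push and re-run the cascade for it
        stack <- c(stack, found$id)
        next
      }
      # terminal anchor (a non-NSS entity, or an NSS already resolved
      # earlier, referenced by its compound name); unwind the stack
      term <- full_name(found$id)
      for (id in rev(stack)) {
        anchors[[id]] <<- list(anchor_id = direct[[id]], anchor_name = term,
                               rule = rules[[id]])
        remaining <<- setdiff(remaining, id)
        term <- paste(term, entity_row(st, id)$name)
      }
      return(invisible())
    }
  }

  for (id in nss$id) {
    if (id %in% remaining) resolve_chain(id)
  }
  rows <- lapply(nss$id, function(id) {
    a <- anchors[[id]]
    resolution_row(st, id, a$anchor_id, a$anchor_name, "rule", a$rule)
  })
  do.call(rbind, rows)
}

#' Resolve a corpus with the rule engine
#'
#' Applies [resolve_statement()] independently to each statement.
#'
#' @param statements List of `nss_statement` objects.
#' @param onto A `part_of_ontology`.
#' @param config A [rule_config()].
#' @return A single resolutions data frame (rows from all statements).
#' @export
resolve_corpus <- function(statements, onto, config = rule_config()) {
  rows <- lapply(statements, resolve_statement, onto = onto, config = config)
  out <- do.call(rbind, c(rows, list(empty_resolutions())))
  rownames(out) <- NULL
  out
}
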