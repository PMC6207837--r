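# Reference heuristics: always the subject entity, or always the closest
# entity. Neither consults relations or the ontology; both answer whenever an
# eligible entity exists, so under evaluation they have P = R = F1.

#' Subject-entity baseline
#'
#' Maps every NSS mention to the subject entity -- the first entity appearing
#' in the statement. An NSS that is itself the subject maps to the next
#' entity in document order, or to `NA` when none exists.
#'
#' @param st An `nss_statement`.
#' @return Resolutions data frame (see [resolve_statement()] for columns);
#'   `method` is `"baseline1"`.
#' @export
baseline_subject <- function(st) {
  stopifnot(inherits(st, "nss_statement"))
  nss <- nss_mentions(st)
  if (nrow(nss) == 0L) return(empty_resolutions())
  en <- st$entities
  rows <- lapply(nss$id, function(id) {
    pool <- en$id[en$id != id]
    anchor <- if (length(pool) > 0L) pool[[1L]] else NULL
    resolution_row(st, id, anchor,
                   if (!is.null(anchor)) entity_row(st, anchor)$name else NULL,
                   "baseline1", "subject")
  })
  do.call(rbind, rows)
}

#' Closest-entity baseline
#'
#' Maps every NSS mention to the entity (self excluded) minimizing the
#' absolute head-token distance; on ties the preceding entity wins. Entities
#' on both sides of the NSS are eligible.
#'
#' @param st An `nss_statement`.
#' @return Resolutions data frame; `method` is `"baseline2"`.
#' @export
baseline_closest <- function(st) {
  stopifnot(inherits(st, "nss_statement"))
  nss <- nss_mentions(st)
  if (nrow(nss) == 0L) return(empty_resolutions())
  en <- st$entities
  rows <- lapply(seq_len(nrow(nss)), function(i) {
    id <- nss$id[i]
    others <- en[en$id != id, , drop = FALSE]
    if (nrow(others) == 0L) {
      return(resolution_row(st, id, NULL, NULL, "baseline2", "closest"))
    }
    delta <- others$head_token - nss$head_token[i]
    pick <- others$id[order(abs(delta), delta)][1L]
    resolution_row(st, id, pick, entity_row(st, pick)$name, "baseline2", "closest")
  })
  do.call(rbind, rows)
}

#' Apply a baseline to a corpus
#'
#' @param statements List of `nss_statement` objects.
#' @param which `"baseline1"` (subject) or `"baseline2"` (closest).
#' @return Resolutions data frame over the whole corpus.
#' @export
baseline_corpus <- function(statements, which = c("baseline1", "baseline2")) {
  which <- match.arg(which)
  fn <- if (which == "baseline1") baseline_subject else baseline_closest
  out <- do.call(rbind, c(lapply(statements, fn), list(empty_resolutions())))
  rownames(out) <- NULL
  out
}
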