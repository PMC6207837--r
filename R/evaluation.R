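# Micro-averaged precision / recall / F1 over pooled NSS occurrences, and
# the pairwise error-overlap partition used to compare two methods.

canonical_anchor <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

# Gold table of a corpus: one row per gold-annotated NSS occurrence.
gold_table <- function(statements) {
  rows <- lapply(statements, function(st) {
    if (is.null(st$gold) || length(st$gold) == 0L) return(NULL)
    data.frame(statement_id = st$id, nss_id = names(st$gold),
               gold_name = canonical_anchor(unname(st$gold)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(statement_id = character(), nss_id = character(),
                      gold_name = character(), stringsAsFactors = FALSE)
  }
  out
}

# Correctness flags for each gold occurrence under a resolution set.
match_gold <- function(resolutions, gold) {
  key <- paste(gold$statement_id, gold$nss_id, sep = "\r")
  rkey <- paste(resolutions$statement_id, resolutions$nss_id, sep = "\r")
  i <- match(key, rkey)
  pred <- ifelse(is.na(i), NA_character_, resolutions$anchor_name[i])
  !is.na(pred) & canonical_anchor(pred) == gold$gold_name
}

#' Score resolutions against gold anchors
#'
#' Computes micro-averaged precision, recall and F1 over all pooled NSS
#' occurrences: with `S` the set of non-null system resolutions and `H` the
#' gold-annotated occurrences, `P = |S intersect H| / |S|`,
#' `R = |S intersect H| / |H|` and F1 their harmonic mean. A resolution is
#' correct when its final anchor name equals the gold anchor string after
#' canonicalization (lowercase, single-spaced); compound names must match
#' exactly. Null (abstained) resolutions are excluded from `S`, so a method
#' that abstains can keep precision above recall.
#'
#' @param resolutions Resolutions data frame (from any resolver).
#' @param statements The gold-annotated corpus the resolutions refer to.
#' @return An `nss_eval_report`: list with `n_gold`, `n_system`, `n_correct`,
#'   and `precision`, `recall`, `f1` as percentages.
#' @export
score <- function(resolutions, statements) {
  gold <- gold_table(statements)
  known <- unlist(lapply(statements, function(st) st$entities$id))
  ids <- unique(resolutions$nss_id)
  if (length(setdiff(ids, known)) > 0L) {
    stop("resolutions reference unknown mention id(s): ",
         paste(setdiff(ids, known), collapse = ", "))
  }
  sys <- resolutions[!is.na(resolutions$anchor_name), , drop = FALSE]
  n_gold <- nrow(gold)
  n_system <- nrow(sys)
  n_correct <- if (n_gold > 0L) sum(match_gold(sys, gold)) else 0L
  precision <- if (n_system > 0L) 100 * n_correct / n_system else 0
  recall <- if (n_gold > 0L) 100 * n_correct / n_gold else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(n_gold = n_gold, n_system = n_system, n_correct = n_correct,
                 precision = precision, recall = recall, f1 = f1),
            class = "nss_eval_report")
}

#' @export
print.nss_eval_report <- function(x, ...) {
  cat(sprintf("<nss_eval_report: |H| = %d, |S| = %d, correct = %d>\n",
              x$n_gold, x$n_system, x$n_correct))
  cat(sprintf("  P = %.1f%%  R = %.1f%%  F1 = %.1f%%\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Error overlap between two methods
#'
#' Partitions the gold NSS occurrences misresolved by at least one of two
#' methods into those wrong under A only, wrong under B only, and wrong under
#' both. An occurrence counts as a mistake for a method when it is either
#' unresolved or resolved to a non-gold anchor, so `errors_a_only +
#' errors_both` equals A's total mistake count (`|H| - n_correct` of A).
#'
#' @param resolutions_a,resolutions_b Resolution sets over the same corpus.
#' @param statements The gold-annotated corpus.
#' @return An `nss_overlap_report`: list with `errors_a_only`,
#'   `errors_b_only`, `errors_both`.
#' @export
error_overlap <- function(resolutions_a, resolutions_b, statements) {
  gold <- gold_table(statements)
  ok_a <- match_gold(resolutions_a, gold)
  ok_b <- match_gold(resolutions_b, gold)
  structure(list(
    errors_a_only = sum(!ok_a & ok_b),
    errors_b_only = sum(ok_a & !ok_b),
    errors_both = sum(!ok_a & !ok_b)
  ), class = "nss_overlap_report")
}

#' @export
print.nss_overlap_report <- function(x, ...) {
  cat(sprintf("<nss_overlap_report: A only = %d, B only = %d, both = %d>\n",
              x$errors_a_only, x$errors_b_only, x$errors_both))
  invisible(x)
}
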