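# Pairwise SVM relation classification. Every (candidate, NSS) pair within a
# statement is scored by a probability-estimating support vector machine and
# the anchor is the argmax candidate:
#   anchor(nss) = argmax_{x in X} Pr(x is the anchor of nss)
# with X all entity mentions of the statement except the NSS being resolved.
# The quadratic-programming solver is LIBSVM via e1071; the pairwise framing,
# feature extraction and anchor selection live here.

.connector_set <- c("in", "on", "at", "of", "has", "have", "with",
                    "contains", "without")

#' SVM configuration
#'
#' Defaults follow the settings tuned by 5-fold cross-validation for this
#' task: polynomial kernel of degree 3, class weight 7 on the positive
#' (true-anchor) class to counter the imbalance of the pairwise expansion,
#' bag-of-words vocabulary restricted to training tokens with frequency
#' >= 9, and a context window of 4 tokens on each side of each mention.
#'
#' @param kernel Kernel type (passed to the SVM backend); default
#'   `"polynomial"`.
#' @param degree Polynomial degree (default 3).
#' @param class_weight_positive Weight of the positive class (default 7).
#' @param word_freq_threshold Minimum training frequency for a token to enter
#'   the bag-of-words vocabulary (default 9).
#' @param context_window Tokens kept on each side of each mention for the
#'   bag-of-words features (default 4).
#' @param feature_groups Subset of `c(1, 2, 3)`: 1 = distance/position,
#'   2 = connectors + bag-of-words, 3 = semantic (ontology membership,
#'   anchor-is-NSS). Excluded groups are absent from the vector, not zeroed.
#' @param bow_counts Use token counts (`TRUE`, default) or binary indicators.
#' @param cv_folds Folds for [tune_svm()] (default 5).
#' @param random_seed Seed for all SVM-internal randomness (default 1).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = "polynomial", degree = 3L,
                       class_weight_positive = 7,
                       word_freq_threshold = 9L, context_window = 4L,
                       feature_groups = c(1L, 2L, 3L), bow_counts = TRUE,
                       cv_folds = 5L, random_seed = 1L) {
  stopifnot(degree >= 1L, word_freq_threshold >= 1L, context_window >= 0L,
            all(feature_groups %in% 1:3), length(feature_groups) >= 1L)
  structure(
    list(kernel = kernel, degree = as.integer(degree),
         class_weight_positive = class_weight_positive,
         word_freq_threshold = as.integer(word_freq_threshold),
         context_window = as.integer(context_window),
         feature_groups = sort(as.integer(feature_groups)),
         bow_counts = isTRUE(bow_counts), cv_folds = as.integer(cv_folds),
         random_seed = as.integer(random_seed)),
    class = "svm_config"
  )
}

#' Build the bag-of-words vocabulary from a training corpus
#'
#' Counts lowercased word tokens across all statements, drops the connector
#' words and non-alphabetic tokens, and keeps tokens whose frequency reaches
#' `config$word_freq_threshold`.
#'
#' @param statements Training statements.
#' @param config An [svm_config()].
#' @return Sorted character vector of vocabulary tokens.
#' @export
build_vocabulary <- function(statements, config = svm_config()) {
  toks <- tolower(unlist(lapply(statements, function(st) st$tokens$text)))
  toks <- toks[grepl("^[a-z]+$", toks) & !(toks %in% .connector_set)]
  tab <- table(toks)
  sort(names(tab)[tab >= config$word_freq_threshold])
}

svm_feature_names <- function(vocab, config) {
  nm <- character()
  if (1L %in% config$feature_groups) {
    nm <- c(nm, "is_subject", "is_closest", "abs_token_distance",
            "rel_token_distance", "abs_entities_between", "rel_entities_between")
  }
  if (2L %in% config$feature_groups) {
    nm <- c(nm, paste0("conn_", .connector_set), paste0("bow_", vocab, recycle0 = TRUE))
  }
  if (3L %in% config$feature_groups) {
    nm <- c(nm, "in_ontology", "anchor_is_nss")
  }
  nm
}

#' Feature vector for one (candidate, NSS) pair
#'
#' Three groups: (1) distance and position -- candidate-is-subject,
#' candidate-is-closest, absolute and relative token distance, absolute and
#' relative number of entities between the pair; (2) lexical -- one indicator
#' per connector word (`in, on, at, of, has, have, with, contains, without`)
#' occurring between the two mentions, plus bag-of-words counts of the tokens
#' within `context_window` positions around each mention (connectors
#' excluded, vocabulary fixed at training time); (3) semantic -- whether the
#' pair is licensed by the part-of ontology and whether the candidate is
#' itself an NSS.
#'
#' @param st An `nss_statement` (must have at least one token).
#' @param nss_id Id of the NSS mention being resolved.
#' @param cand_id Id of the candidate anchor mention (distinct from
#'   `nss_id`).
#' @param onto A `part_of_ontology` (only consulted for group 3).
#' @param vocab Trained vocabulary (see [build_vocabulary()]).
#' @param config An [svm_config()].
#' @return Named numeric vector with names `svm_feature_names()` order.
#' @export
pair_features <- function(st, nss_id, cand_id, onto, vocab,
                          config = svm_config()) {
  if (nrow(st$tokens) == 0L) stop("statement '", st$id, "' has no tokens")
  stopifnot(nss_id != cand_id)
  nssm <- entity_row(st, nss_id)
  cand <- entity_row(st, cand_id)
  en <- st$entities
  out <- numeric()

  if (1L %in% config$feature_groups) {
    others <- en[en$id != nss_id, , drop = FALSE]
    dmin <- min(abs(others$head_token - nssm$head_token))
    adist <- abs(cand$head_token - nssm$head_token)
    between <- sum(en$head_token > min(cand$head_token, nssm$head_token) &
                     en$head_token < max(cand$head_token, nssm$head_token))
    out <- c(out,
             is_subject = as.numeric(cand$is_subject),
             is_closest = as.numeric(adist == dmin),
             abs_token_distance = adist,
             rel_token_distance = adist / nrow(st$tokens),
             abs_entities_between = between,
             rel_entities_between = between / nrow(en))
  }
  if (2L %in% config$feature_groups) {
    lo <- if (cand$head_token < nssm$head_token) cand else nssm
    hi <- if (cand$head_token < nssm$head_token) nssm else cand
    gap <- if (lo$end <= hi$start) {
      tolower(st$tokens$text[seq_len(nrow(st$tokens)) - 1L >= lo$end &
                               seq_len(nrow(st$tokens)) - 1L < hi$start])
    } else character()
    conn <- as.numeric(.connector_set %in% gap)
    names(conn) <- paste0("conn_", .connector_set)
    ctx <- character()
    w <- config$context_window
    for (m in list(cand, nssm)) {
      before <- seq.int(m$start - w, length.out = w)
      after <- seq.int(m$end, length.out = w)
      idx <- c(before[before >= 0L], after[after < nrow(st$tokens)])
      ctx <- c(ctx, tolower(st$tokens$text[idx + 1L]))
    }
    ctx <- ctx[!(ctx %in% .connector_set)]
    bow <- vapply(vocab, function(v) sum(ctx == v), numeric(1L))
    if (!config$bow_counts) bow <- as.numeric(bow > 0)
    names(bow) <- paste0("bow_", vocab, recycle0 = TRUE)
    out <- c(out, conn, bow)
  }
  if (3L %in% config$feature_groups) {
    out <- c(out,
             in_ontology = as.numeric(may_be_part_of(onto, nssm$name, cand$name)),
             anchor_is_nss = as.numeric(cand$is_nss))
  }
  out
}

# All (candidate, NSS) pairs of a corpus as a feature matrix plus metadata.
pair_matrix <- function(statements, onto, vocab, config, with_labels = FALSE) {
  feats <- list(); meta <- list(); labels <- numeric()
  k <- 0L
  for (st in statements) {
    nss <- nss_mentions(st)
    for (i in seq_len(nrow(nss))) {
      nid <- nss$id[i]
      cands <- st$entities$id[st$entities$id != nid]
      gold_name <- if (with_labels) {
        if (!is.null(st$gold) && nid %in% names(st$gold)) {
          canonical_anchor(st$gold[[nid]])
        } else NA_character_
      }
      for (cid in cands) {
        k <- k + 1L
        feats[[k]] <- pair_features(st, nid, cid, onto, vocab, config)
        meta[[k]] <- data.frame(statement_id = st$id, nss_id = nid,
                                cand_id = cid, stringsAsFactors = FALSE)
        if (with_labels) {
          labels[k] <- as.numeric(
            !is.na(gold_name) &&
              canonical_anchor(entity_row(st, cid)$name) == gold_name)
        }
      }
    }
  }
  if (k == 0L) {
    return(list(x = matrix(numeric(), 0L, length(svm_feature_names(vocab, config)),
                           dimnames = list(NULL, svm_feature_names(vocab, config))),
                meta = data.frame(statement_id = character(), nss_id = character(),
                                  cand_id = character(), stringsAsFactors = FALSE),
                y = numeric()))
  }
  list(x = do.call(rbind, feats), meta = do.call(rbind, meta), y = labels)
}

#' Train the pairwise anchor classifier
#'
#' Expands every gold-annotated statement into (candidate, NSS) pairs -- one
#' positive pair per NSS (the candidate whose name matches the gold anchor)
#' and one negative pair for every other entity -- and fits a
#' probability-estimating SVM on the pair features. The positive class is
#' up-weighted by `config$class_weight_positive`. Training requires at least
#' one positive and one negative pair.
#'
#' @param statements Gold-annotated training statements.
#' @param onto A `part_of_ontology`.
#' @param config An [svm_config()].
#' @return An `nss_svm_model`: the fitted backend model plus the frozen
#'   vocabulary, configuration, feature-name layout and a fingerprint.
#' @export
train_svm <- function(statements, onto, config = svm_config()) {
  no_gold <- vapply(statements, function(st) is.null(st$gold) || length(st$gold) == 0L,
                    logical(1L))
  if (any(no_gold)) stop("all training statements must carry gold anchors")
  vocab <- build_vocabulary(statements, config)
  pm <- pair_matrix(statements, onto, vocab, config, with_labels = TRUE)
  if (length(unique(pm$y)) < 2L) {
    stop("training pairs contain a single class; need >= 1 positive and >= 1 negative")
  }
  y <- factor(pm$y, levels = c(0, 1))
  set.seed(config$random_seed)
  fit <- e1071::svm(x = pm$x, y = y, kernel = config$kernel,
                    degree = config$degree, probability = TRUE, scale = FALSE,
                    class.weights = c("0" = 1, "1" = config$class_weight_positive))
  fp_file <- tempfile()
  on.exit(unlink(fp_file))
  saveRDS(list(config = config, vocab = vocab), fp_file)
  structure(
    list(fit = fit, vocab = vocab, config = config,
         feature_names = svm_feature_names(vocab, config),
         fingerprint = unname(tools::md5sum(fp_file))),
    class = "nss_svm_model"
  )
}

#' @export
print.nss_svm_model <- function(x, ...) {
  cat(sprintf("<nss_svm_model: %s kernel deg %d, %d SVs, vocab %d, groups {%s}>\n",
              x$config$kernel, x$config$degree, x$fit$tot.nSV, length(x$vocab),
              paste(x$config$feature_groups, collapse = ",")))
  invisible(x)
}

pair_probabilities <- function(model, x) {
  pr <- stats::predict(model$fit, x, probability = TRUE)
  attr(pr, "probabilities")[, "1"]
}

#' Resolve NSS mentions with a trained pairwise SVM
#'
#' For each NSS mention the anchor is the candidate with the maximum
#' estimated probability among all entity mentions of the statement
#' (self excluded). Probability ties are broken by smaller token distance,
#' then by earlier document position. The SVM always answers when at least
#' one candidate exists; an NSS with no candidate gets an `NA` anchor with a
#' warning. When the predicted anchor is itself an NSS whose own anchor was
#' predicted, the reported anchor name is the compound chain name (outermost
#' organ first), mirroring the rule engine's naming.
#'
#' @param object An `nss_svm_model`.
#' @param statements An `nss_statement` or list thereof.
#' @param onto A `part_of_ontology`.
#' @param ... Unused.
#' @return Resolutions data frame; `method` is `"svm"`, `detail` holds the
#'   winning probability.
#' @export
predict.nss_svm_model <- function(object, statements, onto, ...) {
  if (inherits(statements, "nss_statement")) statements <- list(statements)
  out <- lapply(statements, function(st) svm_resolve_statement(object, st, onto))
  res <- do.call(rbind, c(out, list(empty_resolutions())))
  rownames(res) <- NULL
  res
}

svm_resolve_statement <- function(model, st, onto) {
  nss <- nss_mentions(st)
  if (nrow(nss) == 0L) return(empty_resolutions())
  pm <- pair_matrix(list(st), onto, model$vocab, model$config)
  probs <- if (nrow(pm$x) > 0L) pair_probabilities(model, pm$x) else numeric()
  picks <- list()  # nss_id -> list(cand_id, prob)
  for (i in seq_len(nrow(nss))) {
    nid <- nss$id[i]
    sel <- which(pm$meta$nss_id == nid)
    if (length(sel) == 0L) {
      warning(sprintf("statement '%s': NSS '%s' has no candidate anchors",
                      st$id, nid))
      picks[[nid]] <- NULL
      next
    }
    cid <- pm$meta$cand_id[sel]
    p <- probs[sel]
    dist <- abs(vapply(cid, function(id) entity_row(st, id)$head_token,
                       integer(1L)) - nss$head_token[i])
    pos <- match(cid, st$entities$id)
    best <- order(-p, dist, pos)[1L]
    picks[[nid]] <- list(cand_id = cid[best], prob = p[best])
  }
  # compound naming for chained-NSS anchors (cycle-safe)
  final_name <- function(id, seen = character()) {
    e <- entity_row(st, id)
    pk <- picks[[id]]
    if (!e$is_nss || is.null(pk) || id %in% seen) return(e$name)
    paste(final_name(pk$cand_id, c(seen, id)), e$name)
  }
  rows <- lapply(nss$id, function(nid) {
    pk <- picks[[nid]]
    if (is.null(pk)) {
      resolution_row(st, nid, NULL, NULL, "svm", NA_character_)
    } else {
      resolution_row(st, nid, pk$cand_id, final_name(pk$cand_id),
                     "svm", sprintf("p=%.6f", pk$prob))
    }
  })
  do.call(rbind, rows)
}

#' Save / load a trained model
#'
#' The model file is a self-describing bundle (fitted backend model,
#' vocabulary, configuration, fingerprint); reloading reproduces predictions
#' exactly.
#'
#' @param model An `nss_svm_model`.
#' @param path File path.
#' @return `save_svm_model`: invisibly, `path`. `load_svm_model`: the model.
#' @export
save_svm_model <- function(model, path) {
  stopifnot(inherits(model, "nss_svm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_svm_model
#' @export
load_svm_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "nss_svm_model")) stop("not an nss_svm_model file: ", path)
  model
}

#' Cross-validated degree selection
#'
#' Runs `config$cv_folds`-fold cross-validation over the statements for each
#' candidate polynomial degree and returns the configuration with the best
#' mean F1 (ties favour the smaller degree). Fold assignment and SVM
#' internals are seeded from `config$random_seed`, so the grid is
#' reproducible.
#'
#' @param statements Gold-annotated statements.
#' @param onto A `part_of_ontology`.
#' @param config Base [svm_config()].
#' @param degree_grid Degrees to try (default `c(2, 3, 4)`).
#' @return List with `best_config`, `best_degree` and `mean_f1` (named by
#'   degree).
#' @export
tune_svm <- function(statements, onto, config = svm_config(),
                     degree_grid = c(2L, 3L, 4L)) {
  n <- length(statements)
  stopifnot(n >= config$cv_folds)
  set.seed(config$random_seed)
  folds <- sample(rep(seq_len(config$cv_folds), length.out = n))
  mean_f1 <- vapply(degree_grid, function(d) {
    cfg <- config
    cfg$degree <- as.integer(d)
    f1s <- vapply(seq_len(config$cv_folds), function(k) {
      train <- statements[folds != k]
      test <- statements[folds == k]
      model <- train_svm(train, onto, cfg)
      score(predict(model, test, onto), test)$f1
    }, numeric(1L))
    mean(f1s)
  }, numeric(1L))
  names(mean_f1) <- degree_grid
  best <- degree_grid[which.max(mean_f1)]
  best_config <- config
  best_config$degree <- as.integer(best)
  list(best_config = best_config, best_degree = as.integer(best),
       mean_f1 = mean_f1)
}
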