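# Soft-constraint part-of ontologies. An edge (apex, part_of, leaf) asserts
# only that an apex COULD be part of a leaf -- the 'all some' rule of formal
# ontologies is deliberately not required, which is exactly why these
# resources can hold non-specific structure terms at all. Subclass edges
# (elytron side subclass_of side) let bare queries like (side, elytron)
# succeed through the compound term.

#' Construct a part-of ontology
#'
#' @param terms Character vector of canonical (lowercased) term strings.
#' @param part_of Data frame with columns `child`, `parent`: child could be
#'   part of parent. Edges must join distinct terms.
#' @param subclass_of Data frame with columns `sub`, `super`; must be acyclic.
#' @return An object of class `part_of_ontology`.
#' @export
part_of_ontology <- function(terms = character(),
                             part_of = NULL, subclass_of = NULL) {
  terms <- unique(tolower(terms))
  part_of <- normalize_edges(part_of, c("child", "parent"))
  subclass_of <- normalize_edges(subclass_of, c("sub", "super"))
  onto <- structure(
    list(terms = terms, part_of = part_of, subclass_of = subclass_of),
    class = "part_of_ontology"
  )
  validate_ontology(onto)
  onto
}

normalize_edges <- function(edges, cols) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L)) {
    out <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
    names(out) <- cols
    return(out)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- cols
  edges[] <- lapply(edges, tolower)
  edges <- unique(edges)
  rownames(edges) <- NULL
  edges
}

validate_ontology <- function(onto) {
  endpoints <- c(onto$part_of$child, onto$part_of$parent,
                 onto$subclass_of$sub, onto$subclass_of$super)
  missing <- setdiff(endpoints, onto$terms)
  if (length(missing) > 0L) {
    stop("ontology edge endpoints not in term set: ", paste(missing, collapse = ", "))
  }
  if (any(onto$part_of$child == onto$part_of$parent)) {
    stop("part_of edges must join distinct terms")
  }
  cyc <- find_subclass_cycle(onto$subclass_of)
  if (!is.null(cyc)) {
    stop("subclass_of cycle: ", paste(cyc, collapse = " -> "))
  }
  invisible(onto)
}

# DFS cycle detection over the sub -> super graph; returns one cycle or NULL.
find_subclass_cycle <- function(edges) {
  if (nrow(edges) == 0L) return(NULL)
  adj <- split(edges$super, edges$sub)
  color <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state <- mget(v, envir = color, ifnotfound = "white")[[1L]]
    if (state == "grey") {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (state == "black") return()
    assign(v, "grey", envir = color)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character()) visit(w)
    path <<- path[-length(path)]
    assign(v, "black", envir = color)
  }
  for (v in unique(edges$sub)) visit(v)
  found
}

#' @export
print.part_of_ontology <- function(x, ...) {
  cat(sprintf("<part_of_ontology: %d terms, %d part_of, %d subclass_of>\n",
              length(x$terms), nrow(x$part_of), nrow(x$subclass_of)))
  invisible(x)
}

#' Load a part-of ontology
#'
#' CSV rows are `child,relation,parent` with relation `part_of` or
#' `subclass_of`; terms are the union of all endpoints (a header row is
#' detected and skipped). The OBO-lite reader maps `is_a:` to subclass and
#' `relationship: part_of` to part-of, using `name:` lines as term strings.
#'
#' @param path Input file.
#' @param format `"csv"` or `"obo"`.
#' @return A `part_of_ontology`.
#' @export
load_ontology <- function(path, format = c("csv", "obo")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
      return(part_of_ontology())
    }
    df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("child", "relation", "parent"),
                          strip.white = TRUE)
    if (nrow(df) > 0L && identical(tolower(df$relation[1L]), "relation")) {
      df <- df[-1L, , drop = FALSE]
    }
    if (nrow(df) == 0L) return(part_of_ontology())
    df[] <- lapply(df, tolower)
    bad <- setdiff(unique(df$relation), c("part_of", "subclass_of"))
    if (length(bad) > 0L) {
      stop("unknown relation label(s): ", paste(bad, collapse = ", "))
    }
    part_of_ontology(
      terms = unique(c(df$child, df$parent)),
      part_of = df[df$relation == "part_of", c("child", "parent")],
      subclass_of = stats::setNames(
        df[df$relation == "subclass_of", c("child", "parent")], c("sub", "super"))
    )
  } else {
    load_obo_lite(path)
  }
}

load_obo_lite <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  terms <- character(); part_of <- list(); subclass <- list()
  id2name <- character(); current <- NULL
  pending <- list()  # edges by id, mapped to names at the end
  for (ln in lines) {
    if (ln == "[Term]") { current <- NULL; next }
    if (startsWith(ln, "id:")) { current <- trimws(sub("^id:", "", ln)); next }
    if (is.null(current)) next
    if (startsWith(ln, "name:")) {
      id2name[current] <- tolower(trimws(sub("^name:", "", ln)))
    } else if (startsWith(ln, "is_a:")) {
      target <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      pending[[length(pending) + 1L]] <- c("subclass_of", current, target)
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      target <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      pending[[length(pending) + 1L]] <- c("part_of", current, target)
    }
  }
  nm <- function(id) if (id %in% names(id2name)) id2name[[id]] else tolower(id)
  po <- do.call(rbind, Filter(Negate(is.null), lapply(pending, function(p) {
    if (p[1L] == "part_of") data.frame(child = nm(p[2L]), parent = nm(p[3L]),
                                       stringsAsFactors = FALSE)
  })))
  sc <- do.call(rbind, Filter(Negate(is.null), lapply(pending, function(p) {
    if (p[1L] == "subclass_of") data.frame(sub = nm(p[2L]), super = nm(p[3L]),
                                           stringsAsFactors = FALSE)
  })))
  part_of_ontology(
    terms = unique(c(unname(id2name), po$child, po$parent, sc$sub, sc$super)),
    part_of = po, subclass_of = sc
  )
}

#' Write an ontology as CSV
#'
#' Emits `child,relation,parent` rows. The CSV loader derives the term set
#' from edge endpoints, so the write/load round trip is exact whenever every
#' term occurs in at least one edge; isolated terms cannot be represented in
#' the edge-list format and are dropped with a warning.
#'
#' @param onto A `part_of_ontology`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ontology <- function(onto, path) {
  stopifnot(inherits(onto, "part_of_ontology"))
  used <- unique(c(onto$part_of$child, onto$part_of$parent,
                   onto$subclass_of$sub, onto$subclass_of$super))
  isolated <- setdiff(onto$terms, used)
  if (length(isolated) > 0L) {
    warning("isolated term(s) not representable in edge CSV: ",
            paste(isolated, collapse = ", "))
  }
  rows <- rbind(
    if (nrow(onto$part_of) > 0L)
      data.frame(child = onto$part_of$child, relation = "part_of",
                 parent = onto$part_of$parent, stringsAsFactors = FALSE),
    if (nrow(onto$subclass_of) > 0L)
      data.frame(child = onto$subclass_of$sub, relation = "subclass_of",
                 parent = onto$subclass_of$super, stringsAsFactors = FALSE)
  )
  if (is.null(rows)) {
    writeLines(character(), path)
  } else {
    utils::write.table(rows, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Canonical ontology name for a mention name: the name itself if present,
# else its head (last) word, else the singularized head word. Returns NA
# when nothing matches.
canonical_ontology_term <- function(onto, name) {
  name <- tolower(trimws(name))
  if (name %in% onto$terms) return(name)
  hw <- head_word(name)
  if (hw %in% onto$terms) return(hw)
  sg <- singularize(hw)
  if (sg %in% onto$terms) return(sg)
  NA_character_
}

# All subclasses of `term` (direct and transitive), term itself included.
subclass_closure <- function(onto, term) {
  out <- term
  frontier <- term
  repeat {
    nxt <- onto$subclass_of$sub[onto$subclass_of$super %in% frontier]
    nxt <- setdiff(nxt, out)
    if (length(nxt) == 0L) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Soft part-of query
#'
#' `may_be_part_of(onto, part, whole)` is `TRUE` when some term that is
#' `part` itself or a (transitive) subclass of it has a `part_of` edge to
#' some term that is `whole` itself or a (transitive) subclass of it. This is
#' the single-hop soft-constraint query used by both resolvers: for the
#' ontology fragment elytron side \eqn{\sqsubseteq} side, elytron side
#' part-of elytron, the query (side, elytron) succeeds through the compound
#' term. `part_of` edges are not chained transitively unless
#' `transitive = TRUE`. Names absent from the ontology fall back to their
#' head word and its singular form; if still absent the query is `FALSE`.
#'
#' @param onto A `part_of_ontology`.
#' @param part_name,whole_name Term names (canonicalized internally).
#' @param transitive Chain part_of edges transitively (default `FALSE`).
#' @return Logical scalar.
#' @export
#' @examples
#' o <- part_of_ontology(
#'   terms = c("elytron", "side", "elytron side"),
#'   part_of = data.frame(child = "elytron side", parent = "elytron"),
#'   subclass_of = data.frame(sub = "elytron side", super = "side"))
#' may_be_part_of(o, "side", "elytron")
may_be_part_of <- function(onto, part_name, whole_name, transitive = FALSE) {
  stopifnot(inherits(onto, "part_of_ontology"))
  p <- canonical_ontology_term(onto, part_name)
  w <- canonical_ontology_term(onto, whole_name)
  if (is.na(p) || is.na(w)) return(FALSE)
  if (p == w) return(FALSE)  # self-parthood never licensed
  parts <- subclass_closure(onto, p)
  wholes <- subclass_closure(onto, w)
  hit <- any(onto$part_of$child %in% parts & onto$part_of$parent %in% wholes)
  if (hit || !transitive) return(hit)
  # transitive variant: BFS over part_of, lifting each reached whole through
  # its subclass closure so edges anchored at subclasses keep the chain going
  seen <- parts
  frontier <- parts
  repeat {
    step <- unique(onto$part_of$parent[onto$part_of$child %in% frontier])
    step <- unique(unlist(lapply(step, function(t) subclass_closure(onto, t))))
    if (length(step) > 0L && any(step %in% wholes)) return(TRUE)
    step <- setdiff(step, seen)
    if (length(step) == 0L) return(FALSE)
    seen <- c(seen, step)
    frontier <- step
  }
}

#' Ontology size summary
#'
#' @param onto A `part_of_ontology`.
#' @return List with `n_structures` (unique terms) and `n_part_of`
#'   (part-of relationships).
#' @export
ontology_stats <- function(onto) {
  stopifnot(inherits(onto, "part_of_ontology"))
  list(n_structures = length(onto$terms), n_part_of = nrow(onto$part_of))
}
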