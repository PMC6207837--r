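# NSS lexicon: the configurable list of non-specific structure terms.

# Irregular plurals seen in anatomical vocabulary; extended as needed.
.irregular_plurals <- c(
  axes = "axis", apices = "apex", bases = "base", matrices = "matrix",
  bodies = "body", cavities = "cavity", concavities = "concavity",
  foramina = "foramen", leaves = "leaf", calyces = "calyx"
)

#' Load an NSS lexicon
#'
#' A non-specific structure (NSS) lexicon is a plain-text file with one term
#' per line (`#` comments and blank lines ignored). The packaged default holds
#' the 39 part terms -- "apex", "base", "margin", "side", "surface", ... --
#' that recur across taxon groups in morphological descriptions and that do
#' not denote an identifiable organ until linked to a parent.
#'
#' @param path Path to a lexicon file, or `NULL` for the packaged default.
#' @return A character vector of lowercased terms.
#' @export
#' @examples
#' lex <- nss_lexicon()
#' "margin" %in% lex
nss_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nss_terms.txt", package = "nssanchor")
  }
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  terms <- readLines(path, warn = FALSE)
  terms <- trimws(tolower(terms))
  terms <- terms[nzchar(terms) & !startsWith(terms, "#")]
  unique(terms)
}

#' Singularize a word with simple English rules
#'
#' Used when matching surface forms ("edges", "axes") against bare lexicon and
#' ontology terms ("edge", "axis"). Handles a small irregular table, then
#' `-ies` -> `-y`, `-ches/-shes/-sses/-xes/-zes` -> drop `es`, then drop a
#' trailing `s`. Returns the input unchanged when no rule applies.
#'
#' @param word A single lowercase word.
#' @return The singular form.
#' @export
singularize <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (word %in% names(.irregular_plurals)) {
    return(unname(.irregular_plurals[word]))
  }
  if (grepl("ies$", word) && nchar(word) > 4L) {
    return(sub("ies$", "y", word))
  }
  if (grepl("(ch|sh|ss|x|z)es$", word)) {
    return(sub("es$", "", word))
  }
  if (grepl("[^su]s$", word)) {
    return(sub("s$", "", word))
  }
  word
}

# Head word of a (possibly multi-word) entity name: the last token.
head_word <- function(name) {
  parts <- strsplit(trimws(name), "\\s+")[[1]]
  if (length(parts) == 0L) return("")
  parts[length(parts)]
}

#' Test whether an entity name is a non-specific structure term
#'
#' A name matches the lexicon when the full name, its head (last) word, or the
#' singularized head word is a lexicon entry. This is the canonical membership
#' relation used throughout the package: it makes "edges", "adaxial side" and
#' "epidermal cells" match the bare entries "edge", "side" and "cell".
#'
#' @param name Character vector of entity names (lowercased).
#' @param lexicon Character vector of lexicon terms (see [nss_lexicon()]).
#' @return Logical vector.
#' @export
#' @examples
#' is_nss_term(c("edges", "adaxial side", "leaflets"), nss_lexicon())
is_nss_term <- function(name, lexicon) {
  vapply(tolower(name), function(nm) {
    if (nm %in% lexicon) return(TRUE)
    hw <- head_word(nm)
    hw %in% lexicon || singularize(hw) %in% lexicon
  }, logical(1L), USE.NAMES = FALSE)
}
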