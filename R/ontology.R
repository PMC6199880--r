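#' Construct a concept
#'
#' Low-level constructor for the in-memory concept record.  Users normally
#' obtain concepts from [load_ontology()] or [generate_pair()].
#'
#' @param iri non-empty concept IRI.
#' @param labels character vector of `rdfs:label` values.
#' @param comments character vector of `rdfs:comment` values.
#' @param property_info data frame with columns `property`, `domain`,
#'   `range` holding the labels of properties whose domain is this class.
#' @param children character vector of IRIs of the direct subclasses.
#' @return a list of class `ccoem_concept`.
#' @export
new_concept <- function(iri, labels = character(), comments = character(),
                        property_info = empty_property_info(),
                        children = character()) {
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri))
  structure(list(iri = iri,
                 labels = as.character(labels),
                 comments = as.character(comments),
                 property_info = property_info,
                 children = as.character(children)),
            class = "ccoem_concept")
}

empty_property_info <- function() {
  data.frame(property = character(), domain = character(),
             range = character(), stringsAsFactors = FALSE)
}

#' Construct an ontology
#'
#' Validates and wraps a list of concepts: IRIs must be unique, every
#' child reference must point at a concept of the same ontology, and the
#' direct-subclass relation must be acyclic.
#'
#' @param id text identifier of the ontology.
#' @param concepts list of [new_concept()] records.
#' @return a list of class `ccoem_ontology` with fields `id`, `concepts`
#'   (named by IRI, insertion order preserved) and `concept_count`.
#' @export
new_ontology <- function(id, concepts) {
  iris <- vapply(concepts, function(co) co$iri, character(1))
  if (anyDuplicated(iris))
    stop("duplicate concept IRIs in ontology '", id, "'")
  names(concepts) <- iris
  for (co in concepts) {
    bad <- setdiff(co$children, iris)
    if (length(bad))
      stop("concept ", co$iri, " references children outside the ontology: ",
           paste(bad, collapse = ", "))
  }
  assert_acyclic(concepts, iris)
  structure(list(id = id, concepts = concepts,
                 concept_count = length(concepts)),
            class = "ccoem_ontology")
}

# Kahn peeling over the child relation; leftovers indicate a cycle.
assert_acyclic <- function(concepts, iris) {
  indeg <- stats::setNames(integer(length(iris)), iris)
  for (co in concepts)
    indeg[co$children] <- indeg[co$children] + 1L
  queue <- iris[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    ch <- concepts[[v]]$children
    indeg[ch] <- indeg[ch] - 1L
    queue <- c(queue, ch[indeg[ch] == 0L])
  }
  if (seen < length(iris))
    stop("subclass relation contains a cycle")
  invisible(TRUE)
}

#' @export
print.ccoem_ontology <- function(x, ...) {
  cat("<ccoem_ontology> ", x$id, ": ", x$concept_count, " concepts\n", sep = "")
  invisible(x)
}

#' @export
print.ccoem_concept <- function(x, ...) {
  cat("<concept> ", x$iri, "\n  labels: ",
      paste(x$labels, collapse = " | "),
      "\n  children: ", length(x$children), "\n", sep = "")
  invisible(x)
}

iri_fragment <- function(iri) {
  frag <- sub("^.*#", "", iri)
  if (identical(frag, iri)) frag <- sub("^.*/", "", iri)
  frag
}

#' Normalize a raw label into word tokens
#'
#' Lower-cases, splits on whitespace, underscores, hyphens and camel-case
#' boundaries, strips punctuation and drops empty tokens.  This is the
#' tokenizer feeding every concept profile, so word-level similarity is
#' always computed on its output.
#'
#' @param raw character vector of raw strings.
#' @return character vector of tokens (flattened over the inputs).
#' @examples
#' normalize_term("Cardiac_Muscle-Tissue")  # "cardiac" "muscle" "tissue"
#' normalize_term("NCI_C12727")             # "nci" "c12727"
#' @export
normalize_term <- function(raw) {
  if (!length(raw)) return(character())
  raw <- raw[!is.na(raw)]
  if (!length(raw)) return(character())
  # camel-case boundary -> space, then unify separators
  s <- gsub("(?<=[a-z0-9])(?=[A-Z])", " ", raw, perl = TRUE)
  s <- gsub("[_\\-]+", " ", s, perl = TRUE)
  toks <- unlist(strsplit(tolower(s), "[[:space:]]+"), use.names = FALSE)
  toks <- gsub("[^a-z0-9]", "", toks)
  toks[nzchar(toks)]
}

concept_own_terms <- function(concept) {
  src <- c(concept$labels, concept$comments)
  pi <- concept$property_info
  if (nrow(pi)) src <- c(src, pi$property, pi$domain, pi$range)
  if (!length(src)) src <- iri_fragment(concept$iri)
  normalize_term(src)
}

#' Build the profile of one concept
#'
#' A profile is the multiset of normalized word tokens harvested from a
#' concept's labels, comments and property information (property label,
#' domain label, range label), together with the same information from
#' each of its *direct* descendants.  Duplicated tokens are retained so
#' that the profile cardinality reflects information volume.
#'
#' @param ontology a `ccoem_ontology`.
#' @param concept a `ccoem_concept` belonging to `ontology`, or its IRI.
#' @return a list of class `ccoem_profile` with fields `concept_iri`,
#'   `terms` (character multiset) and `cardinality`.
#' @export
build_profile <- function(ontology, concept) {
  if (is.character(concept)) {
    concept <- ontology$concepts[[concept]]
    if (is.null(concept)) stop("concept not found in ontology")
  }
  if (is.null(ontology$concepts[[concept$iri]]))
    stop("concept ", concept$iri, " does not belong to ontology ", ontology$id)
  terms <- concept_own_terms(concept)
  for (ch in concept$children)
    terms <- c(terms, concept_own_terms(ontology$concepts[[ch]]))
  structure(list(concept_iri = concept$iri, terms = terms,
                 cardinality = length(terms)),
            class = "ccoem_profile")
}

#' Build all profiles of an ontology
#'
#' @param ontology a `ccoem_ontology`.
#' @return a named list (by IRI, in concept order) of `ccoem_profile`s.
#' @export
build_profiles <- function(ontology) {
  lapply(ontology$concepts, function(co) build_profile(ontology, co))
}
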