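RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"

#' Load an ontology from an OWL file
#'
#' Reads the named classes, their `rdfs:label`s and `rdfs:comment`s, the
#' asserted `rdfs:subClassOf` hierarchy, and the declared object/datatype
#' properties (label, domain, range — attached to the domain class) into
#' the internal ontology model.  Anonymous (blank-node) classes are
#' skipped with a warning; concepts without any label fall back to the
#' IRI local fragment so that every profile is non-empty.
#'
#' Two serializations are supported: RDF/XML (parsed with xml2) and a
#' pragmatic Turtle subset (`@prefix` declarations, `a owl:Class`,
#' predicate lists with `;`/`,`, plain literal objects) sufficient for
#' hand-written and generated fixtures.  No reasoning and no imports
#' closure is performed.
#'
#' @param path path to the OWL file.
#' @param format `"auto"` (by extension, default), `"rdfxml"` or
#'   `"turtle"`.
#' @param id ontology identifier; defaults to the file base name.
#' @return a `ccoem_ontology`.
#' @export
load_ontology <- function(path, format = c("auto", "rdfxml", "turtle"),
                          id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read ontology file: ", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (format == "auto") {
    format <- if (grepl("\\.(ttl|turtle|n3)$", path, ignore.case = TRUE))
      "turtle" else "rdfxml"
  }
  raw <- switch(format,
                rdfxml = parse_rdfxml(path),
                turtle = parse_turtle(path))
  build_ontology_from_triples(raw, id)
}

# Both parsers reduce the file to one flat triple table
# (subject, predicate, object, literal?) over full IRIs.
parse_rdfxml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable RDF/XML file: ",
                                           path, " (", conditionMessage(e), ")"))
  nodes <- xml2::xml_find_all(doc, "//*")
  subj <- character(); pred <- character(); obj <- character(); lit <- logical()
  n_blank <- 0L
  for (node in nodes) {
    full <- node_full_name(node)
    if (full %in% c(paste0(OWL_NS, "Class"),
                    paste0(OWL_NS, "ObjectProperty"),
                    paste0(OWL_NS, "DatatypeProperty"),
                    paste0(RDF_NS, "Description"))) {
      about <- xml2::xml_attr(node, "about")
      if (is.na(about))
        about <- xml2::xml_attr(node, "ID")
      if (is.na(about)) {
        if (full != paste0(RDF_NS, "Description")) n_blank <- n_blank + 1L
        next
      }
      if (full != paste0(RDF_NS, "Description")) {
        subj <- c(subj, about); pred <- c(pred, paste0(RDF_NS, "type"))
        obj <- c(obj, full); lit <- c(lit, FALSE)
      }
      for (child in xml2::xml_children(node)) {
        cfull <- node_full_name(child)
        res <- xml2::xml_attr(child, "resource")
        if (!is.na(res)) {
          subj <- c(subj, about); pred <- c(pred, cfull)
          obj <- c(obj, res); lit <- c(lit, FALSE)
        } else if (!length(xml2::xml_children(child))) {
          txt <- xml2::xml_text(child)
          subj <- c(subj, about); pred <- c(pred, cfull)
          obj <- c(obj, txt); lit <- c(lit, TRUE)
        }
        # nested anonymous nodes (e.g. owl:Restriction) are ignored
      }
    }
  }
  if (n_blank > 0L)
    warning(n_blank, " anonymous class/property node(s) skipped")
  data.frame(subject = subj, predicate = pred, object = obj,
             literal = lit, stringsAsFactors = FALSE)
}

node_full_name <- function(node) {
  ns <- xml2::xml_ns(node)
  qn <- xml2::xml_name(node, ns)
  if (grepl(":", qn, fixed = TRUE)) {
    parts <- strsplit(qn, ":", fixed = TRUE)[[1L]]
    uri <- unname(ns[parts[1L]])
    if (!is.na(uri)) return(paste0(uri, parts[2L]))
  }
  qn
}

# Minimal Turtle reader: prefixes, IRIs/<>, prefixed names, "literals",
# ';' and ',' separators.  Enough for simple class hierarchies.
parse_turtle <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  text <- paste(lines[!grepl("^[[:space:]]*#", lines)], collapse = "\n")
  prefixes <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS)
  for (m in regmatches(text, gregexpr(
    "@prefix[[:space:]]+([A-Za-z0-9_]*):[[:space:]]*<([^>]*)>[[:space:]]*\\.",
    text))[[1L]]) {
    p <- sub("@prefix[[:space:]]+([A-Za-z0-9_]*):.*", "\\1", m)
    u <- sub(".*<([^>]*)>.*", "\\1", m)
    prefixes[p] <- u
  }
  text <- gsub("@prefix[^.]*\\.", "", text)
  # tokenize: IRIs, literals, punctuation, names
  toks <- regmatches(text, gregexpr(
    '<[^>]*>|"(?:[^"\\\\]|\\\\.)*"(?:@[A-Za-z-]+|\\^\\^[^[:space:];,.]+)?|[;,.]|[^[:space:];,.]+',
    text))[[1L]]
  toks <- toks[nzchar(trimws(toks))]
  expand <- function(tok) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    if (tok == "a") return(paste0(RDF_NS, "type"))
    if (grepl("^[A-Za-z0-9_]*:", tok)) {
      p <- sub(":.*$", "", tok); loc <- sub("^[^:]*:", "", tok)
      if (!is.na(prefixes[p])) return(paste0(prefixes[p], loc))
    }
    tok
  }
  subj <- character(); pred <- character(); obj <- character(); lit <- logical()
  i <- 1L; cur_s <- NULL; cur_p <- NULL
  while (i <= length(toks)) {
    tok <- toks[[i]]
    if (tok == ".") { cur_s <- NULL; cur_p <- NULL; i <- i + 1L; next }
    if (tok == ";") { cur_p <- NULL; i <- i + 1L; next }
    if (tok == ",") { i <- i + 1L; next }
    if (is.null(cur_s)) { cur_s <- expand(tok); i <- i + 1L; next }
    if (is.null(cur_p)) { cur_p <- expand(tok); i <- i + 1L; next }
    if (startsWith(tok, "\"")) {
      val <- sub('^"((?:[^"\\\\]|\\\\.)*)".*$', "\\1", tok)
      val <- gsub('\\\\(["\\\\])', "\\1", val)
      subj <- c(subj, cur_s); pred <- c(pred, cur_p)
      obj <- c(obj, val); lit <- c(lit, TRUE)
    } else {
      subj <- c(subj, cur_s); pred <- c(pred, cur_p)
      obj <- c(obj, expand(tok)); lit <- c(lit, FALSE)
    }
    i <- i + 1L
  }
  data.frame(subject = subj, predicate = pred, object = obj,
             literal = lit, stringsAsFactors = FALSE)
}

build_ontology_from_triples <- function(tr, id) {
  type_p <- paste0(RDF_NS, "type")
  class_iris <- unique(tr$subject[tr$predicate == type_p &
                                    tr$object == paste0(OWL_NS, "Class")])
  if (!length(class_iris))
    stop("empty ontology: no named owl:Class declarations found")
  getp <- function(s, p, literal) {
    sel <- tr$subject == s & tr$predicate == p & tr$literal == literal
    tr$object[sel]
  }
  label_of <- function(iri) {
    if (iri %in% class_iris) {
      ll <- getp(iri, paste0(RDFS_NS, "label"), TRUE)
      if (length(ll)) return(ll[[1L]])
    }
    iri_fragment(iri)
  }
  # property declarations, attached to their domain class
  prop_iris <- unique(tr$subject[tr$predicate == type_p &
                                   tr$object %in% paste0(OWL_NS,
                                     c("ObjectProperty", "DatatypeProperty"))])
  prop_rows <- lapply(prop_iris, function(pi) {
    dom <- getp(pi, paste0(RDFS_NS, "domain"), FALSE)
    rng <- getp(pi, paste0(RDFS_NS, "range"), FALSE)
    if (!length(dom)) return(NULL)
    plab <- getp(pi, paste0(RDFS_NS, "label"), TRUE)
    plab <- if (length(plab)) plab[[1L]] else iri_fragment(pi)
    data.frame(class = dom[[1L]], property = plab,
               domain = label_of(dom[[1L]]),
               range = if (length(rng)) label_of(rng[[1L]]) else "",
               stringsAsFactors = FALSE)
  })
  prop_tab <- do.call(rbind, prop_rows)
  sub_p <- paste0(RDFS_NS, "subClassOf")
  concepts <- lapply(class_iris, function(iri) {
    labels <- getp(iri, paste0(RDFS_NS, "label"), TRUE)
    if (!length(labels)) labels <- iri_fragment(iri)
    comments <- getp(iri, paste0(RDFS_NS, "comment"), TRUE)
    kids <- tr$subject[tr$predicate == sub_p & !tr$literal & tr$object == iri]
    kids <- intersect(unique(kids), class_iris)
    pi <- if (!is.null(prop_tab)) prop_tab[prop_tab$class == iri, -1L,
                                           drop = FALSE] else NULL
    if (is.null(pi) || !nrow(pi)) pi <- empty_property_info()
    rownames(pi) <- NULL
    new_concept(iri, labels = labels, comments = comments,
                property_info = pi, children = kids)
  })
  new_ontology(id, concepts)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write an ontology as OWL RDF/XML
#'
#' Serializes the internal model back to RDF/XML: one `owl:Class` element
#' per concept with its labels, comments and `rdfs:subClassOf` links, and
#' one `owl:ObjectProperty` per property-info row.
#'
#' @param ontology a `ccoem_ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  parent_of <- list()
  for (co in ontology$concepts)
    for (ch in co$children) parent_of[[ch]] <- c(parent_of[[ch]], co$iri)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<rdf:RDF xmlns:rdf="%s" xmlns:rdfs="%s" xmlns:owl="%s">',
            RDF_NS, RDFS_NS, OWL_NS))
  k <- 0L
  for (co in ontology$concepts) {
    out <- c(out, sprintf('  <owl:Class rdf:about="%s">', xml_escape(co$iri)))
    for (l in co$labels)
      out <- c(out, sprintf('    <rdfs:label>%s</rdfs:label>', xml_escape(l)))
    for (cm in co$comments)
      out <- c(out, sprintf('    <rdfs:comment>%s</rdfs:comment>',
                            xml_escape(cm)))
    for (p in parent_of[[co$iri]])
      out <- c(out, sprintf('    <rdfs:subClassOf rdf:resource="%s"/>',
                            xml_escape(p)))
    out <- c(out, "  </owl:Class>")
    pi <- co$property_info
    if (nrow(pi)) {
      for (r in seq_len(nrow(pi))) {
        k <- k + 1L
        piri <- paste0(co$iri, "_prop", k)
        out <- c(out,
          sprintf('  <owl:ObjectProperty rdf:about="%s">', xml_escape(piri)),
          sprintf('    <rdfs:label>%s</rdfs:label>',
                  xml_escape(pi$property[r])),
          sprintf('    <rdfs:domain rdf:resource="%s"/>', xml_escape(co$iri)),
          "  </owl:ObjectProperty>")
      }
    }
  }
  out <- c(out, "</rdf:RDF>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
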