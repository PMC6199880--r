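#' Construct an alignment
#'
#' An alignment is a set of equivalence correspondences
#' `(source, target, confidence)`.  Within one decoded solution every
#' source IRI appears at most once (one gene segment per source concept).
#'
#' @param source,target character vectors of concept IRIs.
#' @param confidence numeric confidences in `[0, 1]` (default 1).
#' @return a data frame of class `ccoem_alignment`.
#' @export
new_alignment <- function(source = character(), target = character(),
                          confidence = rep(1, length(source))) {
  stopifnot(length(source) == length(target),
            length(source) == length(confidence),
            all(confidence >= 0), all(confidence <= 1))
  structure(data.frame(source = as.character(source),
                       target = as.character(target),
                       confidence = as.numeric(confidence),
                       stringsAsFactors = FALSE),
            class = c("ccoem_alignment", "data.frame"))
}

#' Filter a decoded solution into an alignment
#'
#' Emits one correspondence per source concept `i` mapped to target
#' `j = mapping[i] > 0` whose cached similarity passes the solution's own
#' threshold, with the similarity as confidence.  Zero-similarity pairs
#' are never emitted, even at threshold 0: a correspondence without any
#' lexical evidence would only game the coverage metric.
#'
#' @param sol a `ccoem_solution` from [decode_chromosome()].
#' @param sim a [similarity_matrix()] (rows = source, cols = target).
#' @param o1,o2 the ontologies (used for IRIs; dimensions must agree with
#'   `sim`).
#' @return a `ccoem_alignment`.
#' @export
decode_to_alignment <- function(sol, sim, o1, o2) {
  n1 <- nrow(sim); n2 <- ncol(sim)
  stopifnot(length(sol$mapping) == n1, all(sol$mapping <= n2))
  i <- which(sol$mapping > 0L)
  j <- sol$mapping[i]
  s <- sim[cbind(i, j)]
  keep <- s >= sol$threshold & s > 0
  new_alignment(rownames(sim)[i[keep]], colnames(sim)[j[keep]], s[keep])
}

#' MatchCoverage: the recall surrogate
#'
#' Fraction of all concepts (of both ontologies together) that take part
#' in at least one correspondence:
#' `(|C1_matched| + |C2_matched|) / (|C1| + |C2|)`.
#'
#' @param a a `ccoem_alignment`.
#' @param o1,o2 the matched ontologies (or their concept counts).
#' @return a number in `[0, 1]`.
#' @export
match_coverage <- function(a, o1, o2) {
  n1 <- if (is.numeric(o1)) o1 else o1$concept_count
  n2 <- if (is.numeric(o2)) o2 else o2$concept_count
  if (n1 + n2 == 0) stop("coverage undefined for empty ontologies")
  (length(unique(a$source)) + length(unique(a$target))) / (n1 + n2)
}

#' MatchRatio: the precision surrogate
#'
#' Distinct matched concepts divided by twice the correspondence count:
#' `(|C1_matched| + |C2_matched|) / (2 |A|)`; equal to 1 exactly when the
#' alignment is one-to-one, lower when concepts are reused.  Defined as 0
#' for an empty alignment.
#'
#' @param a a `ccoem_alignment`.
#' @return a number in `[0, 1]`.
#' @export
match_ratio <- function(a) {
  if (!nrow(a)) return(0)
  (length(unique(a$source)) + length(unique(a$target))) / (2 * nrow(a))
}

#' MatchFmeasure: harmonic mean of coverage and ratio
#'
#' @param coverage,ratio numbers in `[0, 1]`.
#' @return `2 c r / (c + r)`, or 0 when both are 0.
#' @export
match_fmeasure <- function(coverage, ratio) {
  if (coverage + ratio == 0) return(0)
  2 * coverage * ratio / (coverage + ratio)
}

#' All three rough metrics of an alignment
#'
#' @inheritParams match_coverage
#' @return a list with `match_coverage`, `match_ratio`, `match_fmeasure`.
#' @export
match_scores <- function(a, o1, o2) {
  cv <- match_coverage(a, o1, o2)
  rt <- match_ratio(a)
  list(match_coverage = cv, match_ratio = rt,
       match_fmeasure = match_fmeasure(cv, rt))
}

#' Precision / recall / f-measure against a reference alignment
#'
#' Correspondence identity is the `(source, target)` pair; confidences
#' are ignored (reference alignments carry uniform confidence).  An empty
#' candidate alignment has precision 1 by convention.
#'
#' @param a candidate `ccoem_alignment`.
#' @param ref non-empty reference `ccoem_alignment`.
#' @return a list with `precision`, `recall`, `fmeasure`.
#' @export
reference_scores <- function(a, ref) {
  if (!nrow(ref)) stop("reference alignment is empty")
  key <- function(x) paste(x$source, x$target, sep = "\r")
  overlap <- sum(key(a) %in% key(ref))
  precision <- if (nrow(a)) overlap / nrow(a) else 1
  recall <- overlap / nrow(ref)
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, fmeasure = f)
}

ALIGN_NS <- "http://knowledgeweb.semanticweb.org/heterogeneity/alignment"

#' Write an alignment
#'
#' `format = "rdf"` emits the OAEI Alignment format (RDF/XML with one
#' `Cell` per correspondence carrying `entity1`, `entity2`, `measure` and
#' relation `=`); `format = "tsv"` emits three tab-separated columns
#' without a header.
#'
#' @param a a `ccoem_alignment`.
#' @param path output path.
#' @param format `"rdf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path, format = c("rdf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(a, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<rdf:RDF xmlns="%s#" xmlns:rdf="%s" xmlns:xsd="http://www.w3.org/2001/XMLSchema#">',
            ALIGN_NS, RDF_NS),
    "  <Alignment>",
    "    <xml>yes</xml>",
    "    <level>0</level>",
    "    <type>11</type>")
  for (k in seq_len(nrow(a))) {
    out <- c(out,
      "    <map>",
      "      <Cell>",
      sprintf('        <entity1 rdf:resource="%s"/>', xml_escape(a$source[k])),
      sprintf('        <entity2 rdf:resource="%s"/>', xml_escape(a$target[k])),
      sprintf('        <measure rdf:datatype="xsd:float">%s</measure>',
              format(a$confidence[k], digits = 10)),
      "        <relation>=</relation>",
      "      </Cell>",
      "    </map>")
  }
  out <- c(out, "  </Alignment>", "</rdf:RDF>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read an alignment
#'
#' Accepts the OAEI Alignment RDF format or a 3-column (or 2-column,
#' confidence defaulting to 1) TSV.
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"rdf"` or `"tsv"`.
#' @return a `ccoem_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "rdf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(tsv|txt|csv)$", path, ignore.case = TRUE))
      "tsv" else "rdf"
  if (format == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    conf <- if (ncol(tab) >= 3L) as.numeric(tab[[3L]]) else rep(1, nrow(tab))
    return(new_alignment(tab[[1L]], tab[[2L]], conf))
  }
  doc <- xml2::read_xml(path)
  cells <- xml2::xml_find_all(doc, "//*[local-name() = 'Cell']")
  src <- character(length(cells)); tgt <- character(length(cells))
  conf <- numeric(length(cells))
  for (k in seq_along(cells)) {
    e1 <- xml2::xml_find_first(cells[[k]], ".//*[local-name() = 'entity1']")
    e2 <- xml2::xml_find_first(cells[[k]], ".//*[local-name() = 'entity2']")
    ms <- xml2::xml_find_first(cells[[k]], ".//*[local-name() = 'measure']")
    src[k] <- xml2::xml_attr(e1, "resource")
    tgt[k] <- xml2::xml_attr(e2, "resource")
    conf[k] <- if (inherits(ms, "xml_missing")) 1
               else as.numeric(xml2::xml_text(ms))
  }
  new_alignment(src, tgt, conf)
}
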