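test_that("normalize_term splits, lowercases and strips as specified", {
  expect_equal(normalize_term("Cardiac_Muscle-Tissue"),
               c("cardiac", "muscle", "tissue"))
  expect_equal(normalize_term("NCI_C12727"), c("nci", "c12727"))
  expect_equal(normalize_term(""), character())
  expect_equal(normalize_term("MyocardialWall"), c("myocardial", "wall"))
  expect_equal(normalize_term("  a,b  (c) "), c("ab", "c"))
})

test_that("profiles collect the concept and its direct descendants only", {
  ns <- "urn:x#"
  o <- new_ontology(ns, list(
    new_concept(paste0(ns, "root"), labels = "Cardiac Muscle Tissue"),
    new_concept(paste0(ns, "myo"), labels = "Myocardium",
                children = paste0(ns, "wall")),
    new_concept(paste0(ns, "wall"), labels = "Myocardial Wall",
                children = paste0(ns, "gc")),
    new_concept(paste0(ns, "gc"), labels = "Deep Leaf")))
  p_root <- build_profile(o, paste0(ns, "root"))
  expect_setequal(p_root$terms, c("cardiac", "muscle", "tissue"))
  expect_equal(p_root$cardinality, 3L)
  # concept + direct child, not the grandchild
  p_myo <- build_profile(o, paste0(ns, "myo"))
  expect_setequal(p_myo$terms, c("myocardium", "myocardial", "wall"))
  # deleting the grandchild leaves the profile unchanged
  o2 <- new_ontology(ns, list(
    new_concept(paste0(ns, "root"), labels = "Cardiac Muscle Tissue"),
    new_concept(paste0(ns, "myo"), labels = "Myocardium",
                children = paste0(ns, "wall")),
    new_concept(paste0(ns, "wall"), labels = "Myocardial Wall")))
  expect_equal(build_profile(o2, paste0(ns, "myo"))$terms, p_myo$terms)
})

test_that("uniform fixtures give the hand-counted profile cardinality", {
  # every concept: one 2-token label and (for internal nodes) 2 children
  ns <- "urn:y#"
  mk <- function(i, kids = character())
    new_concept(paste0(ns, i), labels = paste("Word", i), children = kids)
  o <- new_ontology(ns, list(
    mk("a", paste0(ns, c("b", "c"))), mk("b"), mk("c")))
  expect_equal(build_profile(o, paste0(ns, "a"))$cardinality, 6L)
  # duplicates are retained in the multiset
  o_dup <- new_ontology(ns, list(
    mk2 <- new_concept(paste0(ns, "a"), labels = "Same Same")))
  expect_equal(build_profile(o_dup, paste0(ns, "a"))$terms,
               c("same", "same"))
})

test_that("ontology invariants are enforced", {
  ns <- "urn:z#"
  expect_error(new_ontology(ns, list(
    new_concept(paste0(ns, "a")), new_concept(paste0(ns, "a")))),
    "duplicate")
  expect_error(new_ontology(ns, list(
    new_concept(paste0(ns, "a"), children = paste0(ns, "ghost")))),
    "outside")
  expect_error(new_ontology(ns, list(
    new_concept(paste0(ns, "a"), children = paste0(ns, "b")),
    new_concept(paste0(ns, "b"), children = paste0(ns, "a")))),
    "cycle")
})

test_that("RDF/XML loading reads classes, hierarchy, labels and properties", {
  o <- load_ontology(extdata("cardiac-src.owl"))
  expect_equal(o$concept_count, 3L)
  heart <- o$concepts[["http://example.org/human#Heart"]]
  expect_setequal(heart$children,
                  paste0("http://example.org/human#",
                         c("Myocardium", "MitralValve")))
  expect_equal(heart$labels, "Heart")
  expect_equal(heart$property_info$property, "has part")
  expect_equal(heart$property_info$range, "Mitral Valve")
  myo <- o$concepts[["http://example.org/human#Myocardium"]]
  expect_equal(myo$comments, "Muscle Tissue")
})

test_that("the Turtle subset reader agrees with the RDF/XML reader", {
  a <- load_ontology(extdata("cardiac-src.owl"))
  b <- load_ontology(extdata("cardiac-src.ttl"), format = "turtle")
  pick <- function(o) lapply(o$concepts, function(co)
    co[c("iri", "labels", "comments", "children")])
  expect_equal(pick(b)[names(pick(a))], pick(a))
})

test_that("label-less concepts fall back to the IRI fragment", {
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '  xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Class rdf:about="http://x.org/onto#NCI_C12727"/>',
    "</rdf:RDF>"), f)
  o <- load_ontology(f)
  co <- o$concepts[[1L]]
  expect_equal(co$labels, "NCI_C12727")
  expect_equal(build_profile(o, co)$terms, c("nci", "c12727"))
})

test_that("unreadable and empty files raise their specified errors", {
  expect_error(load_ontology(file.path(tempdir(), "nope.owl")),
               "cannot read")
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines(c(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"/>'), f)
  expect_error(load_ontology(f), "empty ontology")
  g <- withr::local_tempfile(fileext = ".owl")
  writeLines("this is not xml <", g)
  expect_error(load_ontology(g), "unreadable")
})

test_that("anonymous classes are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines(c(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '  xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Class rdf:about="http://x.org/o#A"/>',
    "  <owl:Class/>",
    "</rdf:RDF>"), f)
  expect_warning(o <- load_ontology(f), "anonymous")
  expect_equal(o$concept_count, 1L)
})

test_that("loading is deterministic and round-trips the generator model", {
  pair <- generate_pair(12, seed = 11, synonym_rename_fraction = 0.2)
  dir <- withr::local_tempdir()
  paths <- write_fixture(pair, dir)
  a <- load_ontology(paths[["o1"]])
  b <- load_ontology(paths[["o1"]])
  expect_identical(a$concepts, b$concepts)
  expect_setequal(names(a$concepts), names(pair$o1$concepts))
  for (iri in names(a$concepts)) {
    expect_equal(a$concepts[[iri]]$labels, pair$o1$concepts[[iri]]$labels)
    expect_setequal(a$concepts[[iri]]$children,
                    pair$o1$concepts[[iri]]$children)
  }
  # identical profile outputs, concept by concept
  expect_equal(lapply(build_profiles(a)[names(pair$o1$concepts)],
                      function(p) sort(p$terms)),
               lapply(build_profiles(pair$o1), function(p) sort(p$terms)))
})
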