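mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = "P", source_db = r[[4]], accession = r[[3]],
               description = "", start = r[[1]], end = r[[2]],
               e_value = 1e-6, stringsAsFactors = FALSE)
  }))
}

mk_bir_calls <- function(types, starts, star = FALSE) {
  data.frame(protein_id = "P", bir_index = seq_along(types),
             start = starts, end = starts + 100L, bir_type = types,
             bir_star = rep_len(star, length(types)),
             stringsAsFactors = FALSE)
}

test_that("tokenization orders tokens N->C and substitutes BIR types", {
  hits <- mk_hits(list(10L, 110L, "cd00022", "CDD"),
                  list(120L, 200L, "G3DSA:1.10.533.10", "GENE3D"),
                  list(300L, 340L, "IPR013083", "INTERPRO"))
  bc <- mk_bir_calls("TypeII", 10L)
  expect_equal(tokenize_architecture(hits, bc), c("TII", "DD", "RING"))
})

test_that("overlapping same-category hits merge into one token", {
  hits <- mk_hits(list(300L, 340L, "IPR013083", "INTERPRO"),
                  list(310L, 355L, "IPR001841", "SMART"))
  expect_equal(tokenize_architecture(hits, NULL), "RING")
})

test_that("unmapped accessions become OTHER and BIR calls need evidence", {
  hits <- mk_hits(list(10L, 60L, "IPR999999", "INTERPRO"))
  expect_equal(tokenize_architecture(hits, NULL), "OTHER")
  bc <- mk_bir_calls("TypeII", 500L)
  expect_error(tokenize_architecture(hits, bc), "covering")
})

test_that("token order equals a brute-force interval-merge oracle", {
  toks <- c("RING", "DD", "UBA", "UBC", "WD40")
  accs <- c(RING = "IPR013083", DD = "G3DSA:1.10.533.10",
            UBA = "IPR015940", UBC = "IPR000608", WD40 = "IPR019775")
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    start <- sort(sample(seq(0L, 900L, by = 10L), n))
    len <- sample(40:120, n, TRUE)
    tok <- sample(toks, n, TRUE)
    hits <- data.frame(protein_id = "P", source_db = "X",
                       accession = accs[tok], description = "",
                       start = start, end = start + len,
                       e_value = 1e-6, stringsAsFactors = FALSE)
    got <- tokenize_architecture(hits, NULL)
    want <- oracle_token_order(data.frame(start = start,
                                          end = start + len,
                                          token = tok,
                                          stringsAsFactors = FALSE))
    expect_equal(got, want)
  }
})

test_that("rule table matches the textually defined architectures", {
  expect_equal(classify_architecture(c("TII", "DD")), "BIRC10")
  expect_equal(classify_architecture(c("TII", "DD", "RING")), "BIRC11")
  expect_equal(classify_architecture(c("BIR_STAR", "DD", "RING")),
               "BIRC11")
  expect_equal(classify_architecture(c("TII", "RING")), "BIRC7-like")
  expect_equal(classify_architecture(c("TI", "TII", "DD", "RING")),
               "BIRC2/3-like")
  expect_equal(classify_architecture(c("TI", "TII", "DD", "UBA", "RING")),
               "BIRC2/3-like")
  expect_equal(classify_architecture(c("NZBIR", "TII", "UBA", "DD",
                                       "RING")), "BIRC2/3-like")
  expect_equal(classify_architecture(c("TII")), "BIRC5-like")
  expect_equal(classify_architecture(c("TI")), "BIRC5-like")
  expect_equal(classify_architecture(c("TII", "TII", "BIRC6_DOMAIN",
                                       "UBC")), "BIRC6-like")
  expect_equal(classify_architecture(c("TII", "TII", "BIRC6_DOMAIN",
                                       "UBC", "WD40")), "BIRC6-like")
  expect_equal(classify_architecture(c("TX", "TX", "WD40")), "NOVEL")
})

test_that("matching ignores OTHER tokens and is order-sensitive", {
  expect_equal(classify_architecture(c("TII", "OTHER", "DD")), "BIRC10")
  expect_equal(classify_architecture(c("DD", "TII")), "NOVEL")
  expect_equal(classify_architecture(rev(c("TII", "DD", "RING"))),
               "NOVEL")
})

# a 6-leaf tree with one well-supported mixed-species clade
demo_tree <- function(sup_inner = 95) {
  p <- tempfile(fileext = ".nwk")
  writeLines(sprintf(
    "(((CvP1:1,CgP2:1)%d:1,CvP3:1)40:1,(CgP4:1,CvP5:1)50:1,CgP6:1);",
    sup_inner), p)
  read_newick(p)
}

demo_species <- c(CvP1 = "Cv", CvP3 = "Cv", CvP5 = "Cv",
                  CgP2 = "Cg", CgP4 = "Cg", CgP6 = "Cg")

test_that("supported clusters need support > 90 and both species", {
  cl <- extract_supported_clusters(demo_tree(95), demo_species)
  expect_length(cl, 1L)
  expect_equal(sort(cl[[1]]$members), c("CgP2", "CvP1"))
  expect_equal(cl[[1]]$support, 95)
  expect_length(extract_supported_clusters(demo_tree(85), demo_species),
                0L)
  expect_error(extract_supported_clusters(demo_tree(95),
                                          demo_species[-1]),
               "unlabelled")
})

test_that("cluster extraction matches exhaustive clade enumeration", {
  set.seed(41)
  for (rep in 1:10) {
    ntip <- sample(8:14, 1)
    tr <- ape::rtree(ntip, tip.label = sprintf("t%02d", seq_len(ntip)))
    tr$node.support <- sample(c(NA, 50, 80, 91, 99), tr$Nnode, TRUE)
    sp <- setNames(sample(c("Cv", "Cg"), ntip, TRUE), tr$tip.label)
    got <- extract_supported_clusters(tr, sp)
    want <- oracle_clusters(tr, sp, 90, c("Cv", "Cg"))
    got_sets <- lapply(got, function(cl) sort(cl$members))
    expect_equal(length(got_sets), length(want))
    expect_true(all(got_sets %in% want))
    # disjoint leaf sets
    all_members <- unlist(got_sets)
    expect_equal(anyDuplicated(all_members), 0L)
  }
})

test_that("cluster consensus distinguishes conserved, mixed, and ties", {
  calls <- c(a = "BIRC10", b = "BIRC10", c = "BIRC10", d = "NOVEL",
             e = "BIRC11", f = "BIRC11")
  allsame <- cluster_consensus(c("a", "b", "c"), calls)
  expect_equal(allsame$consensus, "BIRC10")
  expect_true(allsame$conserved)
  maj <- cluster_consensus(c("a", "b", "c", "d"), calls)
  expect_equal(maj$consensus, "BIRC10")
  expect_true(maj$mixed)
  tie <- cluster_consensus(c("a", "b", "e", "f"), calls)
  expect_equal(tie$consensus, "BIRC10/BIRC11")
  expect_true(tie$mixed)
  expect_error(cluster_consensus(character(0), calls), "empty")
})
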