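scan_with_hits <- function() {
  data.frame(
    protein_id = c("P1", "P2", "P3", "P3"),
    source_db = c("CDD", "CDD", "PFAM", "INTERPRO"),
    accession = c("cd00022", "cd00022", "PF00653", "IPR001370"),
    description = c("BIR repeat", "BIR repeat", "BIR repeat (Pfam)",
                    "BIR-like"),
    start = c(10L, 10L, 10L, 10L), end = c(110L, 110L, 110L, 110L),
    e_value = 1e-8, stringsAsFactors = FALSE)
}

test_that("candidate filter applies the E-value cut and CDD confirmation", {
  hmm <- data.frame(protein_id = c("P1", "P2", "P3"),
                    e_value = c(1e-5, 0.01, 1e-8))
  kept <- filter_iap_candidates(hmm, scan_with_hits())
  expect_true("P1" %in% kept)        # passes both rules
  expect_false("P2" %in% kept)       # E-value 0.01 >= 0.001
  expect_false("P3" %in% kept)       # BIR evidence not from CDD
})

test_that("candidates absent from the scan are dropped with a message", {
  hmm <- data.frame(protein_id = c("P1", "P9"), e_value = c(1e-5, 1e-9))
  expect_message(kept <- filter_iap_candidates(hmm, scan_with_hits()),
                 "absent")
  expect_equal(kept, "P1")
})

test_that("identical collapse keeps one representative per sequence", {
  recs <- data.frame(id = c("c", "a", "b"),
                     residues = c("MKL", "MKL", "AAA"),
                     stringsAsFactors = FALSE)
  res <- collapse_identical(recs)
  expect_equal(sort(res$kept$id), c("a", "b"))
  expect_equal(unname(res$map["c"]), "a")  # lexicographically smallest
  distinct <- data.frame(id = c("x", "y"), residues = c("MK", "ML"),
                         stringsAsFactors = FALSE)
  expect_equal(unname(collapse_identical(distinct)$map), c("x", "y"))
})

test_that("identical collapse matches a hash-set oracle on 158 records", {
  set.seed(42)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- replicate(84, paste(sample(aa, 40, TRUE), collapse = ""))
  # 74 duplicates of the first 74 distinct sequences -> 158 records
  residues <- c(base, base[1:74])
  recs <- data.frame(id = sprintf("t%03d", seq_along(residues)),
                     residues = residues, stringsAsFactors = FALSE)
  res <- collapse_identical(recs)
  expect_equal(nrow(res$kept), length(unique(residues)))
  expect_equal(sort(unique(res$map)), sort(res$kept$id))
})

test_that("collapse is idempotent", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  recs <- data.frame(
    id = sprintf("p%02d", 1:20),
    residues = sample(replicate(8, paste(sample(aa, 30, TRUE),
                                         collapse = "")), 20, TRUE),
    stringsAsFactors = FALSE)
  once <- collapse_identical(recs)
  twice <- collapse_identical(once$kept)
  expect_equal(twice$kept, once$kept)
  expect_true(all(twice$map == names(twice$map)))
})

haplotig_fixture <- function(identity, cov) {
  recs <- data.frame(id = c("pA", "pB"), residues = c("M", "M"),
                     stringsAsFactors = FALSE)
  pim <- matrix(c(1, identity, identity, 1), 2, 2,
                dimnames = list(recs$id, recs$id))
  list(recs = recs, pim = pim, cov = setNames(cov, recs$id))
}

test_that("haplotig collapse removes low-coverage high-identity members", {
  fx <- haplotig_fixture(0.96, c(10, 30))
  res <- collapse_haplotigs(fx$recs, fx$pim, fx$cov)
  expect_equal(res$kept$id, "pB")
  expect_equal(unname(res$map["pA"]), "pB")
})

test_that("haplotig collapse respects identity and coverage boundaries", {
  # below the identity threshold: untouched
  fx <- haplotig_fixture(0.90, c(10, 30))
  expect_equal(nrow(collapse_haplotigs(fx$recs, fx$pim, fx$cov)$kept), 2L)
  # exactly half coverage is NOT "< half": both kept
  fx <- haplotig_fixture(0.96, c(15, 30))
  expect_equal(nrow(collapse_haplotigs(fx$recs, fx$pim, fx$cov)$kept), 2L)
  # just under half: removed
  fx <- haplotig_fixture(0.96, c(14.9, 30))
  expect_equal(collapse_haplotigs(fx$recs, fx$pim, fx$cov)$kept$id, "pB")
})

test_that("haplotig collapse errors on missing coverage", {
  fx <- haplotig_fixture(0.96, c(10, NA))
  expect_error(collapse_haplotigs(fx$recs, fx$pim, fx$cov), "coverage")
})

test_that("haplotig count merging conserves totals", {
  counts <- matrix(rpois(12, 50), 4, 3,
                   dimnames = list(c("pA", "pB", "pC", "pD"), NULL))
  map <- c(pA = "pB", pB = "pB", pC = "pC", pD = "pD")
  merged <- merge_haplotig_counts(counts, map)
  expect_equal(sum(merged), sum(counts))
  expect_equal(merged["pB", ], counts["pA", ] + counts["pB", ])
  expect_false("pA" %in% rownames(merged))
})

test_that("single-exon rule flags intronless genes at the gene level", {
  genes <- read_gff3(write_toy_gff3())
  expect_equal(detect_intronless(genes), c(geneB = "geneB"),
               ignore_attr = TRUE)
  # a gene with one single-exon isoform and one spliced isoform is not
  # intronless
  mixed <- c("##gff-version 3",
             "chr1\tsrc\tgene\t1\t900\t.\t+\t.\tID=g1",
             "chr1\tsrc\tmRNA\t1\t900\t.\t+\t.\tID=g1.t1;Parent=g1",
             "chr1\tsrc\texon\t1\t900\t.\t+\t.\tParent=g1.t1",
             "chr1\tsrc\tmRNA\t1\t900\t.\t+\t.\tID=g1.t2;Parent=g1",
             "chr1\tsrc\texon\t1\t300\t.\t+\t.\tParent=g1.t2",
             "chr1\tsrc\texon\t501\t900\t.\t+\t.\tParent=g1.t2")
  expect_length(detect_intronless(read_gff3(write_toy_gff3(mixed))), 0L)
})

test_that("tandem arrays require adjacency within the configured limits", {
  go <- make_gene_order(sprintf("g%02d", 1:9))
  # three adjacent IAP genes form one array
  arr <- detect_tandem_arrays(go, c("g01", "g02", "g03"))
  expect_equal(sort(arr$gene_id), c("g01", "g02", "g03"))
  expect_equal(length(unique(arr$tandem_array_id)), 1L)
  # five intervening non-IAP genes break the default limit of 2
  arr2 <- detect_tandem_arrays(go, c("g01", "g07"))
  expect_equal(nrow(arr2), 0L)
  # a large genomic gap breaks an otherwise adjacent pair
  far <- make_gene_order(c("g01", "g02"), gap = 500000L)
  expect_equal(nrow(detect_tandem_arrays(far, c("g01", "g02"))), 0L)
})

test_that("tandem arrays match exhaustive run enumeration on random data", {
  set.seed(11)
  cfg <- curation_config()
  for (rep in 1:10) {
    n <- 30L
    go <- make_gene_order(sprintf("r%02d", 1:n),
                          gap = sample(c(1000L, 300000L), 1))
    # random subset of positions are IAP genes
    iap <- sample(go$gene_id, sample(5:15, 1))
    got <- detect_tandem_arrays(go, iap, cfg)
    runs <- oracle_tandem_runs(go, iap, cfg$tandem_max_intervening,
                               cfg$tandem_max_gap_bp)
    expect_equal(sort(got$gene_id),
                 sort(as.character(unlist(runs))))
    expect_equal(length(unique(got$tandem_array_id)), length(runs))
  }
})

test_that("retroposition flags fire on the configured accessions", {
  scan <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    protein_id = paste0("g", 1:3, ".t1"),
    source_db = "INTERPRO",
    accession = c("IPR002492", "IPR000477", "IPR999999"),
    description = c("Transposase Tc1-like", "RT domain", "other"),
    start = 0L, end = 50L, e_value = 1e-6, stringsAsFactors = FALSE)
  fl <- flag_retroposition(scan)
  expect_true(fl$transposase_tc1[fl$gene_id == "g1"])
  expect_false(fl$reverse_transcriptase[fl$gene_id == "g1"])
  expect_true(fl$reverse_transcriptase[fl$gene_id == "g2"])
  expect_false(any(unlist(fl[fl$gene_id == "g3", -1])))
})

test_that("RCD mining matches aliases as whole words, case-insensitive", {
  ann <- data.frame(
    gene_id = c("L1", "L2", "L3"),
    transcript_id = c("L1.t1", "L2.t1", "L3.t1"),
    product = c("caspase 3-like protein", "uncharacterized protein LOC1",
                "RAIFX homolog"),
    stringsAsFactors = FALSE)
  catalog <- list("caspase 3" = c("caspase 3", "CASP3"),
                  "AIF" = c("AIF"))
  hits <- mine_rcd_annotations(ann, catalog)
  expect_equal(hits$transcript_id, "L1.t1")
  expect_equal(hits$alias, "caspase 3")
  expect_false("L3.t1" %in% hits$transcript_id)  # AIF inside RAIFX
  expect_error(mine_rcd_annotations(ann, list()), "empty")
})
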