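# BIR typing: residue rules, reference anchoring, conserved-position
# census.

kr <- function(..., del = FALSE) {
  v <- c(...)
  key_residues(setNames(as.character(v), names(v)),
               deletion_span_over_80 = del)
}

test_that("classify_bir implements each residue rule", {
  cases <- list(
    list(kr("76" = "E", "77" = "H", "80" = "W", "84" = "C", "57" = "C"),
         "TypeII"),
    list(kr("76" = "Q", "77" = "H", "80" = "H", "84" = "C", "57" = "C"),
         "TypeII"),
    list(kr("77" = "H", "80" = "V", "84" = "C", "57" = "C", "76" = "A"),
         "TypeI"),
    list(kr("77" = "H", "80" = "L", "84" = "C", "57" = "C", "76" = "A"),
         "TypeI"),
    list(kr("57" = "T", "76" = "E", "77" = "H", "80" = "W", "84" = "C"),
         "NZBIR"),
    list(kr("80" = "G", "82" = "R", "77" = "H", "84" = "C", "57" = "C",
            "76" = "A"), "TypeX"),
    list(kr("77" = "H", "84" = "C", "57" = "C", "76" = "A", del = TRUE),
         "TypeY"),
    list(kr("80" = "I", "81" = "S", "77" = "H", "84" = "C", "57" = "C",
            "76" = "A"), "TypeI_like"),
    list(kr("81" = "S", "80" = "A", "77" = "H", "84" = "C", "57" = "C",
            "76" = "A"), "TypeI_like"),
    list(kr("76" = "E", "77" = "H", "80" = "A", "84" = "C", "57" = "C"),
         "TypeII_like"),
    list(kr("76" = "A", "77" = "A", "80" = "A", "84" = "A", "57" = "C"),
         "Unclassified"))
  for (cs in cases) expect_equal(classify_bir(cs[[1]]), cs[[2]])
})

test_that("novel-type diagnostics take precedence over conserved rules", {
  # T57 wins even over a perfect Type II pattern
  k <- kr("57" = "T", "76" = "E", "77" = "H", "80" = "W", "84" = "C")
  expect_equal(classify_bir(k), "NZBIR")
  # deletion over 80 wins over everything but NZBIR
  k2 <- kr("57" = "C", "76" = "E", "77" = "H", "84" = "C", del = TRUE)
  expect_equal(classify_bir(k2), "TypeY")
  # precedence is overridable
  expect_equal(classify_bir(k, precedence = c("TypeII", "NZBIR")),
               "TypeII")
})

test_that("anchoring a bundled reference sequence gives the identity map", {
  ref <- load_bir_reference()
  q <- ref$alignment[[1]]
  anc <- anchor_to_reference(q, ref)
  expect_equal(anc$canonical_to_query, seq_len(nchar(q)))
  expect_equal(anc$query_to_canonical, seq_len(nchar(q)))
})

test_that("anchoring is invariant to flanking extensions up to 30", {
  ref <- load_bir_reference()
  core <- gen_bir("TypeII", n_flank = 0, seed = 3)$residues
  anc0 <- anchor_to_reference(core, ref)
  k0 <- extract_key_residues(core, anc0, ref)
  for (fl in c(5L, 30L)) {
    b <- gen_bir("TypeII", n_flank = fl, seed = 3)
    anc <- anchor_to_reference(b$residues, ref)
    k <- extract_key_residues(b$residues, anc, ref)
    expect_equal(k$residues, k0$residues)
    expect_equal(classify_bir(k), "TypeII")
  }
})

test_that("a 3-residue deletion over position 80 is reported as gaps", {
  ref <- load_bir_reference()
  q <- gen_bir("TypeY", seed = 5)$residues  # backbone minus 79:81
  anc <- anchor_to_reference(q, ref)
  k <- extract_key_residues(q, anc, ref)
  expect_equal(unname(k$residues["80"]), "-")
  expect_true(k$deletion_span_over_80)
  expect_equal(sum(is.na(anc$canonical_to_query)), 3L)
})

test_that("non-BIR sequences fail anchoring with an Unanchorable error", {
  ref <- load_bir_reference()
  junk <- paste(rep("PG", 60), collapse = "")
  expect_error(anchor_to_reference(junk, ref), "Unanchorable")
  expect_error(anchor_to_reference("ACDEF", ref), "short")
})

test_that("anchoring agrees with an independent dynamic-programming
          oracle on mutated references", {
  ref <- load_bir_reference()
  blosum <- blosum62_oracle()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(17)
  for (rep in 1:10) {
    q <- strsplit(ref$consensus, "")[[1]]
    mut <- sample(seq_along(q), 8)
    q[mut] <- vapply(q[mut], function(r) sample(setdiff(aa, r), 1), "")
    q <- paste(q, collapse = "")
    anc <- anchor_to_reference(q, ref)
    oracle <- oracle_global_map(ref$consensus, q, blosum)
    expect_equal(anc$query_to_canonical, oracle)
  }
})

test_that("synthetic BIRs of every type recover their planted type", {
  ref <- load_bir_reference()
  types <- c("TypeI", "TypeII", "TypeI_like", "TypeII_like", "TypeX",
             "TypeY", "NZBIR")
  for (ty in types) {
    for (s in 1:5) {
      b <- gen_bir(ty, n_flank = 8, n_mutations_nonkey = 0, seed = s)
      anc <- anchor_to_reference(b$residues, ref)
      k <- extract_key_residues(b$residues, anc, ref)
      expect_equal(classify_bir(k), ty)
    }
  }
})

test_that("census reports positions with one shared non-gap residue", {
  ref <- load_bir_reference()
  anc <- function(q) extract_key_residues(
    q, anchor_to_reference(q, ref), ref)
  same <- replicate(3, anc(ref$consensus), simplify = FALSE)
  expect_equal(census_conserved_positions(same, ref$conserved_positions),
               ref$conserved_positions)
  # construct inputs agreeing only at 34, 60, 77, 84
  keep <- c(34, 60, 77, 84)
  k1 <- anc(ref$consensus)
  k2 <- k1
  vary <- setdiff(ref$conserved_positions, keep)
  k2$residues[as.character(vary)] <- "A"
  expect_equal(census_conserved_positions(list(k1, k2),
                                          ref$conserved_positions), keep)
})

test_that("census equals a brute-force column scan and ignores order", {
  set.seed(23)
  positions <- c(10, 20, 30)
  calls <- lapply(1:6, function(i) {
    key_residues(setNames(sample(c("A", "C", "-"), 3, TRUE),
                          as.character(positions)))
  })
  got <- census_conserved_positions(calls, positions)
  brute <- positions[vapply(as.character(positions), function(p) {
    col <- vapply(calls, function(k) unname(k$residues[p]), "")
    length(unique(col)) == 1 && col[1] != "-"
  }, logical(1))]
  expect_equal(got, brute)
  perm <- census_conserved_positions(rev(calls), positions)
  expect_equal(perm, got)
})
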