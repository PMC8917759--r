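# Small in-code fixtures shared across test files.

write_toy_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

toy_gff3 <- function() {
  c("##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=geneA",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tParent=geneA.t1",
    "chr1\tsrc\texon\t1301\t1500\t.\t+\t.\tParent=geneA.t1",
    "chr1\tsrc\texon\t1701\t2000\t.\t+\t.\tParent=geneA.t1",
    "chr1\tsrc\tgene\t3001\t3500\t.\t-\t.\tID=geneB",
    "chr1\tsrc\tmRNA\t3001\t3500\t.\t-\t.\tID=geneB.t1;Parent=geneB",
    "chr1\tsrc\texon\t3001\t3500\t.\t-\t.\tParent=geneB.t1")
}

write_toy_gff3 <- function(lines = toy_gff3()) {
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

toy_scan_table <- function() {
  c("protein_id\tsource_db\taccession\tdescription\tstart\tend\te_value",
    "P1\tCDD\tcd00022\tBIR repeat\t150\t250\t1e-10",
    "P1\tPFAM\tPF00653\tBIR repeat (Pfam)\t10\t100\t1e-8",
    "P2\tINTERPRO\tIPR013083\tRING finger\t5\t60\t-")
}

write_toy_scan <- function(lines = toy_scan_table()) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# a small gene-order table for tandem tests
make_gene_order <- function(ids, chrom = "chr1", gene_len = 2000L,
                            gap = 1000L) {
  starts <- seq(0L, by = gene_len + gap, length.out = length(ids))
  data.frame(gene_id = ids, chromosome = chrom, start = starts,
             end = starts + gene_len, stringsAsFactors = FALSE)
}
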