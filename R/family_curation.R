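# Curation of an IAP gene set from HMM and domain-scan evidence:
# candidate filtering, duplicate and haplotig collapse, and the
# intronless / tandem-array / retroposition flags used to reason about
# gene-family expansion mechanisms.

#' Curation thresholds
#'
#' @param hmm_evalue_max HMM hit E-value ceiling for IAP candidates
#'   (candidates must score strictly below; default 0.001).
#' @param haplotig_identity_min Pairwise identity above which proteins
#'   cluster for haplotig inspection (default 0.95).
#' @param haplotig_coverage_ratio A cluster member is removed as a
#'   suspected haplotig when its read coverage is strictly below this
#'   fraction of the cluster maximum (default 0.5).
#' @param tandem_max_intervening Maximum number of non-IAP genes allowed
#'   between consecutive members of a tandem array (default 2).
#' @param tandem_max_gap_bp Maximum genomic gap between consecutive
#'   array members, in bp (default 200000).
#' @return A `curation_config` list.
#' @export
curation_config <- function(hmm_evalue_max = 0.001,
                            haplotig_identity_min = 0.95,
                            haplotig_coverage_ratio = 0.5,
                            tandem_max_intervening = 2L,
                            tandem_max_gap_bp = 200000L) {
  stopifnot(hmm_evalue_max > 0,
            haplotig_identity_min > 0, haplotig_identity_min <= 1,
            haplotig_coverage_ratio > 0, haplotig_coverage_ratio <= 1,
            tandem_max_intervening >= 0, tandem_max_gap_bp > 0)
  structure(list(hmm_evalue_max = hmm_evalue_max,
                 haplotig_identity_min = haplotig_identity_min,
                 haplotig_coverage_ratio = haplotig_coverage_ratio,
                 tandem_max_intervening = as.integer(tandem_max_intervening),
                 tandem_max_gap_bp = as.integer(tandem_max_gap_bp)),
            class = "curation_config")
}

#' Default accessions accepted as BIR-domain evidence
#' @return Character vector of CDD/Pfam BIR accessions.
#' @export
bir_scan_accessions <- function() {
  c("cd00022", "PF00653", "IPR001370", "SM00238")
}

# BIR-domain evidence: a configured accession, or a description naming
# the BIR repeat as a whole word (so BIRC6-domain hits do not match).
is_bir_hit <- function(scan, bir_accessions = bir_scan_accessions()) {
  scan$accession %in% bir_accessions |
    grepl("\\bBIR\\b|baculoviral iap repeat", scan$description,
          ignore.case = TRUE)
}

#' Filter IAP candidates by HMM E-value and CDD BIR confirmation
#'
#' A candidate is retained iff its HMM hit E-value is strictly below the
#' threshold AND the domain scan contains at least one BIR hit from the
#' CDD source for that protein. Candidates absent from the scan are
#' treated as lacking CDD confirmation and dropped (with a message).
#'
#' @param hmm_hits data.frame with columns `protein_id`, `e_value`.
#' @param scan Domain-scan hits (see [read_domain_scan()]).
#' @param cfg A [curation_config()].
#' @param bir_accessions Accessions counted as BIR evidence; see
#'   [bir_scan_accessions()].
#' @return Character vector of retained protein ids.
#' @export
filter_iap_candidates <- function(hmm_hits, scan, cfg = curation_config(),
                                  bir_accessions =
                                    bir_scan_accessions()) {
  stopifnot(all(c("protein_id", "e_value") %in% names(hmm_hits)))
  pass_e <- hmm_hits$protein_id[hmm_hits$e_value < cfg$hmm_evalue_max]
  is_bir <- is_bir_hit(scan, bir_accessions)
  cdd_bir <- unique(scan$protein_id[is_bir & scan$source_db == "CDD"])
  missing <- setdiff(pass_e, unique(scan$protein_id))
  if (length(missing)) {
    message(length(missing),
            " candidate(s) absent from domain scan, dropped: ",
            paste(head(missing, 5), collapse = ", "))
  }
  intersect(pass_e, cdd_bir)
}

#' Collapse records with identical residue strings
#'
#' Exactly one representative is kept per distinct sequence; the
#' representative is the lexicographically smallest id, for determinism.
#'
#' @param records data.frame with `id`, `residues` (as from
#'   [read_fasta()]).
#' @return List with `kept` (the subset data.frame, original order
#'   restricted to representatives) and `map` (named character vector:
#'   collapsed id -> kept id, identity for representatives).
#' @export
collapse_identical <- function(records) {
  groups <- split(records$id, records$residues)
  map <- character(0)
  for (ids in groups) {
    rep_id <- min(ids)
    map[ids] <- rep_id
  }
  kept_ids <- unique(unname(map))
  list(kept = records[records$id %in% kept_ids, , drop = FALSE],
       map = map[records$id])
}

#' Collapse suspected haplotigs within high-identity clusters
#'
#' Proteins are clustered by single linkage at pairwise identity above
#' the configured threshold. Within each cluster, a member is removed as
#' a suspected haplotig iff its read coverage is strictly below
#' `haplotig_coverage_ratio` times the cluster's maximum coverage;
#' removed members map to the highest-coverage member (their "parent").
#' Downstream, expression counts of removed ids should be added to the
#' parent — see [merge_haplotig_counts()].
#'
#' @param records data.frame with `id` (and usually `residues`).
#' @param pairwise_identity Symmetric numeric matrix in `[0,1]` with
#'   dimnames covering `records$id`.
#' @param coverage Named numeric vector of per-protein read depth.
#' @param cfg A [curation_config()].
#' @return List with `kept` (subset data.frame) and `map` (named vector:
#'   removed id -> parent id; representatives map to themselves).
#' @export
collapse_haplotigs <- function(records, pairwise_identity, coverage,
                               cfg = curation_config()) {
  ids <- records$id
  stopifnot(all(ids %in% rownames(pairwise_identity)),
            all(ids %in% colnames(pairwise_identity)))
  pim <- pairwise_identity[ids, ids, drop = FALSE]
  if (max(abs(pim - t(pim))) > 1e-8) stop("identity matrix not symmetric")
  # single-linkage components over the > threshold graph
  n <- length(ids)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (pim[i, j] > cfg$haplotig_identity_min) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  map <- setNames(ids, ids)
  removed <- character(0)
  for (cl in split(seq_len(n), roots)) {
    if (length(cl) < 2L) next
    cl_ids <- ids[cl]
    cov <- coverage[cl_ids]
    if (anyNA(cov)) {
      stop("missing coverage for clustered protein(s): ",
           paste(cl_ids[is.na(cov)], collapse = ", "))
    }
    parent <- cl_ids[which.max(cov)]
    drop <- cl_ids[cov < cfg$haplotig_coverage_ratio * max(cov)]
    map[drop] <- parent
    removed <- c(removed, drop)
  }
  list(kept = records[!(ids %in% removed), , drop = FALSE], map = map)
}

#' Global pairwise identity matrix for protein records
#'
#' Identity = matches over alignment length from a global alignment
#' (BLOSUM62, affine gap opening 10 / extension 1, the same scoring as
#' the BIR anchoring aligner), computed by a compiled Gotoh kernel.
#'
#' When `screen_min` is set, pairs that provably cannot reach that
#' identity are skipped: matches never exceed the shorter length and
#' the alignment is at least as long as the longer sequence, so
#' identity is bounded by the length ratio. Skipped pairs are reported
#' as 0, which is exact for any clustering threshold at or above
#' `screen_min`.
#'
#' @param records data.frame with `id`, `residues`.
#' @param screen_min Optional identity of interest enabling the
#'   length-ratio screen (e.g. the haplotig clustering threshold).
#' @return Symmetric matrix of fractions in `[0,1]`, unit diagonal.
#' @export
pairwise_identity <- function(records, screen_min = NULL) {
  n <- nrow(records)
  m <- diag(1, n)
  dimnames(m) <- list(records$id, records$id)
  if (n < 2L) return(m)
  blosum <- get_blosum62()
  alpha <- rownames(blosum)
  enc <- lapply(records$residues, function(s) {
    idx <- match(strsplit(s, "")[[1]], alpha)
    idx[is.na(idx)] <- match("X", alpha)
    as.integer(idx - 1L)
  })
  m <- pairwise_identity_cpp(enc, blosum, 10, 1,
                             if (is.null(screen_min)) 0 else screen_min)
  dimnames(m) <- list(records$id, records$id)
  m
}

#' Add counts of removed haplotigs to their parents
#'
#' @param counts Numeric matrix, rows = transcript/protein ids.
#' @param map Collapse map from [collapse_haplotigs()] (removed -> parent).
#' @return Matrix restricted to kept ids with haplotig counts folded in.
#'   Total counts are conserved.
#' @export
merge_haplotig_counts <- function(counts, map) {
  present <- intersect(names(map), rownames(counts))
  map <- map[present]
  dest <- unname(map)
  agg <- rowsum(counts[present, , drop = FALSE], group = dest)
  other <- setdiff(rownames(counts), present)
  out <- rbind(agg, counts[other, , drop = FALSE])
  out[order(rownames(out)), , drop = FALSE]
}

#' Identify intronless genes
#'
#' A gene is intronless iff every one of its transcripts has exactly one
#' exon (multi-isoform genes with any spliced isoform are excluded).
#'
#' @param genes List of gene models from [read_gff3()].
#' @return Character vector of intronless gene ids.
#' @export
detect_intronless <- function(genes) {
  flagged <- vapply(genes, function(g) all(exon_counts(g) == 1L), logical(1))
  vapply(genes[flagged], function(g) g$gene_id, "")
}

#' Detect tandem arrays of IAP genes along chromosomes
#'
#' A tandem array is a maximal run of >= 2 IAP genes on one chromosome
#' with at most `tandem_max_intervening` non-IAP genes between
#' consecutive members and an inter-member gap of at most
#' `tandem_max_gap_bp`.
#'
#' @param gene_order data.frame with columns `gene_id`, `chromosome`,
#'   `start`, `end` (internal coordinates) covering all genes, IAP or
#'   not; order within a chromosome is taken from `start`.
#' @param iap_ids Character vector of IAP gene ids.
#' @param cfg A [curation_config()].
#' @return data.frame with columns `gene_id`, `tandem_array_id`; one row
#'   per IAP gene that belongs to an array. Array ids are
#'   `"<chromosome>_arr<k>"`.
#' @export
detect_tandem_arrays <- function(gene_order, iap_ids,
                                 cfg = curation_config()) {
  out <- list()
  for (chrom in unique(gene_order$chromosome)) {
    g <- gene_order[gene_order$chromosome == chrom, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    is_iap <- g$gene_id %in% iap_ids
    idx <- which(is_iap)
    if (length(idx) < 2L) next
    arr_no <- 0L
    current <- idx[1]
    for (i in seq_along(idx)[-1]) {
      prev <- current[length(current)]
      intervening <- idx[i] - prev - 1L
      gap <- g$start[idx[i]] - g$end[prev]
      if (intervening <= cfg$tandem_max_intervening &&
          gap <= cfg$tandem_max_gap_bp) {
        current <- c(current, idx[i])
      } else {
        if (length(current) >= 2L) {
          arr_no <- arr_no + 1L
          out[[length(out) + 1L]] <- data.frame(
            gene_id = g$gene_id[current],
            tandem_array_id = paste0(chrom, "_arr", arr_no),
            stringsAsFactors = FALSE)
        }
        current <- idx[i]
      }
    }
    if (length(current) >= 2L) {
      arr_no <- arr_no + 1L
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id[current],
        tandem_array_id = paste0(chrom, "_arr", arr_no),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), tandem_array_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Transposase Tc1-like domain accessions
#' @return Character vector of InterPro accessions.
#' @export
tc1_transposase_accessions <- function() {
  c("IPR002492", "IPR027805", "IPR038717")
}

#' Default reverse-transcriptase accession list
#'
#' The domain is named in annotation practice without a single pinned
#' accession; this configurable list covers the common InterPro RT
#' entries.
#' @return Character vector of InterPro accessions.
#' @export
reverse_transcriptase_accessions <- function() {
  c("IPR000477", "IPR013103", "IPR043502")
}

#' Flag retroposition/transposition machinery from ORF domain scans
#'
#' @param orf_scan Domain-scan hits over translated ORFs, with a
#'   `gene_id` column (or `protein_id` used as gene id).
#' @param tc1_accessions,rt_accessions Accession lists; see
#'   [tc1_transposase_accessions()] and
#'   [reverse_transcriptase_accessions()].
#' @return data.frame with `gene_id`, `transposase_tc1`,
#'   `reverse_transcriptase` (logical), one row per gene in the scan.
#' @export
flag_retroposition <- function(orf_scan,
                               tc1_accessions = tc1_transposase_accessions(),
                               rt_accessions =
                                 reverse_transcriptase_accessions()) {
  gid <- if ("gene_id" %in% names(orf_scan)) orf_scan$gene_id else
    orf_scan$protein_id
  rt_hit <- orf_scan$accession %in% rt_accessions |
    grepl("reverse transcriptase", orf_scan$description, ignore.case = TRUE)
  tc1_hit <- orf_scan$accession %in% tc1_accessions
  genes <- unique(gid)
  data.frame(
    gene_id = genes,
    transposase_tc1 = vapply(genes, function(g) any(tc1_hit[gid == g]),
                             logical(1)),
    reverse_transcriptase = vapply(genes, function(g) any(rt_hit[gid == g]),
                                   logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Mine annotation product names for apoptosis/RCD targets
#'
#' Case-insensitive whole-word matching of catalog aliases against
#' product-name strings; each transcript records which alias fired.
#'
#' @param annotations data.frame with `gene_id`, `transcript_id`,
#'   `product` columns.
#' @param catalog Named list: target name -> character vector of aliases
#'   (the target name itself should be included among its aliases if it
#'   is to match).
#' @return data.frame of matches: `gene_id`, `transcript_id`, `product`,
#'   `target`, `alias`.
#' @export
mine_rcd_annotations <- function(annotations, catalog) {
  if (length(catalog) == 0L) stop("empty RCD catalog")
  stopifnot(all(c("gene_id", "transcript_id", "product") %in%
                  names(annotations)))
  out <- list()
  for (target in names(catalog)) {
    for (alias in catalog[[target]]) {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", alias),
                    "\\b")
      hit <- grepl(pat, annotations$product, ignore.case = TRUE)
      if (any(hit)) {
        m <- annotations[hit, c("gene_id", "transcript_id", "product")]
        m$target <- target
        m$alias <- alias
        out[[length(out) + 1L]] <- m
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      product = character(), target = character(),
                      alias = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # one record per transcript x target; first firing alias wins
  res[!duplicated(res[c("transcript_id", "target")]), , drop = FALSE]
}
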