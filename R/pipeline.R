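# End-to-end orchestration in the curation-methods order:
# candidate filter -> CDD prune -> identical collapse -> haplotig
# collapse -> BIR typing -> architecture typing (-> cluster consensus),
# then expression-status classification and per-experiment network
# analysis. Each stage logs record counts in and out so the curation
# funnel is visible.

#' Characterize an IAP gene family from scan evidence
#'
#' Runs the curation and classification stages in order on in-memory
#' inputs (as produced by the readers or by [gen_family()]).
#'
#' @param proteins data.frame `id`, `description`, `residues`.
#' @param scan Domain-scan hits (internal coordinates).
#' @param hmm data.frame `protein_id`, `e_value`.
#' @param genes Gene-model list (see [read_gff3()]); optional.
#' @param gene_order data.frame for tandem detection (see
#'   [detect_tandem_arrays()]); optional.
#' @param coverage Named coverage vector for haplotig collapse;
#'   optional (skips haplotig collapse when NULL).
#' @param orf_scan ORF domain hits for retroposition flags; optional.
#' @param tree `phylo` tree plus `species` map for cluster consensus;
#'   optional.
#' @param species Named vector leaf label -> species tag.
#' @param curation A [curation_config()].
#' @param rules Architecture rule table.
#' @param token_map Accession -> token map.
#' @param ref BIR reference alignment.
#' @param verbose Print the per-stage funnel.
#' @return List with `candidates`, `kept_proteins`, `identical_map`,
#'   `haplotig_map`, `bir_calls` (data.frame), `architecture` (named
#'   vector per protein), `intronless`, `tandem`, `retro_flags`,
#'   `clusters`, `funnel` (data.frame stage/records).
#' @export
run_characterize <- function(proteins, scan, hmm, genes = NULL,
                             gene_order = NULL, coverage = NULL,
                             orf_scan = NULL, tree = NULL, species = NULL,
                             curation = curation_config(),
                             rules = default_architecture_rules(),
                             token_map = default_token_map(),
                             ref = load_bir_reference(),
                             verbose = FALSE) {
  funnel <- list()
  log_stage <- function(stage, n) {
    funnel[[length(funnel) + 1L]] <<- data.frame(stage = stage,
                                                 records = n)
    if (verbose) message(stage, ": ", n)
  }
  log_stage("input_proteins", nrow(proteins))

  ids <- filter_iap_candidates(hmm, scan, curation)
  log_stage("evalue_and_cdd_filtered", length(ids))
  cand <- proteins[proteins$id %in% ids, , drop = FALSE]

  coll <- collapse_identical(cand)
  log_stage("after_identical_collapse", nrow(coll$kept))

  hap_map <- setNames(coll$kept$id, coll$kept$id)
  kept <- coll$kept
  if (!is.null(coverage) && nrow(kept) > 1L) {
    pim <- pairwise_identity(kept,
                             screen_min = curation$haplotig_identity_min)
    hap <- collapse_haplotigs(kept, pim, coverage, curation)
    kept <- hap$kept
    hap_map <- hap$map
  }
  log_stage("after_haplotig_collapse", nrow(kept))

  bir_calls <- list()
  for (i in seq_len(nrow(kept))) {
    pid <- kept$id[i]
    ph <- scan[scan$protein_id == pid, , drop = FALSE]
    bh <- ph[is_bir_hit(ph), , drop = FALSE]
    if (!nrow(bh)) next
    # merge overlapping BIR evidence across sources into one span,
    # recording whether any contributing hit came from CDD
    bh <- bh[order(bh$start), , drop = FALSE]
    spans <- list()
    for (j in seq_len(nrow(bh))) {
      placed <- FALSE
      for (k in seq_along(spans)) {
        if (bh$start[j] < spans[[k]]$end && bh$end[j] > spans[[k]]$start) {
          spans[[k]]$start <- min(spans[[k]]$start, bh$start[j])
          spans[[k]]$end <- max(spans[[k]]$end, bh$end[j])
          spans[[k]]$has_cdd <- spans[[k]]$has_cdd ||
            bh$source_db[j] == "CDD"
          placed <- TRUE
          break
        }
      }
      if (!placed) spans[[length(spans) + 1L]] <-
          list(start = bh$start[j], end = bh$end[j],
               has_cdd = bh$source_db[j] == "CDD")
    }
    span_df <- do.call(rbind, lapply(spans, as.data.frame))
    bir_calls[[pid]] <- call_birs(pid, kept$residues[i], span_df,
                                  ref = ref)
  }
  bir_df <- do.call(rbind, bir_calls)
  rownames(bir_df) <- NULL
  log_stage("bir_domains_typed", if (is.null(bir_df)) 0L else nrow(bir_df))

  architecture <- character(0)
  for (i in seq_len(nrow(kept))) {
    pid <- kept$id[i]
    ph <- scan[scan$protein_id == pid, , drop = FALSE]
    bc <- bir_df[bir_df$protein_id == pid, , drop = FALSE]
    toks <- tokenize_architecture(ph, bc, token_map)
    architecture[pid] <- if (length(toks))
      classify_architecture(toks, rules) else "NOVEL"
  }
  log_stage("architectures_assigned", length(architecture))

  intronless <- if (!is.null(genes)) detect_intronless(genes) else NULL
  tandem <- if (!is.null(gene_order)) {
    iap_gene_ids <- unique(sub("\\.t\\d+$", "", kept$id))
    detect_tandem_arrays(gene_order, iap_gene_ids, curation)
  } else NULL
  retro <- if (!is.null(orf_scan) && nrow(orf_scan))
    flag_retroposition(orf_scan) else NULL

  clusters <- NULL
  if (!is.null(tree) && !is.null(species)) {
    clusters <- extract_supported_clusters(tree, species)
    for (i in seq_along(clusters)) {
      members <- intersect(clusters[[i]]$members, names(architecture))
      if (length(members)) {
        cc <- cluster_consensus(members, architecture)
        clusters[[i]]$consensus <- cc$consensus
        clusters[[i]]$conserved <- cc$conserved
      }
    }
  }

  list(candidates = ids, kept_proteins = kept,
       identical_map = coll$map, haplotig_map = hap_map,
       bir_calls = bir_df, architecture = architecture,
       intronless = intronless, tandem = tandem, retro_flags = retro,
       clusters = clusters, funnel = do.call(rbind, funnel))
}

#' Expression and co-expression analysis across experiments
#'
#' Classifies each gene's expression status per experiment (after
#' folding haplotig counts into their parents), computes cross-
#' experiment DEG sharing and architecture usage, and runs the
#' co-expression network per experiment where expression matrices are
#' supplied.
#'
#' @param de_tables Named list of DE tables per experiment.
#' @param count_matrices Named list of count matrices per experiment
#'   (transcript rows).
#' @param gene_map Named vector transcript -> gene.
#' @param haplotig_map Collapse map (removed -> parent) from
#'   characterization; identity map if no haplotigs.
#' @param architecture Named vector protein/transcript -> type
#'   (optional, enables architecture usage).
#' @param expression Named list per experiment:
#'   `list(matrix =, trait =)` for network analysis (optional).
#' @param iap_ids,apoptosis_ids Id sets for edge extraction (optional).
#' @param expr_cfg An [expression_config()].
#' @param net_cfg A [network_config()].
#' @return List with `status` (named list of status data.frames),
#'   `sharing`, `usage`, `networks` (named list of `coexpr_network`),
#'   `edges` (named list of edge data.frames).
#' @export
run_expression <- function(de_tables, count_matrices, gene_map,
                           haplotig_map = NULL, architecture = NULL,
                           expression = NULL, iap_ids = NULL,
                           apoptosis_ids = NULL,
                           expr_cfg = expression_config(),
                           net_cfg = network_config()) {
  stopifnot(identical(sort(names(de_tables)),
                      sort(names(count_matrices))))
  status <- list()
  deg_sets <- list()
  sig_transcripts <- list()
  for (exp_id in names(de_tables)) {
    cm <- count_matrices[[exp_id]]
    if (!is.null(haplotig_map)) cm <- merge_haplotig_counts(cm,
                                                            haplotig_map)
    de <- de_tables[[exp_id]]
    de <- de[de$transcript_id %in% rownames(cm), , drop = FALSE]
    st <- classify_expression_status(de, cm, gene_map, expr_cfg)
    status[[exp_id]] <- st
    deg_sets[[exp_id]] <- st$gene_id[st$status %in%
                                       c("differential", "mixed")]
    sig <- unique(de$transcript_id[de$padj <= expr_cfg$padj_max])
    sig_transcripts[[exp_id]] <- sig
  }
  sharing <- if (length(deg_sets) >= 2L &&
                 length(unlist(deg_sets))) shared_deg_fraction(deg_sets)
  else NULL
  usage <- if (!is.null(architecture))
    architecture_usage(sig_transcripts, architecture) else NULL

  networks <- list(); edges <- list()
  for (exp_id in names(expression %||% list())) {
    ex <- expression[[exp_id]]
    net <- build_network(ex$matrix, trait = ex$trait,
                         iap_ids = iap_ids,
                         apoptosis_ids = apoptosis_ids, cfg = net_cfg)
    networks[[exp_id]] <- net
    if (!is.null(net$module_trait) && !is.null(iap_ids) &&
        !is.null(apoptosis_ids)) {
      edges[[exp_id]] <- extract_direct_edges(net, iap_ids,
                                              apoptosis_ids)
    }
  }
  list(status = status, sharing = sharing, usage = usage,
       networks = networks, edges = edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
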