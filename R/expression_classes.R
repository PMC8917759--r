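# Post-model expression-status classification. The differential
# expression model itself (DESeq2-style) is upstream; this module
# operates strictly downstream of its adjusted-p decision rule and the
# raw count matrix.

#' Expression classification thresholds
#'
#' @param padj_max Adjusted-p significance ceiling (default 0.05).
#' @param min_total_count Transcripts with a total read count strictly
#'   below this are removed from the analysis entirely (default 10).
#' @param detection_min_count Per-sample count at or above which a
#'   transcript counts as detected in that sample (default 1).
#' @return An `expression_config` list.
#' @export
expression_config <- function(padj_max = 0.05, min_total_count = 10L,
                              detection_min_count = 1L) {
  stopifnot(padj_max > 0, padj_max <= 1, min_total_count > 0,
            detection_min_count > 0)
  structure(list(padj_max = padj_max,
                 min_total_count = as.integer(min_total_count),
                 detection_min_count = as.integer(detection_min_count)),
            class = "expression_config")
}

#' Classify gene expression status within one experiment
#'
#' Transcript-level: a transcript is *significant* iff `padj <= padj_max`
#' in at least one comparison of the experiment; *constitutive* iff it is
#' never significant, passes the total-count prefilter, and is detected
#' (count >= `detection_min_count`) in every sample. Transcripts below
#' the total-count prefilter are excluded entirely.
#'
#' Gene-level: `differential` iff >= 1 significant transcript and no
#' constitutive one; `constitutive` iff >= 1 constitutive transcript and
#' no significant one; `mixed` iff both kinds present; `not_expressed`
#' otherwise.
#'
#' @param de DE table for the experiment (see [read_de_table()]).
#' @param counts Numeric count matrix, rows = transcript ids, columns =
#'   the experiment's samples.
#' @param gene_map Named character vector: transcript id -> gene id.
#' @param cfg An [expression_config()].
#' @return data.frame with `gene_id`, `status`, `n_significant`,
#'   `n_constitutive`, `n_transcripts`.
#' @export
classify_expression_status <- function(de, counts, gene_map,
                                       cfg = expression_config()) {
  missing <- setdiff(unique(de$transcript_id), rownames(counts))
  if (length(missing)) {
    stop("transcript in DE table absent from counts: ", missing[1])
  }
  tids <- intersect(names(gene_map), rownames(counts))
  total <- rowSums(counts[tids, , drop = FALSE])
  kept <- tids[total >= cfg$min_total_count]
  sig_t <- unique(de$transcript_id[de$padj <= cfg$padj_max &
                                     !is.na(de$padj)])
  sig_t <- intersect(sig_t, kept)
  detected_all <- kept[apply(counts[kept, , drop = FALSE] >=
                               cfg$detection_min_count, 1, all)]
  const_t <- setdiff(detected_all,
                     unique(de$transcript_id[de$padj <= cfg$padj_max &
                                               !is.na(de$padj)]))
  genes <- unique(unname(gene_map))
  status <- vapply(genes, function(g) {
    tr <- names(gene_map)[gene_map == g]
    ns <- length(intersect(tr, sig_t))
    nc <- length(intersect(tr, const_t))
    if (ns > 0L && nc > 0L) "mixed"
    else if (ns > 0L) "differential"
    else if (nc > 0L) "constitutive"
    else "not_expressed"
  }, "")
  data.frame(
    gene_id = genes,
    status = unname(status),
    n_significant = vapply(genes, function(g)
      length(intersect(names(gene_map)[gene_map == g], sig_t)), integer(1)),
    n_constitutive = vapply(genes, function(g)
      length(intersect(names(gene_map)[gene_map == g], const_t)),
      integer(1)),
    n_transcripts = vapply(genes, function(g)
      sum(gene_map == g), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of differentially expressed genes shared across experiments
#'
#' Shared = differentially expressed in at least two experiments;
#' denominator = the union of all experiments' DEG sets. The all-
#' experiments variant is returned alongside for comparison since the
#' sharing denominator is a reporting choice.
#'
#' @param deg_sets Named list of character vectors (per-experiment DEG
#'   ids); >= 2 experiments.
#' @return List with `shared_ge2` (fraction in >= 2 experiments),
#'   `shared_all` (fraction in every experiment) and `union_size`.
#' @export
shared_deg_fraction <- function(deg_sets) {
  stopifnot(length(deg_sets) >= 2L)
  all_genes <- unique(unlist(deg_sets))
  if (!length(all_genes)) stop("empty DEG union")
  n_in <- vapply(all_genes, function(g)
    sum(vapply(deg_sets, function(s) g %in% s, logical(1))), integer(1))
  list(shared_ge2 = mean(n_in >= 2L),
       shared_all = mean(n_in == length(deg_sets)),
       union_size = length(all_genes))
}

#' Architecture usage of expressed transcripts per experiment
#'
#' Counts distinct differentially expressed transcripts per architecture
#' type in each experiment, and the number of distinct types used.
#'
#' @param sig_transcripts Named list: experiment id -> character vector
#'   of significantly differentially expressed transcript ids.
#' @param architecture_calls Named character vector: transcript id ->
#'   architecture type.
#' @return List with `counts` (data.frame `experiment`, `type`, `n`) and
#'   `n_types` (named integer vector per experiment).
#' @export
architecture_usage <- function(sig_transcripts, architecture_calls) {
  rows <- list()
  n_types <- integer(0)
  for (exp_id in names(sig_transcripts)) {
    tr <- unique(sig_transcripts[[exp_id]])
    missing <- setdiff(tr, names(architecture_calls))
    if (length(missing)) {
      stop("expressed transcript without architecture call: ", missing[1])
    }
    ty <- architecture_calls[tr]
    if (length(ty)) {
      tab <- table(ty)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = exp_id, type = names(tab), n = as.integer(tab),
        stringsAsFactors = FALSE)
    }
    n_types[exp_id] <- length(unique(ty))
  }
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(experiment = character(), type = character(),
               n = integer(), stringsAsFactors = FALSE)
  list(counts = counts, n_types = n_types)
}
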