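# Synthetic-data generators. Every pipeline input format can be
# generated with known ground truth, so each downstream stage has a
# closure test: the generator's truth must be recovered exactly in the
# no-noise limit. All generators are deterministic given their seed and
# leave the caller's RNG state untouched.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

bir_types <- function() {
  c("TypeI", "TypeII", "TypeI_like", "TypeII_like", "TypeX", "TypeY",
    "NZBIR")
}

#' Generate a synthetic BIR domain of a given type
#'
#' Instantiates the reference backbone with key residues set per the
#' type's rule, optional random flanking sequence, and optional random
#' mutations restricted to non-key, non-conserved positions.
#'
#' @param type One of `r paste(bir_types(), collapse = ", ")`.
#' @param n_flank Number of random residues added on each side.
#' @param n_mutations_nonkey Number of random substitutions at free
#'   (non-key, non-conserved) backbone positions.
#' @param seed Integer seed.
#' @param ref Reference from [load_bir_reference()].
#' @return List with `residues` (string) and `truth` (list: `type`,
#'   `n_flank`, `core_start` 0-based offset of the backbone within the
#'   string).
#' @export
gen_bir <- function(type, n_flank = 0L, n_mutations_nonkey = 0L, seed = 1L,
                    ref = load_bir_reference()) {
  if (!type %in% bir_types()) stop("unknown BIR type: ", type)
  with_seed(seed, {
    s <- strsplit(ref$consensus, "")[[1]]
    free <- setdiff(seq_along(s),
                    union(ref$key_positions, ref$conserved_positions))
    if (n_mutations_nonkey > 0L) {
      mut <- sample(free, n_mutations_nonkey)
      s[mut] <- vapply(s[mut], function(r) sample(setdiff(AA20, r), 1), "")
    }
    s <- switch(type,
      TypeI = { s[80] <- sample(c("V", "L"), 1); s },
      TypeII = { s[76] <- sample(c("E", "Q"), 1)
                 s[80] <- sample(c("W", "H"), 1); s },
      TypeI_like = { s[80] <- "I"; s[81] <- "S"; s },
      TypeII_like = { s[76] <- "E"; s[80] <- "A"; s },
      TypeX = { s[80] <- "G"; s[82] <- "R"; s },
      TypeY = s[-(79:81)],
      NZBIR = { s[57] <- "T"; s[76] <- "E"; s[80] <- "W"; s })
    lf <- if (n_flank > 0L) paste(sample(AA20, n_flank, TRUE),
                                  collapse = "") else ""
    rf <- if (n_flank > 0L) paste(sample(AA20, n_flank, TRUE),
                                  collapse = "") else ""
    list(residues = paste0(lf, paste(s, collapse = ""), rf),
         truth = list(type = type, n_flank = as.integer(n_flank),
                      core_start = as.integer(n_flank)))
  })
}

# Fixed non-BIR domain templates (deterministic module constants).
domain_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- with_seed(424242L, {
        toks <- c("RING", "DD", "UBA", "UBC", "BIRC6_DOMAIN", "WD40")
        setNames(lapply(toks, function(t)
          paste(sample(AA20, 60, TRUE), collapse = "")), toks)
      })
    }
    cache
  }
})

# Representative accession per token for synthetic scan tables.
token_accession <- function() {
  c(RING = "IPR013083", DD = "G3DSA:1.10.533.10", UBA = "IPR015940",
    UBC = "IPR000608", BIRC6_DOMAIN = "IPR022103", WD40 = "IPR019775")
}

# token -> gen_bir type for BIR tokens
token_bir_type <- c(TI = "TypeI", TII = "TypeII", TI_like = "TypeI_like",
                    TII_like = "TypeII_like", TX = "TypeX", TY = "TypeY",
                    NZBIR = "NZBIR", BIR_STAR = "TypeII")

#' Generate a synthetic IAP gene family with planted curation features
#'
#' Builds proteins by concatenating domain templates per architecture
#' (with random linkers), places genes on synthetic chromosomes
#' honouring tandem-array and intronless specifications, adds haplotig
#' near-copies (97% identity, 0.3x parent coverage) and decoy non-IAP
#' candidates, and emits the matching domain-scan, HMM-hit and coverage
#' tables plus a full truth record.
#'
#' @param n_genes Number of true IAP genes.
#' @param architecture_mix Named numeric vector of architecture-type
#'   weights (names from [default_architecture_rules()]); genes are
#'   assigned types round-robin proportional to the weights.
#' @param haplotig_fraction Fraction of IAP genes that receive a
#'   haplotig near-copy.
#' @param intronless_fraction Fraction of IAP genes that are
#'   single-exon.
#' @param tandem_arrays List of `list(chromosome =, size =)` specs;
#'   total size must not exceed `n_genes`.
#' @param n_decoys Non-IAP decoy candidates (half fail the E-value
#'   filter, half lack CDD BIR confirmation).
#' @param n_retro_tc1,n_retro_rt Genes planted with Tc1-transposase /
#'   reverse-transcriptase ORF hits.
#' @param chromosomes Chromosome names used for placement.
#' @param seed Integer seed.
#' @return List with `proteins` (data.frame id/description/residues),
#'   `genes` (gene-model list), `scan`, `orf_scan` (hit data.frames,
#'   internal coordinates), `hmm` (data.frame), `coverage` (named
#'   vector), and `truth`.
#' @export
gen_family <- function(n_genes = 20L,
                       architecture_mix = c("BIRC2/3-like" = 2,
                                            "BIRC10" = 1, "BIRC11" = 1,
                                            "BIRC7-like" = 1,
                                            "BIRC5-like" = 1),
                       haplotig_fraction = 0,
                       intronless_fraction = 0.2,
                       tandem_arrays = list(),
                       n_decoys = 0L, n_retro_tc1 = 0L, n_retro_rt = 0L,
                       chromosomes = c("chrA", "chrB"),
                       seed = 1L) {
  stopifnot(haplotig_fraction >= 0, haplotig_fraction <= 1,
            intronless_fraction >= 0, intronless_fraction <= 1)
  n_tandem <- sum(vapply(tandem_arrays, function(a) a$size, numeric(1)))
  if (n_tandem > n_genes) stop("tandem arrays larger than n_genes")
  rules <- default_architecture_rules()
  stopifnot(all(names(architecture_mix) %in% names(rules)))
  ref <- load_bir_reference()
  with_seed(seed, {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    w <- architecture_mix / sum(architecture_mix)
    n_each <- floor(n_genes * w)
    rem <- n_genes - sum(n_each)
    if (rem > 0L) {
      extra <- order(n_genes * w - n_each, decreasing = TRUE)[seq_len(rem)]
      n_each[extra] <- n_each[extra] + 1L
    }
    arch <- sample(rep(names(architecture_mix), times = n_each))
    names(arch) <- gene_ids

    proteins <- list(); scan_rows <- list(); hmm_rows <- list()
    prot_of_gene <- character(0)
    for (g in gene_ids) {
      pat <- rules[[arch[g]]][[1]]
      # instantiate ANY_BIR+ as two BIR domains for BIRC6-like
      toks <- unlist(lapply(pat, function(el)
        if (el == "ANY_BIR+") c("TII", "TII") else el))
      pid <- paste0(g, ".t1")
      seq_parts <- character(0)
      pos <- 0L
      for (tk in toks) {
        linker <- paste(sample(AA20, 15, TRUE), collapse = "")
        seq_parts <- c(seq_parts, linker)
        pos <- pos + 15L
        if (tk %in% names(token_bir_type)) {
          bir <- gen_bir(token_bir_type[[tk]], 0L, 0L,
                         seed = sample.int(1e6, 1), ref = ref)
          dlen <- nchar(bir$residues)
          if (tk != "BIR_STAR") {
            scan_rows[[length(scan_rows) + 1L]] <- data.frame(
              protein_id = pid, source_db = "CDD", accession = "cd00022",
              description = "BIR repeat", start = pos, end = pos + dlen,
              e_value = 1e-10, stringsAsFactors = FALSE)
          }
          scan_rows[[length(scan_rows) + 1L]] <- data.frame(
            protein_id = pid, source_db = "PFAM", accession = "PF00653",
            description = "BIR repeat (Pfam)", start = pos,
            end = pos + dlen, e_value = 1e-8, stringsAsFactors = FALSE)
          seq_parts <- c(seq_parts, bir$residues)
          pos <- pos + dlen
        } else {
          tmpl <- domain_templates()[[tk]]
          acc <- token_accession()[[tk]]
          scan_rows[[length(scan_rows) + 1L]] <- data.frame(
            protein_id = pid, source_db = "INTERPRO", accession = acc,
            description = tk, start = pos, end = pos + nchar(tmpl),
            e_value = 1e-12, stringsAsFactors = FALSE)
          seq_parts <- c(seq_parts, tmpl)
          pos <- pos + nchar(tmpl)
        }
      }
      seq_parts <- c(seq_parts, paste(sample(AA20, 15, TRUE),
                                      collapse = ""))
      proteins[[pid]] <- paste(seq_parts, collapse = "")
      prot_of_gene[g] <- pid
      hmm_rows[[length(hmm_rows) + 1L]] <- data.frame(
        protein_id = pid, e_value = 10^(-stats::runif(1, 5, 40)),
        stringsAsFactors = FALSE)
    }

    # haplotig near-copies: ~3% substitutions, 0.3x parent coverage
    n_hap <- round(haplotig_fraction * n_genes)
    hap_parents <- if (n_hap > 0L) sample(gene_ids, n_hap) else character(0)
    hap_map <- character(0)
    coverage <- setNames(stats::runif(n_genes, 25, 35),
                         unname(prot_of_gene))
    for (hp in hap_parents) {
      parent_pid <- prot_of_gene[hp]
      hid <- sub("^G", "H", hp)
      hpid <- paste0(hid, ".t1")
      s <- strsplit(proteins[[parent_pid]], "")[[1]]
      n_mut <- max(1L, round(0.03 * length(s)))
      mut <- sample(seq_along(s), n_mut)
      s[mut] <- vapply(s[mut], function(r) sample(setdiff(AA20, r), 1), "")
      proteins[[hpid]] <- paste(s, collapse = "")
      hap_map[hpid] <- parent_pid
      coverage[hpid] <- 0.3 * coverage[parent_pid]
      ps <- do.call(rbind, scan_rows)
      prows <- ps[ps$protein_id == parent_pid, , drop = FALSE]
      prows$protein_id <- hpid
      scan_rows[[length(scan_rows) + 1L]] <- prows
      hmm_rows[[length(hmm_rows) + 1L]] <- data.frame(
        protein_id = hpid, e_value = 10^(-stats::runif(1, 5, 40)),
        stringsAsFactors = FALSE)
    }

    # decoys: half fail the E-value cut, half lack the CDD BIR signature
    decoy_ids <- character(0)
    if (n_decoys > 0L) {
      for (d in seq_len(n_decoys)) {
        dpid <- sprintf("D%04d.t1", d)
        decoy_ids <- c(decoy_ids, dpid)
        proteins[[dpid]] <- paste(sample(AA20, 150, TRUE), collapse = "")
        if (d %% 2L == 0L) {
          hmm_rows[[length(hmm_rows) + 1L]] <- data.frame(
            protein_id = dpid, e_value = stats::runif(1, 0.01, 1),
            stringsAsFactors = FALSE)
          scan_rows[[length(scan_rows) + 1L]] <- data.frame(
            protein_id = dpid, source_db = "CDD", accession = "cd00022",
            description = "BIR repeat", start = 10L, end = 110L,
            e_value = 1e-5, stringsAsFactors = FALSE)
        } else {
          hmm_rows[[length(hmm_rows) + 1L]] <- data.frame(
            protein_id = dpid, e_value = 1e-8, stringsAsFactors = FALSE)
          scan_rows[[length(scan_rows) + 1L]] <- data.frame(
            protein_id = dpid, source_db = "PFAM", accession = "PF00653",
            description = "BIR repeat (Pfam)", start = 10L, end = 110L,
            e_value = 1e-5, stringsAsFactors = FALSE)
        }
        coverage[dpid] <- stats::runif(1, 25, 35)
      }
    }

    # genome placement: tandem arrays adjacent, singletons separated by
    # 4 background genes; haplotig genes on a separate scaffold
    intronless <- if (intronless_fraction > 0)
      sample(gene_ids, round(intronless_fraction * n_genes)) else
        character(0)
    placed <- character(0)
    tandem_truth <- data.frame(gene_id = character(),
                               tandem_array_id = character(),
                               stringsAsFactors = FALSE)
    genes <- list()
    order_rows <- list()
    bg_i <- 0L
    arr_no <- setNames(rep(0L, length(chromosomes)), chromosomes)
    add_gene <- function(gid, chrom, at, iap) {
      glen <- sample(2000:5000, 1)
      tid <- paste0(gid, ".t1")
      n_ex <- if (iap && gid %in% intronless) 1L else sample(2:4, 1)
      bounds <- sort(sample(seq(100L, glen - 100L), 2L * (n_ex - 1L)))
      starts <- c(0L, bounds[seq_along(bounds) %% 2L == 0L])
      ends <- c(bounds[seq_along(bounds) %% 2L == 1L], glen)
      ex <- cbind(start = at + starts, end = at + ends)
      genes[[gid]] <<- list(gene_id = gid, chromosome = chrom,
                            strand = sample(c("+", "-"), 1),
                            start = at, end = at + glen,
                            transcripts = setNames(list(ex), tid))
      order_rows[[length(order_rows) + 1L]] <<- data.frame(
        gene_id = gid, chromosome = chrom, start = at, end = at + glen,
        stringsAsFactors = FALSE)
      at + glen + sample(2000:4000, 1)
    }
    add_background <- function(chrom, at, k) {
      for (i in seq_len(k)) {
        bg_i <<- bg_i + 1L
        at <- add_gene(sprintf("BG%04d", bg_i), chrom, at, FALSE)
      }
      at
    }
    cursor <- setNames(rep(1000L, length(chromosomes)), chromosomes)
    for (spec in tandem_arrays) {
      chrom <- spec$chromosome
      members <- setdiff(gene_ids, placed)[seq_len(spec$size)]
      placed <- c(placed, members)
      cursor[chrom] <- add_background(chrom, cursor[chrom], 4L)
      arr_no[chrom] <- arr_no[chrom] + 1L
      for (m in members) cursor[chrom] <- add_gene(m, chrom,
                                                   cursor[chrom], TRUE)
      tandem_truth <- rbind(tandem_truth, data.frame(
        gene_id = members,
        tandem_array_id = paste0(chrom, "_arr", arr_no[chrom]),
        stringsAsFactors = FALSE))
      cursor[chrom] <- add_background(chrom, cursor[chrom], 4L)
    }
    singles <- setdiff(gene_ids, placed)
    for (m in singles) {
      chrom <- sample(chromosomes, 1)
      cursor[chrom] <- add_gene(m, chrom, cursor[chrom], TRUE)
      cursor[chrom] <- add_background(chrom, cursor[chrom], 4L)
    }
    hap_cursor <- 1000L
    for (hpid in names(hap_map)) {
      hid <- sub("\\.t1$", "", hpid)
      parent_gid <- sub("\\.t1$", "", hap_map[hpid])
      hap_cursor <- add_gene(hid, "scaffold_hap", hap_cursor, FALSE)
      names(genes[[hid]]$transcripts) <- hpid
    }

    # retroposition machinery ORF hits
    orf_rows <- list()
    retro_tc1 <- if (n_retro_tc1 > 0L) sample(gene_ids, n_retro_tc1) else
      character(0)
    retro_rt <- if (n_retro_rt > 0L)
      sample(setdiff(gene_ids, retro_tc1), n_retro_rt) else character(0)
    for (g in retro_tc1) {
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        gene_id = g, protein_id = prot_of_gene[g], source_db = "INTERPRO",
        accession = sample(tc1_transposase_accessions(), 1),
        description = "Transposase Tc1-like", start = 5L, end = 80L,
        e_value = 1e-6, stringsAsFactors = FALSE)
    }
    for (g in retro_rt) {
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        gene_id = g, protein_id = prot_of_gene[g], source_db = "INTERPRO",
        accession = reverse_transcriptase_accessions()[1],
        description = "Reverse transcriptase domain", start = 5L,
        end = 80L, e_value = 1e-6, stringsAsFactors = FALSE)
    }
    orf_scan <- if (length(orf_rows)) do.call(rbind, orf_rows) else
      data.frame(gene_id = character(), protein_id = character(),
                 source_db = character(), accession = character(),
                 description = character(), start = integer(),
                 end = integer(), e_value = numeric(),
                 stringsAsFactors = FALSE)

    prot_df <- data.frame(id = names(proteins), description = "",
                          residues = unlist(proteins, use.names = FALSE),
                          stringsAsFactors = FALSE)
    scan <- do.call(rbind, scan_rows)
    scan <- scan[order(scan$protein_id, scan$start), , drop = FALSE]
    rownames(scan) <- NULL
    hmm <- do.call(rbind, hmm_rows)
    rownames(hmm) <- NULL
    list(proteins = prot_df, genes = genes, scan = scan,
         orf_scan = orf_scan, hmm = hmm, coverage = coverage,
         gene_order = do.call(rbind, order_rows),
         truth = list(architecture = arch,
                      protein_of_gene = prot_of_gene,
                      haplotig_map = hap_map,
                      intronless = sort(intronless),
                      tandem = tandem_truth,
                      retro_tc1 = sort(retro_tc1),
                      retro_rt = sort(retro_rt),
                      decoys = decoy_ids,
                      seed = seed))
  })
}

#' Write a synthetic family to disk in the pipeline's input formats
#'
#' @param fam Result of [gen_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Emits `proteins.fasta`, `genes.gff3`,
#'   `domain_scan.tsv`, `hmm_hits.tsv`, `coverage.tsv` and
#'   `truth_genes.tsv`.
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fam$proteins, file.path(dir, "proteins.fasta"))
  write_gff3(fam$genes, file.path(dir, "genes.gff3"))
  write_domain_scan(fam$scan, file.path(dir, "domain_scan.tsv"))
  write.table(fam$hmm, file.path(dir, "hmm_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(protein_id = names(fam$coverage),
                         coverage = unname(fam$coverage)),
              file.path(dir, "coverage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tt <- fam$truth
  gids <- names(tt$architecture)
  tg <- data.frame(
    gene_id = gids,
    architecture = unname(tt$architecture),
    intronless = gids %in% tt$intronless,
    tandem_array_id = tt$tandem$tandem_array_id[
      match(gids, tt$tandem$gene_id)],
    stringsAsFactors = FALSE)
  write.table(tg, file.path(dir, "truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a synthetic expression matrix with planted modules
#'
#' Module genes load on a shared latent factor (pairwise within-module
#' correlation = `within_cor`); each module's factor correlates with the
#' binary challenge trait at the specified `trait_r`. Leftover genes are
#' independent noise. Values are on a transformed (log-like) continuous
#' scale.
#'
#' @param n_genes Total genes.
#' @param n_samples Samples (half control, half challenged).
#' @param module_sizes Integer vector of module sizes (sum <= n_genes).
#' @param within_cor Target within-module pairwise correlation, one
#'   value or one per module.
#' @param trait_r Module latent-factor vs trait correlation, one value
#'   or one per module (|r| <= 1).
#' @param seed Integer seed.
#' @return List with `matrix` (genes x samples), `trait` (0/1 vector),
#'   `truth` (list: `labels` named integer vector, 0 = background;
#'   `within_cor`; `trait_r`).
#' @export
gen_expression <- function(n_genes = 200L, n_samples = 20L,
                           module_sizes = c(50L, 50L, 50L),
                           within_cor = 0.7, trait_r = 0.6, seed = 1L) {
  stopifnot(sum(module_sizes) <= n_genes)
  if (any(abs(trait_r) > 1)) stop("impossible trait correlation (|r| > 1)")
  k <- length(module_sizes)
  within_cor <- rep_len(within_cor, k)
  trait_r <- rep_len(trait_r, k)
  with_seed(seed, {
    trait <- rep(c(0, 1), length.out = n_samples)
    zt <- as.numeric(scale(trait))
    m <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    labels <- rep(0L, n_genes)
    at <- 0L
    for (j in seq_len(k)) {
      idx <- at + seq_len(module_sizes[j])
      at <- at + module_sizes[j]
      labels[idx] <- j
      z <- as.numeric(scale(stats::rnorm(n_samples)))
      f <- trait_r[j] * zt + sqrt(1 - trait_r[j]^2) * z
      load <- sqrt(within_cor[j])
      m[idx, ] <- load * matrix(f, length(idx), n_samples, byrow = TRUE) +
        sqrt(1 - within_cor[j]) * matrix(
          stats::rnorm(length(idx) * n_samples), length(idx), n_samples)
    }
    rownames(m) <- sprintf("g%04d", seq_len(n_genes))
    colnames(m) <- sprintf("s%02d", seq_len(n_samples))
    names(labels) <- rownames(m)
    list(matrix = m, trait = trait,
         truth = list(labels = labels, within_cor = within_cor,
                      trait_r = trait_r, seed = seed))
  })
}

#' Generate differential-expression tables with planted gene statuses
#'
#' For each experiment, every gene's planted status (`differential`,
#' `constitutive`, `mixed`, `not_expressed`) determines its transcripts'
#' adjusted p values and counts: significant transcripts draw
#' `padj < 0.05`, constitutive ones draw `padj > 0.05` with detection in
#' every sample, mixed genes get one transcript of each kind, and
#' not-expressed genes fall below the total-count prefilter.
#'
#' @param status_by_experiment Named list: experiment id -> named
#'   character vector (gene id -> status).
#' @param n_samples Samples per experiment.
#' @param seed Integer seed.
#' @return List with `de` (named list of DE tables), `counts` (named
#'   list of count matrices), `gene_map` (transcript -> gene) and
#'   `truth` (the input statuses).
#' @export
gen_de_tables <- function(status_by_experiment, n_samples = 6L,
                          seed = 1L) {
  statuses <- c("differential", "constitutive", "mixed", "not_expressed")
  all_genes <- unique(unlist(lapply(status_by_experiment, names)))
  with_seed(seed, {
    gene_map <- character(0)
    for (g in all_genes) {
      any_mixed <- any(vapply(status_by_experiment, function(s)
        identical(unname(s[g]), "mixed"), logical(1)))
      n_tr <- if (any_mixed) 2L else 1L
      for (t in seq_len(n_tr)) gene_map[paste0(g, ".t", t)] <- g
    }
    de <- list(); counts <- list()
    for (exp_id in names(status_by_experiment)) {
      st <- status_by_experiment[[exp_id]]
      stopifnot(all(st %in% statuses))
      tids <- names(gene_map)[gene_map %in% names(st)]
      cm <- matrix(0, length(tids), n_samples,
                   dimnames = list(tids, sprintf("%s_s%02d", exp_id,
                                                 seq_len(n_samples))))
      rows <- list()
      for (tid in tids) {
        g <- gene_map[tid]
        s <- st[g]
        tr_i <- as.integer(sub("^.*\\.t", "", tid))
        kind <- switch(unname(s),
          differential = "sig",
          constitutive = "const",
          mixed = if (tr_i == 1L) "sig" else "const",
          not_expressed = "low")
        if (kind == "sig") {
          padj <- stats::runif(1, 1e-6, 0.04)
          cm[tid, ] <- stats::rnbinom(n_samples, mu = 120, size = 5) + 1
        } else if (kind == "const") {
          padj <- stats::runif(1, 0.2, 0.95)
          cm[tid, ] <- stats::rnbinom(n_samples, mu = 60, size = 5) + 1
        } else {
          padj <- stats::runif(1, 0.3, 0.95)
          cm[tid, ] <- c(rep(1, min(4L, n_samples)),
                         rep(0, max(0L, n_samples - 4L)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tid, comparison_id = "challenge_vs_control",
          lfc = stats::rnorm(1, 0, 2), padj = padj,
          stringsAsFactors = FALSE)
      }
      de[[exp_id]] <- do.call(rbind, rows)
      counts[[exp_id]] <- cm
    }
    list(de = de, counts = counts, gene_map = gene_map,
         truth = status_by_experiment)
  })
}
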