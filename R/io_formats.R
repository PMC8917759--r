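#' @importFrom utils read.delim write.table head tail
#' @importFrom stats median sd cor cutree hclust as.dist prcomp pt quantile setNames
NULL

# Internal coordinate convention: 0-based half-open intervals everywhere.
# External formats (GFF3, domain-scan tables) are 1-based inclusive; the
# conversion happens at the I/O boundary and nowhere else.

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' @param start,end integer vectors, 1-based inclusive (`start <= end`).
#' @return A two-column matrix with columns `start` (0-based) and `end`
#'   (exclusive).
#' @keywords internal
to_internal <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert 0-based half-open coordinates back to 1-based inclusive
#' @param start,end integer vectors, 0-based half-open.
#' @return A two-column matrix with 1-based inclusive `start`, `end`.
#' @keywords internal
to_external <- function(start, end) {
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and enforces the package's record
#' contract: ids unique and nonempty, residues uppercased, terminal stop
#' symbols (`*`) stripped.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `residues`,
#'   one row per record, in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  res <- toupper(as.character(set))
  res <- gsub("\\*+$", "", gsub("^\\*+", "", res))
  if (any(!nzchar(res))) stop("empty sequence for id: ", id[!nzchar(res)][1])
  data.frame(id = id, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records data.frame with `id`, `description`, `residues` columns
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features linked by `ID`/`Parent` attributes.
#' GFF3 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A list of gene models. Each element is a list with fields
#'   `gene_id`, `chromosome`, `strand`, `start`, `end` (gene span,
#'   internal coordinates) and `transcripts`, itself a named list mapping
#'   transcript id to an exon matrix (columns `start`, `end`, 0-based
#'   half-open, sorted, non-overlapping).
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("no features in GFF3 file: ", path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) stop("malformed GFF3 line ", bad[1], " in ", path)
  f <- do.call(rbind, f)
  type <- f[, 3]
  start <- suppressWarnings(as.integer(f[, 4]))
  end <- suppressWarnings(as.integer(f[, 5]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinate in ", path)
  if (any(end < start)) {
    stop("GFF3 feature with end < start at line ",
         which(end < start)[1], " in ", path)
  }
  attr_field <- f[, 9]
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  ids <- get_attr(attr_field, "ID")
  parents <- get_attr(attr_field, "Parent")

  genes <- which(type == "gene")
  mrnas <- which(type %in% c("mRNA", "transcript"))
  exons <- which(type == "exon")
  if (!length(genes)) stop("no gene features in ", path)
  if (anyNA(ids[genes])) stop("gene feature without ID in ", path)
  if (anyNA(ids[mrnas])) stop("mRNA feature without ID in ", path)
  mrna_parent <- parents[mrnas]
  if (anyNA(mrna_parent)) stop("mRNA feature without Parent in ", path)
  exon_parent <- parents[exons]
  if (anyNA(exon_parent)) stop("exon feature without Parent in ", path)
  unknown <- setdiff(exon_parent, ids[mrnas])
  if (length(unknown)) {
    stop("exon with no parent transcript: ", unknown[1])
  }

  mrna_ids <- ids[mrnas]
  out <- lapply(genes, function(g) {
    gid <- ids[g]
    tix <- mrnas[mrna_parent == gid]
    transcripts <- list()
    for (t in tix) {
      tid <- ids[t]
      eix <- exons[exon_parent == tid]
      if (!length(eix)) stop("transcript with no exons: ", tid)
      ex <- to_internal(start[eix], end[eix])
      ex <- ex[order(ex[, 1]), , drop = FALSE]
      if (nrow(ex) > 1L && any(ex[-1L, 1] < ex[-nrow(ex), 2])) {
        stop("overlapping exons in transcript: ", tid)
      }
      transcripts[[tid]] <- ex
    }
    list(gene_id = gid, chromosome = f[g, 1], strand = f[g, 7],
         start = start[g] - 1L, end = end[g], transcripts = transcripts)
  })
  names(out) <- ids[genes]
  out
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]; internal 0-based half-open coordinates are
#' converted back to 1-based inclusive on output.
#'
#' @param genes List of gene models as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    ext <- to_external(g$start, g$end)
    writeLines(paste(g$chromosome, "iapfam", "gene", ext[1], ext[2], ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      text <- to_external(min(ex[, 1]), max(ex[, 2]))
      writeLines(paste(g$chromosome, "iapfam", "mRNA", text[1], text[2], ".",
                       g$strand, ".",
                       paste0("ID=", tid, ";Parent=", g$gene_id), sep = "\t"),
                 con)
      for (i in seq_len(nrow(ex))) {
        eext <- to_external(ex[i, 1], ex[i, 2])
        writeLines(paste(g$chromosome, "iapfam", "exon", eext[1], eext[2], ".",
                         g$strand, ".", paste0("Parent=", tid), sep = "\t"),
                   con)
      }
    }
  }
  invisible(path)
}

#' Number of exons per transcript of a gene model
#' @param gene A single gene model from [read_gff3()].
#' @return Named integer vector, one entry per transcript.
#' @export
exon_counts <- function(gene) {
  vapply(gene$transcripts, nrow, integer(1))
}

#' Read an InterProScan-style domain-scan table
#'
#' Expects a header line and tab-separated columns `protein_id`,
#' `source_db`, `accession`, `description`, `start`, `end`, `e_value`.
#' Coordinates are 1-based inclusive residue positions and are converted
#' to 0-based half-open. A literal `-` in the E-value column is read as
#' missing.
#'
#' @param path Path to the table.
#' @return data.frame of hits, grouped by protein and sorted by start
#'   within each protein, with internal coordinates.
#' @export
read_domain_scan <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_id", "source_db", "accession", "description",
            "start", "end", "e_value")
  if (!all(need %in% names(tab))) {
    stop("domain-scan table must have columns: ", paste(need, collapse = ", "))
  }
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1] + 1L, " of ", path)
  }
  if (any(start < 1L) || any(end < 1L)) {
    stop("negative or zero coordinate at line ",
         which(start < 1L | end < 1L)[1] + 1L, " of ", path)
  }
  ev <- rep(NA_real_, nrow(tab))
  has_ev <- tab$e_value != "-" & nzchar(tab$e_value)
  ev[has_ev] <- suppressWarnings(as.numeric(tab$e_value[has_ev]))
  if (anyNA(ev[has_ev])) {
    stop("malformed E-value at line ",
         which(has_ev)[which(is.na(ev[has_ev]))[1]] + 1L, " of ", path)
  }
  if (any(ev < 0, na.rm = TRUE)) stop("negative E-value in ", path)
  int <- to_internal(start, end)
  if (any(int[, 1] >= int[, 2])) {
    stop("empty domain interval at line ",
         which(int[, 1] >= int[, 2])[1] + 1L, " of ", path)
  }
  out <- data.frame(protein_id = tab$protein_id, source_db = tab$source_db,
                    accession = tab$accession, description = tab$description,
                    start = int[, 1], end = int[, 2], e_value = ev,
                    stringsAsFactors = FALSE)
  out[order(out$protein_id, out$start), , drop = FALSE]
}

#' Write a domain-scan table
#' @param hits data.frame as returned by [read_domain_scan()] (internal
#'   coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_scan <- function(hits, path) {
  ext <- to_external(hits$start, hits$end)
  out <- data.frame(protein_id = hits$protein_id, source_db = hits$source_db,
                    accession = hits$accession, description = hits$description,
                    start = ext[, 1], end = ext[, 2],
                    e_value = ifelse(is.na(hits$e_value), "-",
                                     format(hits$e_value, trim = TRUE)),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Newick tree with bootstrap supports
#'
#' Internal node labels are interpreted as bootstrap support values
#' (the RAxML convention).
#'
#' @param path Path to a file containing a single Newick tree.
#' @return An [ape::read.tree()] `phylo` object with an added numeric
#'   `node.support` vector (NA where no label was present).
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) stop("unbalanced parentheses in Newick file: ", path)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label in tree: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  }
  sup <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    lab[!nzchar(lab)] <- NA
    sup <- suppressWarnings(as.numeric(lab))
  }
  if (any(sup < 0 | sup > 100, na.rm = TRUE)) {
    stop("bootstrap support outside [0, 100] in ", path)
  }
  tree$node.support <- sup
  tree
}

#' Read a differential-expression result table
#'
#' Tab-separated with header; columns `transcript_id`, `comparison_id`,
#' `lfc`, `padj`.
#'
#' @param path Path to the table.
#' @return data.frame with one row per transcript x comparison.
#' @export
read_de_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "comparison_id", "lfc", "padj")
  if (!all(need %in% names(tab))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE)) {
    stop("padj outside [0, 1] in ", path)
  }
  key <- paste(tab$transcript_id, tab$comparison_id)
  if (anyDuplicated(key)) {
    stop("duplicate transcript x comparison row in ", path, ": ",
         key[duplicated(key)][1])
  }
  tab[need]
}

#' Read an expression matrix with sample metadata
#'
#' @param expr_path Tab-separated genes x samples matrix; first column
#'   holds the gene/transcript id.
#' @param meta_path Tab-separated sample metadata with columns `sample_id`
#'   and `trait` (and optionally `batch`).
#' @return List with `matrix` (numeric, rownames = ids) and `metadata`
#'   (data.frame, rows in matrix column order).
#' @export
read_expression <- function(expr_path, meta_path) {
  stopifnot(file.exists(expr_path), file.exists(meta_path))
  tab <- read.delim(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate id in expression matrix: ", ids[duplicated(ids)][1])
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "trait") %in% names(meta))) {
    stop("sample metadata must have columns sample_id and trait")
  }
  if (!setequal(colnames(m), meta$sample_id)) {
    stop("expression matrix samples and metadata samples differ")
  }
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(matrix = m, metadata = meta)
}

#' Write an expression matrix and its sample metadata
#' @param expr list as from [read_expression()].
#' @param expr_path,meta_path Output paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(expr, expr_path, meta_path) {
  tab <- data.frame(id = rownames(expr$matrix), expr$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$metadata, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(expr_path)
}
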