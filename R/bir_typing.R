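# BIR domain typing against a bundled reference alignment.
#
# Canonical numbering (positions 1..100) follows the bundled reference
# alignment; key positions 34, 57, 60, 76, 77, 80, 81, 82, 84 sit in the
# zinc-coordinating core and the alpha-3/alpha-4 helix regions used for
# classification. The bundled alignment is a constructed (synthetic)
# consensus-backbone stand-in for a model-organism BIR alignment: typing
# depends only on residues at canonical positions, never on the backbone.

#' Load the bundled BIR reference alignment
#'
#' The reference ships as a gap-free alignment of Type I and Type II BIR
#' sequences (synthetic, consensus-backbone) plus a positions table
#' defining the canonical numbering, the 9 key classification positions
#' and the 15 canonically conserved positions.
#'
#' @return List with `alignment` (named character vector of aligned
#'   sequences), `positions` (data.frame), `consensus` (character
#'   scalar), `key_positions` and `conserved_positions` (integer
#'   vectors of canonical positions).
#' @export
load_bir_reference <- function() {
  fa <- system.file("extdata", "bir_reference_alignment_synthetic.fasta",
                    package = "iapfam", mustWork = TRUE)
  ptsv <- system.file("extdata", "bir_reference_positions.tsv",
                      package = "iapfam", mustWork = TRUE)
  recs <- read_fasta(fa)
  pos <- read.delim(ptsv, stringsAsFactors = FALSE)
  list(alignment = setNames(recs$residues, recs$id),
       positions = pos,
       consensus = paste(pos$consensus_residue, collapse = ""),
       key_positions = pos$canonical[pos$is_key],
       conserved_positions = pos$canonical[pos$is_conserved15])
}

#' Anchor a query BIR sequence to the canonical reference numbering
#'
#' Globally aligns the reference consensus (affine gaps, BLOSUM62)
#' within the query — query flanks are free, the full reference must
#' align — and converts the alignment into a monotone map between query
#' residue indices and canonical positions.
#'
#' @param query Amino-acid string (length >= 20).
#' @param ref Reference from [load_bir_reference()].
#' @param score_floor Minimum alignment score below which the sequence is
#'   rejected as not anchorable (likely not a BIR).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return List with `query_to_canonical` (integer vector over query
#'   residues, NA where unaligned), `canonical_to_query` (integer vector
#'   over canonical positions, NA at deletions) and `score`.
#' @export
anchor_to_reference <- function(query, ref = load_bir_reference(),
                                score_floor = 100,
                                gap_opening = 10, gap_extension = 1) {
  stopifnot(is.character(query), length(query) == 1L)
  if (nchar(query) < 20L) stop("query too short to anchor (< 20 residues)")
  blosum <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(ref$consensus),
    subject = Biostrings::AAString(query),
    type = "global-local", substitutionMatrix = blosum,
    gapOpening = gap_opening, gapExtension = gap_extension)
  sc <- Biostrings::score(pa)
  if (sc < score_floor) {
    stop("Unanchorable: alignment score ", round(sc, 1), " below floor ",
         score_floor, "; sequence is likely not a BIR domain")
  }
  ali_ref <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  ali_qry <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  n_can <- nchar(ref$consensus)
  q2c <- rep(NA_integer_, nchar(query))
  c2q <- rep(NA_integer_, n_can)
  ci <- 0L
  qi <- Biostrings::start(Biostrings::subject(pa)) - 1L
  for (k in seq_along(ali_ref)) {
    rgap <- ali_ref[k] == "-"
    qgap <- ali_qry[k] == "-"
    if (!rgap) ci <- ci + 1L
    if (!qgap) qi <- qi + 1L
    if (!rgap && !qgap) {
      q2c[qi] <- ci
      c2q[ci] <- qi
    }
  }
  list(query_to_canonical = q2c, canonical_to_query = c2q, score = sc)
}

# BLOSUM62 lookup, cached per session.
get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Extract residues at the canonical key and conserved positions
#'
#' @param query Amino-acid string that was anchored.
#' @param anchoring Result of [anchor_to_reference()] for `query`.
#' @param ref Reference from [load_bir_reference()].
#' @return A `key_residues` object: list with `residues` (named character
#'   vector over the union of key and conserved canonical positions,
#'   `"-"` at deletions) and `deletion_span_over_80` (TRUE when a run of
#'   >= 3 consecutive deleted canonical positions covers position 80).
#' @export
extract_key_residues <- function(query, anchoring,
                                 ref = load_bir_reference()) {
  pos <- sort(union(ref$key_positions, ref$conserved_positions))
  qchars <- strsplit(query, "")[[1]]
  c2q <- anchoring$canonical_to_query
  res <- vapply(pos, function(p) {
    qi <- c2q[p]
    if (is.na(qi)) "-" else qchars[qi]
  }, "")
  names(res) <- as.character(pos)
  del <- is.na(c2q)
  r <- rle(del)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  covered <- any(r$values & r$lengths >= 3L & starts <= 80L & ends >= 80L)
  structure(list(residues = res, deletion_span_over_80 = covered),
            class = "key_residues")
}

#' Construct a key-residue set directly
#'
#' Convenience constructor, mainly for tests and for the synthetic
#' generator's truth records.
#'
#' @param residues Named character vector, names = canonical positions.
#' @param deletion_span_over_80 Logical flag.
#' @return A `key_residues` object.
#' @export
key_residues <- function(residues, deletion_span_over_80 = FALSE) {
  stopifnot(!is.null(names(residues)))
  structure(list(residues = residues,
                 deletion_span_over_80 = isTRUE(deletion_span_over_80)),
            class = "key_residues")
}

#' The default BIR type rule precedence
#'
#' Novel single-position diagnostics come before the broad conserved
#' patterns: a Threonine at the first zinc-coordinating Cysteine (57) or
#' a 3-residue deletion over position 80 is more specific evidence than a
#' conserved Type I/II match.
#' @return Character vector of type names in matching order.
#' @export
bir_type_precedence <- function() {
  c("NZBIR", "TypeY", "TypeX", "TypeII", "TypeI", "TypeII_like", "TypeI_like")
}

#' Classify a BIR domain from its key residues
#'
#' Pure total function implementing the residue rules:
#' * `NZBIR` — Threonine replaces the first zinc-coordinating Cysteine
#'   (position 57).
#' * `TypeY` — loss of three residues spanning conserved position 80.
#' * `TypeX` — Glycine at 80 and Arginine at 82.
#' * `TypeII` — E or Q at 76, H77, W or H at 80, C84.
#' * `TypeI` — H77, V or L at 80, C84.
#' * `TypeII_like` — E76 immediately before the conserved H77, without
#'   the full Type II pattern.
#' * `TypeI_like` — hydrophobic residue (I, V, L) at 80 and/or Serine at
#'   81, without any pattern above.
#' * `Unclassified` otherwise.
#'
#' @param k A `key_residues` object.
#' @param precedence Order in which rules are tried; see
#'   [bir_type_precedence()].
#' @return A single type name.
#' @export
classify_bir <- function(k, precedence = bir_type_precedence()) {
  stopifnot(inherits(k, "key_residues"))
  r <- function(p) {
    v <- k$residues[as.character(p)]
    if (is.na(v) || is.null(v)) "-" else unname(v)
  }
  rules <- list(
    NZBIR = function() r(57) == "T",
    TypeY = function() isTRUE(k$deletion_span_over_80),
    TypeX = function() r(80) == "G" && r(82) == "R",
    TypeII = function() r(76) %in% c("E", "Q") && r(77) == "H" &&
      r(80) %in% c("W", "H") && r(84) == "C",
    TypeI = function() r(77) == "H" && r(80) %in% c("V", "L") &&
      r(84) == "C",
    TypeII_like = function() r(76) == "E" && r(77) == "H",
    TypeI_like = function() r(80) %in% c("I", "V", "L") || r(81) == "S"
  )
  stopifnot(all(precedence %in% names(rules)))
  for (ty in precedence) {
    if (isTRUE(rules[[ty]]())) return(ty)
  }
  "Unclassified"
}

#' Type every BIR domain of a protein
#'
#' Takes the protein's residues and the spans of its BIR domain-scan
#' hits, anchors each BIR subsequence to the reference and classifies it.
#' BIR domains whose evidence lacks a CDD-source hit are flagged
#' `bir_star` (detected by the broader scan only).
#'
#' @param protein_id Protein identifier (carried into the output).
#' @param residues Full protein amino-acid string.
#' @param bir_spans data.frame with columns `start`, `end` (0-based
#'   half-open spans of BIR hits on the protein) and optionally
#'   `has_cdd` (logical).
#' @param ref Reference from [load_bir_reference()].
#' @param flank Extra residues taken either side of the hit span before
#'   anchoring (the scan spans are often tight).
#' @param ... Passed to [anchor_to_reference()].
#' @return data.frame of BIR calls: `protein_id`, `bir_index`, `start`,
#'   `end`, `bir_type`, `bir_star`, the residues at the 9 key positions,
#'   and a list-column `key_residues` with the full objects.
#' @export
call_birs <- function(protein_id, residues, bir_spans,
                      ref = load_bir_reference(), flank = 10L, ...) {
  if (nrow(bir_spans) == 0L) {
    return(data.frame(protein_id = character(), bir_index = integer(),
                      start = integer(), end = integer(),
                      bir_type = character(), bir_star = logical()))
  }
  bir_spans <- bir_spans[order(bir_spans$start), , drop = FALSE]
  has_cdd <- if ("has_cdd" %in% names(bir_spans)) bir_spans$has_cdd else
    rep(TRUE, nrow(bir_spans))
  n <- nchar(residues)
  calls <- vector("list", nrow(bir_spans))
  for (i in seq_len(nrow(bir_spans))) {
    s <- max(0L, bir_spans$start[i] - flank)
    e <- min(n, bir_spans$end[i] + flank)
    sub <- substr(residues, s + 1L, e)
    anc <- anchor_to_reference(sub, ref, ...)
    kr <- extract_key_residues(sub, anc, ref)
    calls[[i]] <- list(type = classify_bir(kr), kr = kr)
  }
  key9 <- as.character(ref$key_positions)
  out <- data.frame(
    protein_id = protein_id,
    bir_index = seq_len(nrow(bir_spans)),
    start = bir_spans$start, end = bir_spans$end,
    bir_type = vapply(calls, function(x) x$type, ""),
    bir_star = !has_cdd,
    stringsAsFactors = FALSE)
  for (p in key9) {
    out[[paste0("pos", p)]] <- vapply(calls, function(x) {
      v <- x$kr$residues[p]
      if (is.na(v)) "-" else unname(v)
    }, "")
  }
  out$key_residues <- I(lapply(calls, function(x) x$kr))
  out
}

#' Census of positions conserved across a set of BIR domains
#'
#' @param calls List of `key_residues` objects.
#' @param positions Canonical positions to examine (default: the 15
#'   canonically conserved positions of the bundled reference).
#' @return Integer vector of positions at which every input shares the
#'   same non-gap residue.
#' @export
census_conserved_positions <- function(calls,
                                       positions = NULL) {
  stopifnot(length(calls) >= 1L)
  if (is.null(positions)) positions <- load_bir_reference()$conserved_positions
  keep <- vapply(positions, function(p) {
    res <- vapply(calls, function(k) {
      v <- k$residues[as.character(p)]
      if (is.null(v) || is.na(v)) "-" else unname(v)
    }, "")
    length(unique(res)) == 1L && res[1] != "-"
  }, logical(1))
  positions[keep]
}
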