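# Domain-architecture typing: turn a transcript's domain hits into an
# ordered N->C token string, match it against a rule table of named
# architecture types (including the novel oyster BIRC9-12), and assign
# consensus architectures on bootstrap-supported phylogenetic clusters.

BIR_TOKENS <- c("TI", "TII", "TI_like", "TII_like", "TX", "TY", "NZBIR",
                "BIR_STAR")

# bir_type (typing module vocabulary) -> architecture token
bir_type_token <- c(TypeI = "TI", TypeII = "TII", TypeI_like = "TI_like",
                    TypeII_like = "TII_like", TypeX = "TX", TypeY = "TY",
                    NZBIR = "NZBIR", Unclassified = "BIR_STAR")

#' Default accession-to-token map for non-BIR domains
#'
#' Maps InterPro/CDD/Gene3D accessions to architecture tokens; accessions
#' outside the map become `OTHER` tokens, which are ignored during rule
#' matching.
#' @return Named character vector: accession -> token.
#' @export
default_token_map <- function() {
  c("cd16713" = "RING", "IPR013083" = "RING", "IPR001841" = "RING",
    "G3DSA:1.10.533.10" = "DD",
    "IPR015940" = "UBA", "cd14321" = "UBA",
    "IPR016135" = "UBC", "IPR000608" = "UBC",
    "IPR022103" = "BIRC6_DOMAIN",
    "IPR019775" = "WD40", "IPR036322" = "WD40")
}

#' Tokenize a transcript's domain architecture
#'
#' Non-BIR hits are mapped to tokens through `token_map`; hits of the
#' same token category that overlap are merged into one token (the
#' longest span wins). BIR spans are replaced by their typed tokens from
#' the BIR calls (`bir_star` calls and `Unclassified` types become
#' `BIR_STAR`).
#'
#' @param hits Domain-scan hits for one protein (internal coordinates).
#' @param bir_calls BIR calls for the same protein from [call_birs()]
#'   (may have zero rows).
#' @param token_map Accession -> token map; see [default_token_map()].
#' @return Character vector of tokens in N->C order.
#' @export
tokenize_architecture <- function(hits, bir_calls = NULL,
                                  token_map = default_token_map()) {
  segs <- list()
  if (!is.null(bir_calls) && nrow(bir_calls) > 0L) {
    if (nrow(hits) > 0L) {
      covered <- vapply(seq_len(nrow(bir_calls)), function(i) {
        any(hits$start <= bir_calls$start[i] + 5L &
              hits$end >= bir_calls$end[i] - 5L)
      }, logical(1))
      if (!all(covered)) {
        stop("BIR call without a covering domain hit: index ",
             which(!covered)[1])
      }
    }
    tok <- unname(bir_type_token[bir_calls$bir_type])
    tok[bir_calls$bir_star] <- "BIR_STAR"
    segs[[1]] <- data.frame(start = bir_calls$start, end = bir_calls$end,
                            token = tok, stringsAsFactors = FALSE)
  }
  if (nrow(hits) > 0L) {
    tk <- unname(token_map[hits$accession])
    is_bir <- is_bir_hit(hits) & !(hits$accession %in% names(token_map))
    # hits covered by a BIR call are represented by the typed call
    if (!is.null(bir_calls) && nrow(bir_calls) > 0L) {
      covered_by_call <- vapply(seq_len(nrow(hits)), function(i) {
        any(hits$start[i] < bir_calls$end & hits$end[i] > bir_calls$start)
      }, logical(1))
      is_bir <- is_bir | covered_by_call
    }
    tk[is.na(tk) & !is_bir] <- "OTHER"
    keep <- !is.na(tk)  # BIR hits themselves are represented by calls
    if (any(keep)) {
      segs[[length(segs) + 1L]] <- data.frame(
        start = hits$start[keep], end = hits$end[keep], token = tk[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) return(character(0))
  seg <- do.call(rbind, segs)
  # merge overlapping hits of the same token category: a sorted sweep
  # collapses each connected overlap run into one token
  merged <- list()
  for (tk in unique(seg$token)) {
    s <- seg[seg$token == tk, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    cur_start <- s$start[1]; cur_end <- s$end[1]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] < cur_end) {
        cur_end <- max(cur_end, s$end[i])
      } else {
        merged[[length(merged) + 1L]] <- list(start = cur_start,
                                              token = tk)
        cur_start <- s$start[i]; cur_end <- s$end[i]
      }
    }
    merged[[length(merged) + 1L]] <- list(start = cur_start, token = tk)
  }
  starts <- vapply(merged, `[[`, numeric(1), "start")
  toks <- vapply(merged, `[[`, "", "token")
  toks[order(starts)]
}

#' The default architecture rule table
#'
#' Ordered list of named rules; each rule is a list of acceptable token
#' patterns (N->C). A pattern element `"ANY_BIR+"` matches one or more
#' consecutive BIR-type tokens. Matching drops `OTHER` tokens first and
#' takes the first rule, in table order, with an exactly matching
#' pattern; the table is ordered most-specific (longest) first.
#'
#' Textually defined types: BIRC2/3-like (TI-TII-DD-RING,
#' TI-TII-DD-UBA-RING, or NZBIR-TII-UBA-DD-RING), BIRC6-like (BIR
#' domains, the BIRC6 domain, UBC, WD40 optional), BIRC11
#' (TII-DD-RING or BIR*-DD-RING), BIRC10 (TII-DD), BIRC7-like
#' (TII-RING), BIRC5-like (a single BIR and nothing else). The
#' remaining patterns (DIAP1-like, BIRC4-like, BIRC9, BIRC12) are
#' editable placeholders and results that depend on them are
#' provisional.
#'
#' @return Named list of pattern lists.
#' @export
default_architecture_rules <- function() {
  list(
    "BIRC6-like" = list(c("ANY_BIR+", "BIRC6_DOMAIN", "UBC", "WD40"),
                        c("ANY_BIR+", "BIRC6_DOMAIN", "UBC")),
    "BIRC4-like" = list(c("TI", "TII", "TII", "UBA", "RING")),
    "BIRC2/3-like" = list(c("TI", "TII", "DD", "UBA", "RING"),
                          c("NZBIR", "TII", "UBA", "DD", "RING"),
                          c("TI", "TII", "DD", "RING")),
    "BIRC12" = list(c("TII", "TII", "DD", "RING")),
    "BIRC9" = list(c("TII", "TII", "RING")),
    "DIAP1-like" = list(c("TI", "TII", "RING")),
    "BIRC11" = list(c("TII", "DD", "RING"), c("BIR_STAR", "DD", "RING")),
    "BIRC10" = list(c("TII", "DD")),
    "BIRC7-like" = list(c("TII", "RING")),
    "BIRC5-like" = list(c("TII"), c("TI"))
  )
}

match_pattern <- function(tokens, pattern) {
  # exact sequence match with ANY_BIR+ greedily matching >=1 BIR tokens
  rec <- function(ti, pi) {
    if (pi > length(pattern)) return(ti > length(tokens))
    if (ti > length(tokens)) return(FALSE)
    el <- pattern[pi]
    if (el == "ANY_BIR+") {
      if (!(tokens[ti] %in% BIR_TOKENS)) return(FALSE)
      ti2 <- ti
      while (ti2 <= length(tokens) && tokens[ti2] %in% BIR_TOKENS) {
        if (rec(ti2 + 1L, pi + 1L)) return(TRUE)
        ti2 <- ti2 + 1L
      }
      FALSE
    } else {
      tokens[ti] == el && rec(ti + 1L, pi + 1L)
    }
  }
  rec(1L, 1L)
}

#' Classify a token string against the architecture rule table
#'
#' @param tokens Character vector of tokens in N->C order.
#' @param rules Rule table; see [default_architecture_rules()].
#' @return The matched type name, or `"NOVEL"` when no rule matches.
#' @export
classify_architecture <- function(tokens,
                                  rules = default_architecture_rules()) {
  stopifnot(length(tokens) >= 1L)
  tokens <- tokens[tokens != "OTHER"]
  if (!length(tokens)) return("NOVEL")
  for (name in names(rules)) {
    for (pattern in rules[[name]]) {
      if (match_pattern(tokens, pattern)) return(name)
    }
  }
  "NOVEL"
}

#' Extract well-supported mixed-species clusters from a tree
#'
#' Finds maximal (outermost, non-nested) clades whose bootstrap support
#' exceeds `support_min` and that contain at least one leaf from every
#' required species.
#'
#' @param tree A `phylo` tree from [read_newick()] (with
#'   `node.support`).
#' @param species Named character vector mapping leaf label -> species
#'   tag; every leaf must be covered.
#' @param support_min Support threshold (strict; default 90).
#' @param require_species Species tags that must all be present in a
#'   cluster (default both oyster tags `c("Cv", "Cg")`).
#' @return List of clusters; each is a list with `cluster_id`, `members`
#'   (leaf labels), `support`, `species` (tags present).
#' @export
extract_supported_clusters <- function(tree, species, support_min = 90,
                                       require_species = c("Cv", "Cg")) {
  if (!all(tree$tip.label %in% names(species))) {
    stop("unlabelled species for leaf: ",
         setdiff(tree$tip.label, names(species))[1])
  }
  ntip <- length(tree$tip.label)
  nodes <- seq_len(tree$Nnode) + ntip
  qualifies <- logical(max(nodes))
  leafsets <- vector("list", max(nodes))
  for (nd in nodes) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    leafsets[[nd]] <- tips
    sup <- tree$node.support[nd - ntip]
    sp <- unique(species[tips])
    qualifies[nd] <- !is.na(sup) && sup > support_min &&
      all(require_species %in% sp)
  }
  # outermost qualifying clades: drop any qualifying node whose leaf set
  # is a subset of another qualifying node's leaf set
  qn <- nodes[qualifies[nodes]]
  keep <- vapply(qn, function(nd) {
    !any(vapply(qn, function(other) {
      other != nd && all(leafsets[[nd]] %in% leafsets[[other]]) &&
        length(leafsets[[other]]) > length(leafsets[[nd]])
    }, logical(1)))
  }, logical(1))
  qn <- qn[keep]
  qn <- qn[order(vapply(qn, function(nd) min(match(leafsets[[nd]],
                                                   tree$tip.label)), 1))]
  lapply(seq_along(qn), function(i) {
    nd <- qn[i]
    list(cluster_id = paste0("cluster", i),
         members = leafsets[[nd]],
         support = tree$node.support[nd - ntip],
         species = unique(unname(species[leafsets[[nd]]])))
  })
}

#' Consensus architecture of a cluster
#'
#' @param members Character vector of member protein/transcript ids.
#' @param calls Named character vector: id -> architecture type.
#' @return List with `consensus` (type name, or tied types collapsed
#'   with "/"), `conserved` (TRUE when all members agree) and `mixed`
#'   (TRUE when they do not).
#' @export
cluster_consensus <- function(members, calls) {
  if (!length(members)) stop("empty cluster")
  if (!all(members %in% names(calls))) {
    stop("missing architecture call for: ",
         setdiff(members, names(calls))[1])
  }
  types <- unname(calls[members])
  tab <- sort(table(types), decreasing = TRUE)
  if (length(tab) == 1L) {
    return(list(consensus = names(tab), conserved = TRUE, mixed = FALSE))
  }
  top <- names(tab)[tab == max(tab)]
  consensus <- if (length(top) > 1L) paste(sort(top), collapse = "/") else top
  list(consensus = consensus, conserved = FALSE, mixed = TRUE)
}
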