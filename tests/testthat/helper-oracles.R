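# Independent oracles, written before the implementations they check and
# kept free of package internals: plain-R dynamic programming, direct
# formula evaluation, and exhaustive enumeration at toy sizes.

# Gotoh global alignment (affine gaps, gap of length L costs open+ext*L)
# returning the query-index -> reference-position map of one optimal
# alignment. Pure R, O(n*m) with explicit traceback.
oracle_global_map <- function(ref_seq, query, subst, open = 10, ext = 1) {
  a <- strsplit(ref_seq, "")[[1]]
  b <- strsplit(query, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -Inf
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) { X[i + 1, 1] <- -(open + ext * i); tX[i + 1, 1] <- 1L }
  for (j in seq_len(m)) { Y[1, j + 1] <- -(open + ext * j); tY[1, j + 1] <- 2L }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- subst[a[i], b[j]]
    cand <- c(M[i, j], X[i, j], Y[i, j])
    k <- which.max(cand)
    if (is.finite(cand[k])) { M[i + 1, j + 1] <- cand[k] + s; tM[i + 1, j + 1] <- k - 1L }
    cand <- c(M[i, j + 1] - (open + ext), X[i, j + 1] - ext,
              Y[i, j + 1] - (open + ext))
    k <- which.max(cand)
    X[i + 1, j + 1] <- cand[k]; tX[i + 1, j + 1] <- k - 1L
    cand <- c(M[i + 1, j] - (open + ext), X[i + 1, j] - (open + ext),
              Y[i + 1, j] - ext)
    k <- which.max(cand)
    Y[i + 1, j + 1] <- cand[k]; tY[i + 1, j + 1] <- k - 1L
  }
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])) - 1L
  i <- n; j <- m
  map <- rep(NA_integer_, m)
  while (i > 0 || j > 0) {
    if (state == 0L) {
      map[j] <- i
      state <- tM[i + 1, j + 1]; i <- i - 1L; j <- j - 1L
    } else if (state == 1L) {
      state <- tX[i + 1, j + 1]; i <- i - 1L
    } else {
      state <- tY[i + 1, j + 1]; j <- j - 1L
    }
  }
  map
}

# Direct-formula biweight midcorrelation for one pair (spec formula,
# no shared code with the package implementation).
oracle_bicor <- function(x, y) {
  tf <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    if (madv == 0) return(scale(v, center = TRUE, scale = FALSE)[, 1])
    u <- (v - med) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  xa <- tf(x); ya <- tf(y)
  val <- sum(xa * ya) / sqrt(sum(xa^2) * sum(ya^2))
  max(-1, min(1, val))
}

# Exhaustive tandem-array enumeration: every maximal contiguous run of
# IAP genes satisfying the gap and intervening-gene constraints.
oracle_tandem_runs <- function(gene_order, iap_ids, max_intervening,
                               max_gap) {
  runs <- list()
  for (chrom in unique(gene_order$chromosome)) {
    g <- gene_order[gene_order$chromosome == chrom, ]
    g <- g[order(g$start), ]
    idx <- which(g$gene_id %in% iap_ids)
    if (length(idx) < 2L) next
    ok_link <- function(a, b) {
      (b - a - 1L) <= max_intervening && (g$start[b] - g$end[a]) <= max_gap
    }
    i <- 1L
    while (i <= length(idx)) {
      j <- i
      while (j < length(idx) && ok_link(idx[j], idx[j + 1L])) j <- j + 1L
      if (j > i) runs[[length(runs) + 1L]] <- g$gene_id[idx[i:j]]
      i <- j + 1L
    }
  }
  runs
}

# Exhaustive supported-clade enumeration on an ape tree.
oracle_clusters <- function(tree, species, support_min, require_species) {
  ntip <- length(tree$tip.label)
  sets <- list()
  for (nd in seq_len(tree$Nnode) + ntip) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    sup <- tree$node.support[nd - ntip]
    if (!is.na(sup) && sup > support_min &&
        all(require_species %in% species[tips])) {
      sets[[length(sets) + 1L]] <- sort(tips)
    }
  }
  # keep maximal sets only
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      j != i && length(sets[[j]]) > length(sets[[i]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  unique(sets[keep])
}

# Brute-force interval merging for tokenization: same-token hits in one
# connected overlap component collapse to a single token anchored at the
# component's leftmost start. Uses explicit union-find over all pairs,
# unlike the package's sorted sweep.
oracle_token_order <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && df$token[i] == df$token[j] &&
        df$start[i] < df$end[j] && df$end[i] > df$start[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp_start <- as.vector(tapply(df$start, roots, min))
  comp_token <- as.vector(tapply(df$token, roots, function(x) x[1]))
  comp_token[order(comp_start)]
}

# Exhaustive direct-edge scan over all id pairs.
oracle_edges <- function(adj, labels, sig_mods, iap_ids, apo_ids, min_w) {
  out <- list()
  for (i in iap_ids) for (a in apo_ids) {
    if (i == a) next
    if (labels[i] == labels[a] && labels[i] %in% sig_mods &&
        adj[i, a] >= min_w) {
      out[[length(out) + 1L]] <- data.frame(iap_id = i, partner_id = a,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(iap_id = character(),
                                      partner_id = character()))
  res <- do.call(rbind, out)
  res[order(res$iap_id, res$partner_id), ]
}

blosum62_oracle <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
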