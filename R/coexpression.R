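# Weighted co-expression network analysis written from scratch:
# biweight midcorrelation, signed-hybrid adjacency, scale-free soft
# threshold selection with the small-sample fallback, topological
# overlap, static-cut module detection with eigengene merging,
# module-trait association, and direct IAP <-> apoptosis edge
# extraction.

#' Network construction parameters
#'
#' @param candidate_powers Soft-threshold powers to evaluate (default
#'   1:20).
#' @param scale_free_r2_min Signed scale-free fit R-squared a power must
#'   reach (default 0.8).
#' @param fallback_power Power used when no candidate satisfies the fit
#'   and there are fewer than 30 samples (default 9, the signed-hybrid
#'   small-sample convention).
#' @param min_module_size Smallest retained module (default 30).
#' @param merge_height Modules whose eigengenes correlate above
#'   `1 - merge_height` are merged (default 0.25).
#' @param cut_height_fracs Candidate static tree-cut heights, as
#'   fractions of the dendrogram's maximum merge height; the cut
#'   producing the most accepted modules wins (default a grid over
#'   0.5-0.999).
#' @param module_density_min A cluster is accepted as a module only if
#'   its mean within-cluster topological overlap is at least this
#'   multiple of the mean overlap between its members and the rest of
#'   the network (default 2); this keeps unstructured data module-free.
#' @param module_trait_p_max Module-trait significance ceiling (default
#'   0.05).
#' @param edge_adjacency_min Minimum adjacency for a reported direct
#'   edge (default 0.1).
#' @return A `network_config` list.
#' @export
network_config <- function(candidate_powers = 1:20,
                           scale_free_r2_min = 0.8,
                           fallback_power = 9L,
                           min_module_size = 30L,
                           merge_height = 0.25,
                           cut_height_fracs = c(seq(0.5, 0.95,
                                                    by = 0.05),
                                                seq(0.96, 0.999,
                                                    by = 0.005)),
                           module_density_min = 2,
                           module_trait_p_max = 0.05,
                           edge_adjacency_min = 0.1) {
  stopifnot(all(candidate_powers >= 1), scale_free_r2_min > 0,
            scale_free_r2_min < 1, fallback_power >= 1,
            min_module_size >= 2, merge_height > 0, merge_height < 1,
            all(cut_height_fracs > 0), all(cut_height_fracs < 1),
            module_density_min >= 1,
            module_trait_p_max > 0, module_trait_p_max < 1,
            edge_adjacency_min >= 0)
  structure(list(network_type = "signed_hybrid",
                 candidate_powers = as.integer(candidate_powers),
                 scale_free_r2_min = scale_free_r2_min,
                 fallback_power = as.integer(fallback_power),
                 min_module_size = as.integer(min_module_size),
                 merge_height = merge_height,
                 cut_height_fracs = cut_height_fracs,
                 module_density_min = module_density_min,
                 module_trait_p_max = module_trait_p_max,
                 edge_adjacency_min = edge_adjacency_min),
            class = "network_config")
}

#' Biweight midcorrelation of a single pair of vectors
#'
#' Tukey biweights around the median: `u_i = (x_i - med) / (9 mad)`
#' (unscaled median absolute deviation), weights
#' `w_i = (1 - u_i^2)^2` for `|u_i| < 1` and 0 otherwise; the
#' correlation is the weighted cross-product of the median-centred
#' vectors normalised by the weighted norms. A vector with zero MAD
#' falls back to its Pearson transform (mean-centred) for the pair.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @return Correlation in `[-1, 1]`.
#' @export
bicor_pair <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  tx <- bicor_transform(x)
  ty <- bicor_transform(y)
  if (is.null(tx) || is.null(ty)) return(0)
  max(-1, min(1, sum(tx * ty)))
}

# Returns the normalised biweight-transformed vector (or the Pearson
# transform on zero MAD), or NULL for a constant vector.
bicor_transform <- function(x) {
  med <- median(x)
  madx <- median(abs(x - med))
  if (madx == 0) {
    cx <- x - mean(x)
    nrm <- sqrt(sum(cx^2))
    if (nrm == 0) return(NULL)
    return(cx / nrm)
  }
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  v <- (x - med) * w
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) return(NULL)
  v / nrm
}

#' Biweight midcorrelation matrix
#'
#' @param expr Numeric matrix, rows = genes, columns = samples (>= 4).
#' @return Symmetric gene x gene correlation matrix, values clamped to
#'   `[-1, 1]`, unit diagonal. Constant genes yield 0 correlations with
#'   a warning.
#' @export
bicor_matrix <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 4L)
  tr <- apply(expr, 1L, function(x) {
    v <- bicor_transform(x)
    if (is.null(v)) rep(NA_real_, length(x)) else v
  })
  tr <- t(tr)  # genes x samples again
  bad <- apply(tr, 1L, anyNA)
  if (any(bad)) {
    warning(sum(bad), " constant gene(s); correlations reported as 0")
    tr[bad, ] <- 0
  }
  m <- tr %*% t(tr)
  m[m > 1] <- 1
  m[m < -1] <- -1
  diag(m) <- 1
  if (any(bad)) diag(m)[bad] <- 1
  dimnames(m) <- list(rownames(expr), rownames(expr))
  m
}

#' Signed-hybrid adjacency
#'
#' `a_ij = cor_ij ^ beta` for positive correlations, 0 otherwise;
#' `a_ii = 1`.
#'
#' @param cor_mat Symmetric correlation matrix in `[-1, 1]`.
#' @param beta Soft-threshold power.
#' @return Adjacency matrix in `[0, 1]`.
#' @export
adjacency_signed_hybrid <- function(cor_mat, beta) {
  stopifnot(beta >= 1)
  a <- ifelse(cor_mat > 0, cor_mat^beta, 0)
  diag(a) <- 1
  a
}

# Signed scale-free topology fit: bin log10 connectivity, regress
# log10(freq) on log10(mean k), R^2 signed by minus the slope sign.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  br <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 3L) return(NA_real_)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  ok <- !is.na(mean_k) & !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(NA_real_)
  lx <- log10(mean_k[ok])
  ly <- log10(freq[ok])
  if (sd(lx) == 0 || sd(ly) == 0) return(NA_real_)
  slope <- stats::cov(lx, ly) / stats::var(lx)
  -sign(slope) * cor(lx, ly)^2
}

#' Pick the soft-threshold power by scale-free fit
#'
#' For each candidate power the signed-hybrid adjacency is built and the
#' signed scale-free fit R-squared of the connectivity distribution is
#' computed. The chosen power is the smallest one reaching the fit
#' threshold; when none does and there are fewer than 30 samples, the
#' fallback power (9) is used. With >= 30 samples and no fitting power,
#' the power maximising the signed fit is returned.
#'
#' @param expr Numeric matrix, rows = genes, columns = samples.
#' @param cfg A [network_config()].
#' @param cor_mat Optional precomputed correlation matrix.
#' @return List with `beta`, `fit_table` (data.frame `power`, `r2`,
#'   `mean_k`) and `used_fallback`.
#' @export
pick_soft_threshold <- function(expr, cfg = network_config(),
                                cor_mat = NULL) {
  if (is.null(cor_mat)) cor_mat <- bicor_matrix(expr)
  powers <- cfg$candidate_powers
  r2 <- mean_k <- numeric(length(powers))
  for (i in seq_along(powers)) {
    a <- adjacency_signed_hybrid(cor_mat, powers[i])
    k <- rowSums(a) - 1
    if (all(k == 0)) stop("all connectivities zero at power ", powers[i])
    r2[i] <- scale_free_fit(k)
    mean_k[i] <- mean(k)
  }
  fit_table <- data.frame(power = powers, r2 = r2, mean_k = mean_k)
  ok <- which(!is.na(r2) & r2 >= cfg$scale_free_r2_min)
  if (length(ok)) {
    list(beta = powers[min(ok)], fit_table = fit_table,
         used_fallback = FALSE)
  } else if (ncol(expr) < 30L) {
    list(beta = cfg$fallback_power, fit_table = fit_table,
         used_fallback = TRUE)
  } else {
    list(beta = powers[which.max(r2)], fit_table = fit_table,
         used_fallback = FALSE)
  }
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j`; `TOM_ii = 1`.
#'
#' @param adj Adjacency matrix in `[0, 1]` with unit diagonal.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression
#' (samples x genes), sign-aligned to the module's mean expression
#' profile.
#'
#' @param expr Expression matrix (genes x samples) restricted to the
#'   module's genes.
#' @return Numeric vector over samples, unit variance.
#' @export
module_eigengene <- function(expr) {
  z <- t(scale(t(expr)))  # standardize each gene
  z[is.na(z)] <- 0
  sv <- svd(t(z), nu = 1, nv = 0)
  eg <- sv$u[, 1]
  avg <- colMeans(z)
  if (cor(eg, avg) < 0) eg <- -eg
  as.numeric(scale(eg))
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' followed by a static tree cut: candidate cut heights (fractions of
#' the maximum merge height) are scanned and the cut producing the most
#' accepted modules wins. A cluster is accepted when it reaches
#' `min_module_size` and its mean within-cluster topological overlap is
#' at least `module_density_min` times the mean background overlap —
#' unstructured data therefore yields no modules. Remaining genes get
#' label 0; accepted modules whose eigengenes correlate above
#' `1 - merge_height` are merged iteratively.
#'
#' @param expr Expression matrix, genes x samples.
#' @param adj Adjacency matrix for the same genes.
#' @param cfg A [network_config()].
#' @return List with `labels` (named integer vector, 0 = unassigned)
#'   and `eigengenes` (samples x modules matrix, columns named
#'   `ME<label>`).
#' @export
detect_modules <- function(expr, adj, cfg = network_config()) {
  n <- nrow(adj)
  ids <- rownames(adj)
  if (n < cfg$min_module_size) {
    return(list(labels = setNames(rep(0L, n), ids),
                eigengenes = NULL))
  }
  tom <- tom_similarity(adj)
  h <- hclust(as.dist(1 - tom), method = "average")
  accepted_of_cut <- function(raw) {
    sizes <- table(raw)
    big <- as.integer(names(sizes)[sizes >= cfg$min_module_size])
    ok <- logical(length(big))
    for (i in seq_along(big)) {
      member <- which(raw == big[i])
      outside <- setdiff(seq_len(n), member)
      if (!length(outside)) next  # spans the whole network: no signal
      within <- tom[member, member][upper.tri(diag(length(member)))]
      between <- tom[member, outside]
      ok[i] <- mean(within) >= cfg$module_density_min * mean(between)
    }
    big[ok]
  }
  best <- list(score = -1L, assigned = -1L, labels = integer(n))
  for (fr in sort(cfg$cut_height_fracs)) {
    raw <- cutree(h, h = fr * max(h$height))
    acc <- accepted_of_cut(raw)
    score <- length(acc)
    assigned <- sum(raw %in% acc)
    if (score > best$score ||
        (score == best$score && assigned > best$assigned)) {
      labels <- integer(n)
      for (i in seq_along(acc)) labels[raw == acc[i]] <- i
      best <- list(score = score, assigned = assigned, labels = labels)
    }
  }
  labels <- best$labels
  names(labels) <- ids
  labels <- merge_close_modules(expr, labels, cfg)
  egs <- eigengene_matrix(expr, labels)
  list(labels = labels, eigengenes = egs)
}

eigengene_matrix <- function(expr, labels) {
  mods <- sort(setdiff(unique(labels), 0L))
  if (!length(mods)) return(NULL)
  egs <- vapply(mods, function(m) {
    module_eigengene(expr[names(labels)[labels == m], , drop = FALSE])
  }, numeric(ncol(expr)))
  colnames(egs) <- paste0("ME", mods)
  rownames(egs) <- colnames(expr)
  egs
}

merge_close_modules <- function(expr, labels, cfg) {
  repeat {
    mods <- sort(setdiff(unique(labels), 0L))
    if (length(mods) < 2L) break
    egs <- eigengene_matrix(expr, labels)
    cm <- cor(egs)
    diag(cm) <- -Inf
    top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (max(cm) <= 1 - cfg$merge_height) break
    a <- mods[top[1]]; b <- mods[top[2]]
    labels[labels == b] <- a
    # relabel contiguously
    mods <- sort(setdiff(unique(labels), 0L))
    relab <- setNames(seq_along(mods), mods)
    labels[labels != 0L] <- relab[as.character(labels[labels != 0L])]
  }
  labels
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with the trait; the p
#' value comes from `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom (two-sided). A module is flagged significant iff
#' `p <= module_trait_p_max` AND it contains at least one IAP transcript
#' AND more than one apoptosis-related transcript (when those id sets
#' are supplied).
#'
#' @param eigengenes Samples x modules matrix from [detect_modules()].
#' @param trait Numeric/binary trait vector over samples.
#' @param labels Module labels (needed for the membership conditions).
#' @param iap_ids,apoptosis_ids Ids of IAP and apoptosis-related
#'   transcripts; `NULL` disables the corresponding membership
#'   condition.
#' @param cfg A [network_config()].
#' @return data.frame with `module`, `r`, `p`, `n_iap`, `n_apoptosis`,
#'   `significant`.
#' @export
module_trait_significance <- function(eigengenes, trait, labels,
                                      iap_ids = NULL, apoptosis_ids = NULL,
                                      cfg = network_config()) {
  stopifnot(nrow(eigengenes) == length(trait))
  if (sd(trait) == 0) stop("constant trait")
  n <- length(trait)
  mods <- as.integer(sub("^ME", "", colnames(eigengenes)))
  res <- lapply(seq_along(mods), function(i) {
    r <- cor(eigengenes[, i], trait)
    r2 <- min(r^2, 1 - 1e-15)
    tstat <- r * sqrt(n - 2) / sqrt(1 - r2)
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    member <- names(labels)[labels == mods[i]]
    n_iap <- if (is.null(iap_ids)) NA_integer_ else
      length(intersect(member, iap_ids))
    n_apo <- if (is.null(apoptosis_ids)) NA_integer_ else
      length(intersect(member, apoptosis_ids))
    sig <- p <= cfg$module_trait_p_max &&
      (is.null(iap_ids) || n_iap >= 1L) &&
      (is.null(apoptosis_ids) || n_apo > 1L)
    data.frame(module = mods[i], r = r, p = p, n_iap = n_iap,
               n_apoptosis = n_apo, significant = sig)
  })
  do.call(rbind, res)
}

#' Build a full co-expression network
#'
#' Convenience wrapper running correlation, soft-threshold selection,
#' adjacency, module detection and (optionally) module-trait testing.
#'
#' @param expr Expression matrix, genes x samples.
#' @param trait Optional trait vector over samples.
#' @param iap_ids,apoptosis_ids Optional id sets for the module
#'   significance membership conditions.
#' @param cfg A [network_config()].
#' @param beta Optional fixed power (skips soft-threshold selection).
#' @return A `coexpr_network` object: list with `cor`, `beta`,
#'   `fit_table`, `adjacency`, `labels`, `eigengenes`, `trait`,
#'   `module_trait` (NULL without a trait) and `config`.
#' @export
build_network <- function(expr, trait = NULL, iap_ids = NULL,
                          apoptosis_ids = NULL, cfg = network_config(),
                          beta = NULL) {
  cm <- bicor_matrix(expr)
  fit <- NULL
  used_fallback <- FALSE
  if (is.null(beta)) {
    st <- pick_soft_threshold(expr, cfg, cor_mat = cm)
    beta <- st$beta
    fit <- st$fit_table
    used_fallback <- st$used_fallback
  }
  adj <- adjacency_signed_hybrid(cm, beta)
  det <- detect_modules(expr, adj, cfg)
  mt <- NULL
  if (!is.null(trait) && !is.null(det$eigengenes)) {
    mt <- module_trait_significance(det$eigengenes, trait, det$labels,
                                    iap_ids, apoptosis_ids, cfg)
  }
  structure(list(cor = cm, beta = beta, fit_table = fit,
                 used_fallback = used_fallback, adjacency = adj,
                 labels = det$labels, eigengenes = det$eigengenes,
                 trait = trait, module_trait = mt, config = cfg),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$labels), 0L))
  cat("Co-expression network (signed hybrid, beta =", x$beta,
      if (x$used_fallback) "[small-sample fallback]" else "", ")\n")
  cat("  genes:", length(x$labels), " modules:", n_mod,
      " unassigned:", sum(x$labels == 0L), "\n")
  if (!is.null(x$module_trait)) {
    cat("  significant trait modules:",
        sum(x$module_trait$significant), "\n")
  }
  invisible(x)
}

#' @export
summary.coexpr_network <- function(object, ...) {
  tab <- table(factor(object$labels))
  out <- list(beta = object$beta, module_sizes = tab,
              module_trait = object$module_trait)
  class(out) <- "summary.coexpr_network"
  out
}

#' @export
print.summary.coexpr_network <- function(x, ...) {
  cat("beta:", x$beta, "\nmodule sizes:\n")
  print(x$module_sizes)
  if (!is.null(x$module_trait)) {
    cat("module-trait associations:\n")
    print(x$module_trait, digits = 3)
  }
  invisible(x)
}

#' Plot connectivity distribution and module sizes of a network
#' @param x A `coexpr_network`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.coexpr_network <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  k <- rowSums(x$adjacency) - 1
  graphics::hist(k, main = paste0("Connectivity (beta = ", x$beta, ")"),
                 xlab = "k", ...)
  graphics::barplot(table(factor(x$labels)), main = "Module sizes",
                    xlab = "module", ylab = "genes")
  invisible(x)
}

#' Extract direct IAP-apoptosis edges within significant modules
#'
#' An edge is reported iff both endpoints are assigned to the same
#' module flagged significant and their adjacency is at least
#' `edge_adjacency_min`.
#'
#' @param network A `coexpr_network` with `module_trait` computed.
#' @param iap_ids,apoptosis_ids Endpoint id sets (subsets of network
#'   genes).
#' @param cfg Optional config override (defaults to the network's).
#' @return data.frame with `iap_id`, `partner_id`, `module`,
#'   `adjacency`, sorted by ids.
#' @export
extract_direct_edges <- function(network, iap_ids, apoptosis_ids,
                                 cfg = NULL) {
  stopifnot(inherits(network, "coexpr_network"),
            !is.null(network$module_trait))
  if (is.null(cfg)) cfg <- network$config
  genes <- names(network$labels)
  stopifnot(all(iap_ids %in% genes), all(apoptosis_ids %in% genes))
  sig_mods <- network$module_trait$module[network$module_trait$significant]
  out <- list()
  for (m in sig_mods) {
    member <- genes[network$labels == m]
    mi <- intersect(iap_ids, member)
    ma <- intersect(apoptosis_ids, member)
    for (i in mi) for (a in ma) {
      if (i == a) next
      w <- network$adjacency[i, a]
      if (w >= cfg$edge_adjacency_min) {
        out[[length(out) + 1L]] <- data.frame(
          iap_id = i, partner_id = a, module = m, adjacency = w,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(iap_id = character(), partner_id = character(),
                      module = integer(), adjacency = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$iap_id, res$partner_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Presence/absence matrix of apoptosis partners per IAP
#'
#' Mirrors the pipeline's partner summary: rows = IAP ids, columns =
#' apoptosis partner ids, entries 1 where a direct edge was reported.
#'
#' @param edges Edge list from [extract_direct_edges()].
#' @return Binary matrix (0 rows/cols when no edges).
#' @export
partner_matrix <- function(edges) {
  if (!nrow(edges)) return(matrix(0L, 0, 0))
  iaps <- sort(unique(edges$iap_id))
  partners <- sort(unique(edges$partner_id))
  m <- matrix(0L, length(iaps), length(partners),
              dimnames = list(iaps, partners))
  for (i in seq_len(nrow(edges))) {
    m[edges$iap_id[i], edges$partner_id[i]] <- 1L
  }
  m
}
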