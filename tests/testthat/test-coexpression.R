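test_that("bicor handles self, anti, and outlier-free Gaussian pairs", {
  set.seed(2)
  x <- rnorm(20)
  expect_equal(bicor_pair(x, x), 1)
  expect_equal(bicor_pair(x, -x), -1)
  # reduces toward Pearson on clean large-n Gaussian data
  for (i in 1:20) {
    a <- rnorm(500); b <- 0.5 * a + rnorm(500)
    expect_lt(abs(bicor_pair(a, b) - cor(a, b)), 0.05)
  }
})

test_that("bicor equals the direct-formula oracle on 100 random pairs", {
  set.seed(8)
  for (i in 1:100) {
    x <- rnorm(20); y <- rnorm(20)
    if (i %% 5 == 0) x[1] <- x[1] + 10  # inject outliers sometimes
    expect_equal(bicor_pair(x, y), oracle_bicor(x, y), tolerance = 1e-10)
  }
})

test_that("bicor matrix matches pairwise evaluation and flags constants", {
  set.seed(12)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  cm <- bicor_matrix(m)
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), rep(1, 6), ignore_attr = TRUE)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(cm[i, j], bicor_pair(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  m2 <- rbind(m, gconst = rep(3, 10))
  expect_warning(cm2 <- bicor_matrix(m2), "constant")
  expect_equal(unname(cm2["gconst", "g1"]), 0)
})

test_that("signed-hybrid adjacency zeroes negative correlations", {
  expect_equal(adjacency_signed_hybrid(matrix(c(1, -0.9, -0.9, 1), 2),
                                       6)[1, 2], 0)
  expect_equal(adjacency_signed_hybrid(matrix(c(1, 1, 1, 1), 2), 9)[1, 2],
               1)
  set.seed(21)
  cm <- matrix(runif(25, -1, 1), 5, 5)
  cm <- (cm + t(cm)) / 2; diag(cm) <- 1
  a <- adjacency_signed_hybrid(cm, 6)
  want <- ifelse(cm > 0, cm^6, 0); diag(want) <- 1
  expect_equal(a, want)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("soft threshold falls back to 9 for small noisy data", {
  set.seed(33)
  wn <- matrix(rnorm(150 * 20), 150, 20,
               dimnames = list(sprintf("g%03d", 1:150),
                               sprintf("s%02d", 1:20)))
  st <- pick_soft_threshold(wn)
  expect_equal(st$beta, 9L)
  expect_true(st$used_fallback)
  expect_equal(nrow(st$fit_table), 20L)
})

test_that("soft threshold takes the smallest power passing the fit", {
  set.seed(34)
  # strong hub structure: genes loading on one factor with graded
  # loadings gives a broad connectivity spectrum
  n <- 150; ns <- 25
  f <- rnorm(ns)
  load <- runif(n, 0.2, 0.98)
  m <- t(sapply(load, function(l) l * f + sqrt(1 - l^2) * rnorm(ns)))
  dimnames(m) <- list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:ns))
  st <- pick_soft_threshold(m)
  # oracle: independent scan using the package's adjacency but an
  # independent fit computation
  cm <- bicor_matrix(m)
  r2o <- sapply(1:20, function(p) {
    k <- rowSums(adjacency_signed_hybrid(cm, p)) - 1
    k <- k[k > 0]
    br <- unique(quantile(k, seq(0, 1, length.out = 11)))
    b <- cut(k, br, include.lowest = TRUE)
    mk <- tapply(k, b, mean); fr <- tapply(k, b, length) / length(k)
    ok <- !is.na(mk) & fr > 0
    fit <- lm(log10(fr[ok]) ~ log10(mk[ok]))
    -sign(coef(fit)[2]) * suppressWarnings(summary(fit)$r.squared)
  })
  passing <- which(r2o >= 0.8)
  if (length(passing)) {
    expect_equal(st$beta, min(passing))
    expect_false(st$used_fallback)
  } else {
    expect_equal(st$beta, 9L)
  }
})

test_that("TOM is a similarity: symmetric, unit diagonal, in [0,1]", {
  set.seed(44)
  cm <- matrix(runif(100, 0, 1), 10, 10)
  cm <- (cm + t(cm)) / 2; diag(cm) <- 1
  a <- adjacency_signed_hybrid(cm, 3)
  tom <- tom_similarity(a)
  expect_equal(tom, t(tom))
  expect_equal(diag(tom), rep(1, 10), ignore_attr = TRUE)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  # overlap never falls below nothing: TOM >= 0 even with sparse adjacency
  a0 <- a; a0[a0 < 0.5] <- 0; diag(a0) <- 1
  expect_true(all(tom_similarity(a0) >= 0))
})

test_that("two planted separable blocks are recovered exactly", {
  set.seed(55)
  ex <- gen_expression(n_genes = 100, n_samples = 20,
                       module_sizes = c(50, 50), within_cor = 0.9,
                       trait_r = 0, seed = 77)
  adj <- adjacency_signed_hybrid(bicor_matrix(ex$matrix), 9)
  det <- detect_modules(ex$matrix, adj)
  truth <- ex$truth$labels
  for (m in 1:2) {
    found <- det$labels[names(truth)[truth == m]]
    expect_equal(length(unique(found)), 1L)
    expect_true(unique(found) != 0L)
  }
  expect_equal(length(setdiff(unique(det$labels), 0L)), 2L)
})

test_that("white noise yields no modules", {
  set.seed(56)
  wn <- matrix(rnorm(120 * 20), 120, 20,
               dimnames = list(sprintf("g%03d", 1:120),
                               sprintf("s%02d", 1:20)))
  adj <- adjacency_signed_hybrid(bicor_matrix(wn), 9)
  det <- detect_modules(wn, adj)
  expect_true(all(det$labels == 0L))
})

test_that("module-trait p values match the t-distribution oracle", {
  set.seed(65)
  labels <- setNames(rep(1L, 30), sprintf("g%02d", 1:30))
  for (i in 1:10) {
    n <- 30
    eg <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "ME1"))
    trait <- rnorm(n)
    mt <- module_trait_significance(eg, trait, labels)
    want <- cor.test(eg[, 1], trait)  # independent oracle route
    expect_equal(mt$p, want$p.value, tolerance = 1e-8)
    expect_equal(mt$r, unname(want$estimate), tolerance = 1e-12)
  }
  # eigengene equal to trait: r = 1, p ~ 0
  tr <- rnorm(20)
  eg <- matrix(tr, ncol = 1, dimnames = list(NULL, "ME1"))
  mt <- module_trait_significance(eg, tr,
                                  setNames(rep(1L, 5), paste0("g", 1:5)))
  expect_equal(mt$r, 1)
  expect_lt(mt$p, 1e-12)
  expect_error(module_trait_significance(eg, rep(1, 20), labels),
               "constant")
})

test_that("membership conditions gate module significance", {
  set.seed(66)
  n <- 20
  trait <- rep(c(0, 1), 10)
  eg <- matrix(scale(trait + rnorm(n, 0, 0.1)), ncol = 1,
               dimnames = list(NULL, "ME1"))
  labels <- setNames(rep(1L, 10), paste0("g", 1:10))
  # needs >= 1 IAP and > 1 apoptosis members
  mt <- module_trait_significance(eg, trait, labels,
                                  iap_ids = "g1",
                                  apoptosis_ids = c("g2", "g3"))
  expect_true(mt$significant)
  mt2 <- module_trait_significance(eg, trait, labels,
                                   iap_ids = "g1",
                                   apoptosis_ids = "g2")
  expect_false(mt2$significant)  # only one apoptosis transcript
  mt3 <- module_trait_significance(eg, trait, labels,
                                   iap_ids = character(0),
                                   apoptosis_ids = c("g2", "g3"))
  expect_false(mt3$significant)  # no IAP member
})

test_that("direct edges match an exhaustive pair scan", {
  set.seed(71)
  ex <- gen_expression(n_genes = 80, n_samples = 24,
                       module_sizes = c(40), within_cor = 0.8,
                       trait_r = 0.8, seed = 99)
  genes <- rownames(ex$matrix)
  iap <- genes[c(1:5, 60:62)]
  apo <- genes[c(6:15, 70:75)]
  net <- build_network(ex$matrix, trait = ex$trait, iap_ids = iap,
                       apoptosis_ids = apo, beta = 9)
  edges <- extract_direct_edges(net, iap, apo)
  sig_mods <- net$module_trait$module[net$module_trait$significant]
  want <- oracle_edges(net$adjacency, net$labels, sig_mods, iap, apo,
                       net$config$edge_adjacency_min)
  expect_equal(edges[c("iap_id", "partner_id")], want,
               ignore_attr = TRUE)
  expect_gt(nrow(edges), 0)
  # invariant under gene reordering
  perm <- sample(nrow(ex$matrix))
  net2 <- build_network(ex$matrix[perm, ], trait = ex$trait,
                        iap_ids = iap, apoptosis_ids = apo, beta = 9)
  edges2 <- extract_direct_edges(net2, iap, apo)
  expect_equal(edges2[c("iap_id", "partner_id")],
               edges[c("iap_id", "partner_id")])
  # a threshold above every weight empties the list
  cfg_hi <- network_config(edge_adjacency_min = 1.01)
  expect_equal(nrow(extract_direct_edges(net, iap, apo, cfg_hi)), 0L)
})

test_that("planted 4-module data is recovered with high ARI", {
  skip_if_not_installed("mclust")
  aris <- sapply(1:3, function(s) {
    ex <- gen_expression(n_genes = 200, n_samples = 20,
                         module_sizes = rep(40, 4), within_cor = 0.7,
                         trait_r = 0.3, seed = 100 + s)
    net <- build_network(ex$matrix, beta = 9)
    mclust::adjustedRandIndex(net$labels, ex$truth$labels)
  })
  expect_true(all(aris >= 0.8))
})
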