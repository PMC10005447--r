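test_that("residue feature matrix concatenates per-protein profiles", {
  cas <- bundled_caseins()
  obs <- rbind(
    make_obs("A", intensity = 2, substrate = "casein", time_min = 5L,
             protein_id = "CASB_BOVIN", start = 1L, end = 10L),
    make_obs("B", intensity = 7, substrate = "hydrolysate", time_min = 5L,
             protein_id = "CASA1_BOVIN", start = 90L, end = 96L))
  fm <- residue_feature_matrix(obs, cas)
  expect_equal(dim(fm), c(2L, 209L + 199L + 207L + 169L))
  expect_equal(fm["hydrolysate@5", "CASA1_BOVIN:93"], 7)
  expect_equal(fm["casein@5", "CASA1_BOVIN:93"], 0)
  # cross-check against residue_profile cell by cell
  pr <- residue_profile(obs[obs$substrate == "casein", ], cas$CASB_BOVIN)
  expect_equal(unname(fm["casein@5", paste0("CASB_BOVIN:", 1:209)]), pr$values)
})

test_that("PCA recovers two-group geometry and matches the eigen oracle", {
  x <- rbind(matrix(rep(c(1, 2, 3, 4), 3), nrow = 3, byrow = TRUE),
             matrix(rep(c(5, 5, 1, 0), 3), nrow = 3, byrow = TRUE))
  p <- peptidome_pca(x)
  expect_equal(p$explained_ratio[1], 1)

  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rnorm(6 * 20), 6, 20)
    fit <- peptidome_pca(m)
    # eigendecomposition of the covariance matrix, brute force
    eig <- eigen(stats::cov(m), symmetric = TRUE)
    k <- length(fit$explained_ratio)
    expect_equal(fit$explained_ratio,
                 (eig$values / sum(eig$values))[seq_len(k)], tolerance = 1e-8)
    for (j in seq_len(5)) {
      v <- eig$vectors[, j]
      v <- v * sign(v[which.max(abs(v))])
      expect_equal(unname(fit$loadings[, j]), v, tolerance = 1e-8)
    }
    # reconstruction of the centered matrix from all retained components
    cen <- sweep(m, 2, colMeans(m))
    expect_equal(unname(fit$scores %*% t(fit$loadings)), cen,
                 tolerance = 1e-8)
    # sign convention: dominant loading entry is positive
    expect_true(all(apply(fit$loadings, 2,
                          function(v) v[which.max(abs(v))] > 0)))
  }

  # explained variance is invariant to row and column permutation
  m <- matrix(rnorm(8 * 12), 8, 12)
  expect_equal(peptidome_pca(m[sample(8), sample(12)])$explained_ratio,
               peptidome_pca(m)$explained_ratio, tolerance = 1e-10)

  expect_equal(sum(peptidome_pca(m)$explained_ratio), 1, tolerance = 1e-9)
  expect_error(peptidome_pca(m[1, , drop = FALSE]), "2 samples")
})

test_that("zero-variance columns are dropped only under scaling", {
  m <- cbind(matrix(rnorm(12), 4, 3), rep(2, 4))
  expect_message(p <- peptidome_pca(m, scale. = TRUE), "zero-variance")
  expect_equal(nrow(p$loadings), 3L)
  expect_silent(p2 <- peptidome_pca(m))
  expect_equal(nrow(p2$loadings), 4L)
})

test_that("peptide feature matrix applies the presence filter", {
  obs <- rbind(
    make_obs("AAAAA", intensity = 1, time_min = 5L),
    make_obs("AAAAA", intensity = 2, time_min = 30L),
    make_obs("CCCCC", intensity = 4, time_min = 5L),          # one time only
    make_obs("DDDDD", intensity = 3, substrate = "hydrolysate", time_min = 5L),
    make_obs("DDDDD", intensity = 5, substrate = "hydrolysate", time_min = 30L))
  pm <- peptide_feature_matrix(obs, min_presence = 2)
  expect_setequal(colnames(pm), c("AAAAA", "DDDDD"))
  expect_equal(pm["casein@5", "AAAAA"], 1)
  expect_equal(pm["hydrolysate@30", "DDDDD"], 5)
  expect_equal(pm["casein@5", "DDDDD"], 0)

  # min_presence = 1 keeps everything
  expect_equal(ncol(peptide_feature_matrix(obs, 1)), 3L)
  expect_error(peptide_feature_matrix(obs, 0), "min_presence")

  # filter count equals a brute-force presence tally (substrate scope)
  set.seed(13)
  pool <- random_peptides(40)
  rows <- list()
  for (t in c(5L, 30L, 60L)) {
    rows[[length(rows) + 1L]] <- make_obs(sample(pool, 15), time_min = t)
  }
  obs2 <- do.call(rbind, rows)
  pm2 <- peptide_feature_matrix(obs2, 2)
  tally <- sapply(unique(obs2$sequence), function(s)
    length(unique(obs2$time_min[obs2$sequence == s])))
  expect_equal(ncol(pm2), sum(tally >= 2))

  # overall scope pools presence across substrates
  mixed <- rbind(make_obs("EEEEE", time_min = 5L),
                 make_obs("EEEEE", substrate = "hydrolysate", time_min = 30L))
  expect_equal(ncol(peptide_feature_matrix(mixed, 2, scope = "substrate")), 0L)
  expect_equal(ncol(peptide_feature_matrix(mixed, 2, scope = "overall")), 1L)
})

test_that("hierarchical clustering matches a naive agglomeration oracle", {
  set.seed(77)
  for (linkage in c("average", "single", "ward")) {
    x <- matrix(rnorm(10 * 6), 10, 6)
    rownames(x) <- paste0("s", 1:10)
    cl <- cluster_samples(x, linkage = linkage, log_transform = FALSE)
    coph_impl <- as.matrix(stats::cophenetic(cl$merge_tree))
    coph_oracle <- naive_agglomerate(x, linkage)
    expect_equal(unname(coph_impl), unname(coph_oracle), tolerance = 1e-8)
  }

  # single-linkage merge heights are the MST edge weights
  x <- matrix(rnorm(12 * 5), 12, 5)
  cl <- cluster_samples(x, linkage = "single", log_transform = FALSE)
  expect_equal(sort(cl$merge_tree$height), mst_edges(x), tolerance = 1e-10)
})

test_that("clustering handles duplicates, permutations and degenerate rows", {
  x <- rbind(a1 = c(1, 2, 3), a2 = c(1, 2, 3), b1 = c(9, 1, 0), b2 = c(9, 1, 0))
  cl <- cluster_samples(x, log_transform = FALSE)
  expect_equal(sort(cl$merge_tree$height)[1:2], c(0, 0))
  k2 <- cut_clusters(cl, 2)
  expect_equal(unname(k2[c("a1", "a2")] == k2[c("b1", "b2")]),
               c(FALSE, FALSE))

  # permutation invariance of the merge-height multiset
  y <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(paste0("r", 1:8), NULL))
  h1 <- sort(cluster_samples(y, log_transform = FALSE)$merge_tree$height)
  h2 <- sort(cluster_samples(y[sample(8), ],
                             log_transform = FALSE)$merge_tree$height)
  expect_equal(h1, h2, tolerance = 1e-10)

  # correlation distance with a zero-variance row falls back to distance 2
  z <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(5, 5, 5, 5))
  rownames(z) <- c("up", "up2", "flat")
  clz <- cluster_samples(z, distance = "correlation", linkage = "average",
                         log_transform = FALSE)
  expect_equal(max(clz$merge_tree$height), 2, tolerance = 1e-10)

  expect_error(cluster_samples(x[1, , drop = FALSE]), "2 samples")
})

test_that("dendrograms export to Newick with the right tips", {
  x <- matrix(runif(5 * 4, 0, 1e6), 5, 4,
              dimnames = list(paste0("s", 1:5), NULL))
  cl <- cluster_samples(x)
  txt <- as_newick(cl)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, rownames(x))
  tmp <- tempfile(fileext = ".nwk")
  as_newick(cl, tmp)
  expect_equal(ape::read.tree(tmp)$tip.label, phy$tip.label)
})
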