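test_that("mixing score matches a naive entropy loop on a fixed pool", {
  emb <- toy_embedding(n_per = 15, types = c("A", "B"), seed = 41)
  # n_samples >= group size and reps = 1 makes the pooled sample the whole
  # table, so the sampled neighborhoods are deterministic
  got <- mixing_score(emb, "modality", n_neighbors = 10, n_samples = 1000,
                      reps = 1, seed = 7)
  groups <- as.character(emb$covariates$modality)
  # reorder to the sampling order used internally (grouped by level)
  lev <- unique(groups)
  ord <- unlist(lapply(lev, function(g) which(groups == g)))
  want <- naive_mixing(emb$z[ord, ], groups[ord], k = 10)
  expect_equal(got$value, want, tolerance = 1e-10)
  expect_error(mixing_score(subset_embedding(emb, groups == "m1"),
                            "modality"), "at least 2 groups")
})

test_that("mixing score is near log(G) when mixed, near 0 when separated", {
  set.seed(42)
  z_mix <- matrix(rnorm(400), 200, 2)
  g <- rep(c("a", "b"), 100)
  mixed <- embedding_table(z_mix, sprintf("c%03d", 1:200),
                           covariates = data.frame(batch = g))
  split_z <- z_mix; split_z[g == "b", 1] <- split_z[g == "b", 1] + 50
  apart <- embedding_table(split_z, sprintf("c%03d", 1:200),
                           covariates = data.frame(batch = g))
  m1 <- mixing_score(mixed, "batch", n_neighbors = 30, n_samples = 100,
                     reps = 5, seed = 1)$value
  m2 <- mixing_score(apart, "batch", n_neighbors = 30, n_samples = 100,
                     reps = 5, seed = 1)$value
  expect_gt(m1, 0.9 * log(2))
  expect_lt(m2, 0.05)
})

test_that("cell-type ASW matches a naive silhouette loop", {
  emb <- toy_embedding(n_per = 8, types = c("A", "B", "C"), seed = 43)
  got <- asw_cell_type(emb)
  want <- (naive_asw(emb$z, emb$cell_type_labels) + 1) / 2
  expect_equal(got$value, want, tolerance = 1e-10)
  expect_gt(got$value, 0.8)     # well-separated blobs
  one <- emb; one$cell_type_labels <- rep("A", length(emb$cell_ids))
  expect_error(asw_cell_type(one), "at least 2")
})

test_that("modality ASW averages 1 - |ASW_m| over types, naive oracle", {
  emb <- toy_embedding(n_per = 10, types = c("A", "B"), seed = 44)
  got <- asw_modality(emb)
  mods <- as.character(emb$covariates$modality)
  want <- mean(vapply(c("A", "B"), function(tp) {
    s <- emb$cell_type_labels == tp
    1 - abs(naive_asw(emb$z[s, ], mods[s]))
  }, 0))
  expect_equal(got$value, want, tolerance = 1e-10)
  # modalities sampled from the same blob are well mixed
  expect_gt(got$value, 0.8)
  single <- emb
  single$covariates$modality[emb$cell_type_labels == "B"] <- "m1"
  expect_warning(r <- asw_modality(single), "skipped")
  expect_length(r$breakdown, 1)
})

test_that("LAES matches the naive loop and its closed forms", {
  emb <- toy_embedding(n_per = 12, types = c("A", "B"), sd = 2, seed = 45)
  mods <- as.character(emb$covariates$modality)
  got <- laes(emb, "A", k_neighbors = 8)
  want <- naive_laes(emb$z, emb$cell_type_labels, mods, "A", k = 8)
  expect_equal(got$value, want, tolerance = 1e-10)

  # closed form: balanced populations, every neighborhood pure own-modality
  z <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 100, 0.1), 20, 2))
  pure <- embedding_table(z, sprintf("c%03d", 1:40),
                          covariates = data.frame(
                            modality = rep(c("m1", "m2"), each = 20)),
                          cell_type_labels = rep("T", 40))
  expect_equal(laes(pure, "T", k_neighbors = 10)$value, 2,
               tolerance = 1e-12)
  # perfectly alternating line: own-modality share in any k-neighborhood
  # equals the population share, LAES ~ 0
  zl <- cbind(seq_len(40), 0)
  alt <- embedding_table(zl, sprintf("c%03d", 1:40),
                         covariates = data.frame(
                           modality = rep(c("m1", "m2"), 20)),
                         cell_type_labels = rep("T", 40))
  # small positive bias remains from the line's edge cells
  expect_lt(abs(laes(alt, "T", k_neighbors = 10)$value), 0.5)
  expect_error(laes(pure, "T", k_neighbors = 40), "below the cell-type")
  expect_error(laes(pure, "missing"), "not present")
})

test_that("label transfer matches a naive majority-vote loop", {
  set.seed(46)
  emb <- toy_embedding(n_per = 20, types = c("A", "B", "C"), sd = 3,
                       seed = 46)
  idx <- sample(length(emb$cell_ids), 30)
  ref <- subset_embedding(emb, setdiff(seq_along(emb$cell_ids), idx))
  qry <- subset_embedding(emb, idx)
  got <- transfer_labels(ref, qry, k = 7)
  want <- naive_transfer(ref$z, ref$cell_type_labels, qry$z, k = 7)
  expect_identical(got$predicted, want)
  expect_equal(got$accuracy, mean(want == qry$cell_type_labels))
  # macro F1 by per-class loops
  f1s <- vapply(unique(qry$cell_type_labels), function(cl) {
    tp <- sum(got$predicted == cl & qry$cell_type_labels == cl)
    fp <- sum(got$predicted == cl & qry$cell_type_labels != cl)
    fn <- sum(got$predicted != cl & qry$cell_type_labels == cl)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  expect_equal(got$macro_f1, mean(f1s), tolerance = 1e-12)
})

test_that("query_neighbors returns ranked true nearest neighbors", {
  emb <- toy_embedding(n_per = 6, types = c("A", "B"), seed = 47)
  ref <- subset_embedding(emb, 1:12)
  qry <- subset_embedding(emb, 13:16)
  nb <- query_neighbors(qry, ref, k = 3)
  expect_equal(nrow(nb), 12L)
  for (i in 1:4) {
    d <- sqrt(colSums((t(ref$z) - qry$z[i, ])^2))
    want <- ref$cell_ids[order(d)[1:3]]
    expect_equal(nb$neighbor_id[nb$query_id == qry$cell_ids[i]], want)
  }
  expect_true(all(diff(nb$distance[nb$query_id == qry$cell_ids[1]]) >= 0))
  expect_warning(query_neighbors(qry, ref, k = 99), "clamping")
})

test_that("NMI and ARI agree with external oracles", {
  set.seed(48)
  for (r in 1:4) {
    a <- sample(letters[1:4], 60, replace = TRUE)
    b <- sample(LETTERS[1:3], 60, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-10)
    expect_equal(nmi(a, b),
                 igraph::compare(as.integer(factor(a)),
                                 as.integer(factor(b)), method = "nmi"),
                 tolerance = 1e-10)
  }
  a <- rep(c("x", "y", "z"), each = 10)
  expect_equal(nmi(a, a), 1)
  expect_equal(ari(a, a), 1)
  perm <- c(x = "q", y = "r", z = "s")[a]    # relabeling invariance
  expect_equal(nmi(a, perm), 1)
  expect_equal(ari(a, perm), 1)
  expect_equal(nmi(a, rep("k", 30)), 0)
  expect_error(nmi(a, a[1:5]), "mismatch")
})

test_that("rank aggregation reproduces a hand-computed table", {
  # three methods, one metric per category
  scores <- rbind(M1 = c(BCSm = 0.9, MASm = 0.8, CPSm = 0.7, CMSm = 0.9),
                  M2 = c(0.8, 0.9, 0.9, 0.7),
                  M3 = c(0.7, 0.7, 0.8, 0.8))
  cmap <- c(BCSm = "BCS", MASm = "MAS", CPSm = "CPS", CMSm = "CMS")
  got <- rank_methods(scores, cmap)
  # hand-computed: ranks per metric (best = 1):
  # BCSm: M1=1 M2=2 M3=3; MASm: M2=1 M1=2 M3=3;
  # CPSm: M2=1 M3=2 M1=3; CMSm: M1=1 M3=2 M2=3
  want <- c(M1 = 1 * 0.2 + 2 * 0.2 + 3 * 0.3 + 1 * 0.3,
            M2 = 2 * 0.2 + 1 * 0.2 + 1 * 0.3 + 3 * 0.3,
            M3 = 3 * 0.2 + 3 * 0.2 + 2 * 0.3 + 2 * 0.3)
  expect_equal(got, want, tolerance = 1e-12)
  # a method ranked first everywhere gets exactly R = 1
  best <- rbind(W = c(1, 1, 1, 1), L = c(0, 0, 0, 0))
  colnames(best) <- names(cmap)
  expect_equal(rank_methods(best, cmap)[["W"]], 1)
  # ties average; unused categories renormalize
  two <- rbind(A = c(m1 = 1, m2 = 2), B = c(1, 1))
  got2 <- rank_methods(two, c(m1 = "CPS", m2 = "CMS"))
  expect_equal(got2[["A"]], 1.5 * 0.5 + 1 * 0.5)
  expect_error(rank_methods(rbind(A = c(m1 = NA_real_)), c(m1 = "CPS")),
               "scored")
})
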