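test_that("the generator is deterministic in its seed", {
  cfg <- simulation_config(n_cell_types = 3, cells_per_type = 20,
                           latent_dim_true = 5,
                           modalities = list(
                             rna = list(n_features = 20,
                                        link = "shared_genes",
                                        render = "counts"),
                             atac = list(n_features = 25,
                                         link = "linear_map",
                                         render = "counts")),
                           seed = 9)
  s1 <- simulate_multiome(cfg)
  s2 <- simulate_multiome(cfg)
  expect_identical(s1$datasets$rna$matrix, s2$datasets$rna$matrix)
  expect_identical(s1$truth$Z, s2$truth$Z)
  cfg2 <- cfg; cfg2$seed <- 10
  expect_false(identical(simulate_multiome(cfg2)$datasets$rna$matrix,
                         s1$datasets$rna$matrix))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(simulation_config(paired_fraction = 2), "paired_fraction")
  expect_error(simulation_config(n_cell_types = 12), "latent_dim_true")
  expect_error(simulation_config(blinded_cell_types = "type9"),
               "declared cell types")
  expect_error(simulation_config(modalities = list(
    a = list(n_features = 20, link = "linear_map", render = "counts"))),
    "shared_genes")
  expect_error(simulation_config(modalities = list(
    a = list(n_features = 3, link = "shared_genes", render = "counts"))),
    "at least latent_dim_true")
})

test_that("noiseless gaussian data admit the exact stored linear map", {
  cfg <- simulation_config(
    n_cell_types = 4, cells_per_type = 25, latent_dim_true = 6,
    noise_scale = 0, batch_effect_scale = 0,
    modalities = list(rna = list(n_features = 40, link = "shared_genes",
                                 render = "gaussian"),
                      atac = list(n_features = 30, link = "linear_map",
                                  render = "gaussian")),
    seed = 13)
  sim <- simulate_multiome(cfg)
  ra <- sim$datasets$rna; at <- sim$datasets$atac
  Wt <- sim$truth$true_maps$atac
  # X_atac %*% W_true equals the reference gene signal exactly
  joint <- intersect(ra$pairing, at$pairing)
  ia <- match(names(at$pairing)[match(joint, at$pairing)], at$cell_ids)
  ir <- match(names(ra$pairing)[match(joint, ra$pairing)], ra$cell_ids)
  expect_lt(max(abs(at$matrix[ia, ] %*% Wt - ra$matrix[ir, ])), 1e-8)
  # and least squares on paired cells recovers the map to precision
  reg <- init_translator_by_regression(at$matrix[ia, ], ra$matrix[ir, ])
  expect_lt(max(abs(reg$W - Wt)), 1e-8)
})

test_that("simulated populations are separable in the true latent space", {
  sim <- simulate_multiome(simulation_config(
    n_cell_types = 4, cells_per_type = 30, latent_dim_true = 6,
    modalities = list(rna = list(n_features = 40, link = "shared_genes",
                                 render = "counts")),
    seed = 14))
  d <- as.matrix(dist(sim$truth$Z)); diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  ct <- unname(sim$truth$cell_types)
  expect_gte(mean(ct[nn] == ct), 0.95)
})

test_that("pairing contract: visible pairing excludes blinded types only", {
  cfg <- simulation_config(
    n_cell_types = 4, cells_per_type = 20, latent_dim_true = 5,
    blinded_cell_types = c("type2"), paired_fraction = 0.8,
    modalities = list(rna = list(n_features = 20, link = "shared_genes",
                                 render = "counts"),
                      atac = list(n_features = 25, link = "linear_map",
                                  render = "counts")),
    seed = 15)
  sim <- simulate_multiome(cfg)
  rna <- sim$datasets$rna
  vis_types <- unname(sim$truth$cell_types[rna$pairing])
  expect_false("type2" %in% vis_types)
  # blinded joint cells remain in the ground truth pairing
  joint_types <- unname(sim$truth$cell_types[sim$truth$pairing])
  expect_true("type2" %in% joint_types)
  # visible paired cells are exactly the unblinded joint cells present
  jt <- sim$truth$pairing
  expected <- jt[!(sim$truth$cell_types[jt] %in% "type2")]
  present <- intersect(expected, sub("_rna$", "", rna$cell_ids))
  expect_setequal(unname(rna$pairing), present)
  # paired_fraction respected approximately
  expect_equal(mean(sim$truth$joint), 0.8, tolerance = 0.1)
})

test_that("preprocess_dataset dispatches on modality and render", {
  cfg <- simulation_config(
    n_cell_types = 3, cells_per_type = 15, latent_dim_true = 4,
    modalities = list(rna = list(n_features = 15, link = "shared_genes",
                                 render = "counts"),
                      atac = list(n_features = 20, link = "linear_map",
                                  render = "gaussian")),
    seed = 16)
  sim <- simulate_multiome(cfg)
  pr <- preprocess_dataset(sim$datasets$rna)
  expect_lt(max(abs(colMeans(pr$matrix))), 1e-10)  # standardized
  # gaussian render (signed values) must not go through count pipelines
  pa <- preprocess_dataset(sim$datasets$atac)
  expect_lt(max(abs(colMeans(pa$matrix))), 1e-10)
  expect_identical(pa$pairing, sim$datasets$atac$pairing)
  # shared gene subsetting keeps order and errors on unknown genes
  sub <- preprocess_dataset(sim$datasets$rna, shared_genes = c("gene3",
                                                               "gene1"))
  expect_equal(sub$feature_ids, c("gene3", "gene1"))
  expect_equal(sub$matrix[, "gene1"], pr$matrix[, "gene1"])
  expect_error(preprocess_dataset(sim$datasets$rna,
                                  shared_genes = "geneX"), "missing")
})

test_that("blinded benchmark hooks score only the blinded types", {
  cfg <- simulation_config(
    n_cell_types = 4, cells_per_type = 30, latent_dim_true = 5,
    blinded_cell_types = c("type1", "type3"),
    modalities = list(rna = list(n_features = 20, link = "shared_genes",
                                 render = "counts"),
                      atac = list(n_features = 25, link = "linear_map",
                                  render = "counts")),
    seed = 17)
  bench <- make_blinded_benchmark(cfg, laes_k = 10, transfer_k = 5,
                                  mixing_neighbors = 15)
  # evaluate the ground-truth latent coordinates of all simulated cells:
  # perfect integration, so LAES ~ 0 and F1 = 1 on blinded types
  tabs <- lapply(names(bench$datasets), function(m) {
    ds <- bench$datasets[[m]]
    gid <- sub(paste0("_", m, "$"), "", ds$cell_ids)
    embedding_table(bench$truth$Z[match(gid, names(bench$truth$cell_types)),
                                  , drop = FALSE],
                    ds$cell_ids, ds$covariates, ds$cell_type_labels,
                    rep(m, length(ds$cell_ids)))
  })
  emb <- do.call(rbind_embeddings, tabs)
  res <- bench$evaluate(emb)
  expect_named(res$laes_by_type, c("type1", "type3"))
  expect_lt(res$mean_abs_laes, 0.35)
  expect_equal(res$macro_f1, 1, tolerance = 0.05)
  expect_gt(res$modality_mixing, 0.9 * log(2))
  expect_error(make_blinded_benchmark(simulation_config(
    n_cell_types = 2, cells_per_type = 10, latent_dim_true = 4,
    blinded_cell_types = c("type1", "type2"),
    modalities = list(rna = list(n_features = 10, link = "shared_genes",
                                 render = "counts"),
                      atac = list(n_features = 12, link = "linear_map",
                                  render = "counts")))),
    "anchors")
})
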