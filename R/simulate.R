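pinv <- function(m, tol = NULL) {
  sv <- svd(m)
  tol <- tol %||% (max(dim(m)) * max(sv$d) * .Machine$double.eps)
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
}

#' Configuration for the synthetic multi-modal generator
#'
#' The generator draws per-type latent centroids on a scaled simplex (one
#' separation knob controls difficulty), per-cell latent states as Gaussians
#' around their centroid, and renders each modality as a linear read-out of
#' the latent state plus an additive per-batch offset and Gaussian noise.
#' Count modalities pass the signal through softplus and Poisson sampling so
#' the count-preprocessing paths are exercised on realistic sparse data.
#' Exactly one modality must use `link = "shared_genes"` (the gene-space
#' reference); every other modality's read-out is constructed so that an
#' exact linear map back to the gene space exists, and that map is stored as
#' ground truth.
#'
#' @param n_cell_types number of populations (default 5)
#' @param cells_per_type cells per population (default 100)
#' @param latent_dim_true true latent dimensionality (default 10; must be at
#'   least `n_cell_types` and at most each modality's feature count)
#' @param modalities named list; each entry a list with `n_features`,
#'   `link` (`"shared_genes"` or `"linear_map"`), and `render` (`"counts"`
#'   or `"gaussian"`)
#' @param n_batches batches per modality (default 2)
#' @param batch_effect_scale sd of the additive per-batch feature offsets
#'   (default 0.5)
#' @param noise_scale sd of the per-entry observation noise (default 0.3)
#' @param type_separation centroid scale; larger = easier (default 6)
#' @param paired_fraction fraction of cells jointly profiled in all
#'   modalities (default 1)
#' @param blinded_cell_types types whose joint profiling is hidden from the
#'   training-visible pairing (stress test); must be a subset of the
#'   declared types
#' @param seed generator seed (all randomness flows from it)
#' @return list of class `SimulationConfig`
#' @export
simulation_config <- function(n_cell_types = 5, cells_per_type = 100,
                              latent_dim_true = 10,
                              modalities = list(
                                rna = list(n_features = 150,
                                           link = "shared_genes",
                                           render = "counts"),
                                atac = list(n_features = 200,
                                            link = "linear_map",
                                            render = "counts")),
                              n_batches = 2, batch_effect_scale = 0.5,
                              noise_scale = 0.3, type_separation = 6,
                              paired_fraction = 1,
                              blinded_cell_types = character(0), seed = 1) {
  stop_if(paired_fraction < 0 || paired_fraction > 1,
          "paired_fraction must be in [0, 1]")
  stop_if(latent_dim_true < n_cell_types,
          "latent_dim_true must be at least n_cell_types")
  types <- paste0("type", seq_len(n_cell_types))
  stop_if(!all(blinded_cell_types %in% types),
          "blinded types must be declared cell types")
  links <- vapply(modalities, function(m) m$link, "")
  stop_if(sum(links == "shared_genes") != 1,
          "exactly one modality must have link = 'shared_genes'")
  for (m in modalities) {
    stop_if(m$n_features < latent_dim_true,
            "each modality needs at least latent_dim_true features")
  }
  structure(list(n_cell_types = n_cell_types,
                 cells_per_type = cells_per_type,
                 latent_dim_true = latent_dim_true, modalities = modalities,
                 n_batches = n_batches,
                 batch_effect_scale = batch_effect_scale,
                 noise_scale = noise_scale,
                 type_separation = type_separation,
                 paired_fraction = paired_fraction,
                 blinded_cell_types = blinded_cell_types, seed = seed),
            class = "SimulationConfig")
}

#' Simulate multi-modal single-cell data with full ground truth
#'
#' @param config a [simulation_config()]
#' @return list with `datasets` (named list of [omics_dataset()], counts or
#'   Gaussian signal per the config, training-visible pairing only) and
#'   `truth` (list with per-cell `cell_types`, `batches`, complete `pairing`
#'   including blinded types, latent states `Z`, per-modality `presence`,
#'   and `true_maps`: the exact linear map from each non-reference modality
#'   to the gene space)
#' @export
simulate_multiome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  T_ <- config$n_cell_types
  n <- T_ * config$cells_per_type
  L <- config$latent_dim_true
  types <- rep(paste0("type", seq_len(T_)), each = config$cells_per_type)
  global_ids <- sprintf("cell%05d", seq_len(n))
  # centroids on a scaled simplex in the first T_ latent coordinates
  centroids <- matrix(0, T_, L)
  centroids[cbind(seq_len(T_), seq_len(T_))] <- config$type_separation
  centroids <- sweep(centroids, 2, colMeans(centroids), "-")
  Z <- with_seed(derive_seed(config$seed, "latent"),
                 centroids[rep(seq_len(T_), each = config$cells_per_type), ] +
                   matrix(rnorm(n * L), n, L))
  batches <- with_seed(derive_seed(config$seed, "batch"),
                       sample(paste0("b", seq_len(config$n_batches)), n,
                              replace = TRUE))
  # which cells are jointly profiled across all modalities
  mod_names <- names(config$modalities)
  joint <- with_seed(derive_seed(config$seed, "pairing"),
                     runif(n) < config$paired_fraction)
  solo_mod <- with_seed(derive_seed(config$seed, "solo"),
                        sample(mod_names, n, replace = TRUE))
  presence <- sapply(mod_names, function(m) joint | solo_mod == m)
  ref_mod <- mod_names[vapply(config$modalities,
                              function(m) m$link == "shared_genes", TRUE)]
  g <- config$modalities[[ref_mod]]$n_features
  M_ref <- with_seed(derive_seed(config$seed, "map", ref_mod),
                     matrix(rnorm(L * g), L, g) / sqrt(L))
  gene_ids <- paste0("gene", seq_len(g))
  datasets <- list()
  true_maps <- list()
  for (m in mod_names) {
    spec_m <- config$modalities[[m]]
    f <- spec_m$n_features
    if (m == ref_mod) {
      M_m <- M_ref
      feat_ids <- gene_ids
    } else {
      M_m <- with_seed(derive_seed(config$seed, "map", m),
                       matrix(rnorm(L * f), L, f) / sqrt(L))
      true_maps[[m]] <- pinv(M_m) %*% M_ref
      dimnames(true_maps[[m]]) <- NULL
      # peak-style interval ids so genomic utilities can be exercised
      starts <- seq(0, by = 3000, length.out = f)
      feat_ids <- sprintf("chr1:%d-%d", starts, starts + 500)
    }
    keep <- which(presence[, m])
    signal <- Z[keep, , drop = FALSE] %*% M_m
    boff <- with_seed(derive_seed(config$seed, "batchfx", m),
                      matrix(rnorm(config$n_batches * f, 0,
                                   config$batch_effect_scale),
                             config$n_batches, f))
    signal <- signal + boff[match(batches[keep],
                                  paste0("b", seq_len(config$n_batches))), ,
                            drop = FALSE]
    if (config$noise_scale > 0) {
      signal <- signal + with_seed(derive_seed(config$seed, "noise", m),
                                   matrix(rnorm(length(signal), 0,
                                                config$noise_scale),
                                          nrow(signal), ncol(signal)))
    }
    mat <- if (spec_m$render == "counts") {
      lam <- softplus(signal)
      cnt <- with_seed(derive_seed(config$seed, "poisson", m),
                       matrix(rpois(length(lam), as.numeric(lam)),
                              nrow(lam), ncol(lam)))
      cnt
    } else {
      signal
    }
    cell_ids <- paste0(global_ids[keep], "_", m)
    visible <- joint[keep] & !(types[keep] %in% config$blinded_cell_types)
    pairing <- if (any(visible)) {
      setNames(global_ids[keep][visible], cell_ids[visible])
    } else NULL
    datasets[[m]] <- omics_dataset(
      mat, feat_ids, cell_ids, modality = m,
      covariates = data.frame(batch = paste0(m, "_", batches[keep]),
                              modality = m, stringsAsFactors = FALSE),
      cell_type_labels = types[keep], pairing = pairing)
  }
  truth <- list(cell_types = setNames(types, global_ids),
                batches = setNames(batches, global_ids),
                pairing = setNames(global_ids[joint],
                                   global_ids[joint]),
                joint = setNames(joint, global_ids),
                presence = presence, Z = Z, centroids = centroids,
                true_maps = true_maps, ref_modality = ref_mod,
                gene_ids = gene_ids)
  list(datasets = datasets, truth = truth, config = config)
}

#' Preprocess a simulated (or real) dataset for training
#'
#' Dispatches on the modality tag: `rna` goes through [normalize_rna()],
#' `atac` through [tfidf_transform()], `histone:*` through
#' [bin_histone_features()], and anything else (or Gaussian-rendered
#' simulation output) through plain per-feature standardization.
#'
#' @param dataset an [omics_dataset()] of raw values
#' @param method override the modality dispatch
#' @param shared_genes optional gene subset (applied to gene-feature data
#'   after normalization)
#' @param bin_bp bin width for histone data
#' @return an [omics_dataset()] with a standardized dense matrix
#' @export
preprocess_dataset <- function(dataset,
                               method = c("auto", "rna", "tfidf", "histone",
                                          "standardize"),
                               shared_genes = NULL, bin_bp = 10000) {
  method <- match.arg(method)
  if (method == "auto") {
    has_neg <- any(as_dense(dataset$matrix) < 0)
    method <- if (has_neg) "standardize"  # already continuous/signed signal
      else if (dataset$modality == "rna") "rna"
      else if (dataset$modality == "atac") "tfidf"
      else if (grepl("^histone", dataset$modality)) "histone"
      else "standardize"
  }
  if (method == "rna") {
    x <- normalize_rna(dataset$matrix)$x
    feats <- dataset$feature_ids
    if (!is.null(shared_genes)) {
      stop_if(!all(shared_genes %in% feats),
              "shared genes missing from dataset")
      x <- x[, match(shared_genes, feats), drop = FALSE]
      feats <- shared_genes
    }
  } else if (method == "tfidf") {
    x <- tfidf_transform(dataset$matrix)$x
    feats <- dataset$feature_ids
  } else if (method == "histone") {
    res <- bin_histone_features(dataset$matrix,
                                parse_interval_ids(dataset$feature_ids),
                                bin_bp = bin_bp)
    x <- res$x
    feats <- res$bin_ids
  } else {
    x <- standardize_features(dataset$matrix)$x
    feats <- dataset$feature_ids
  }
  omics_dataset(x, feats, dataset$cell_ids, modality = dataset$modality,
                covariates = dataset$covariates,
                cell_type_labels = dataset$cell_type_labels,
                pairing = dataset$pairing)
}

#' Build the blinded-pairing stress-test benchmark
#'
#' Simulates jointly-profiled data in which the pairing of the configured
#' blinded cell types is withheld from training (the model must place them
#' by generalisation, not anchors), and returns evaluation hooks that score
#' the blinded types only, against ground truth: pooled LAES per blinded
#' type, modality mixing over blinded cells, and cross-modal label-transfer
#' macro F1 with blinded query cells.
#'
#' @param config a [simulation_config()] with at least one blinded type (and
#'   at least one anchor type left unblinded)
#' @param transfer_k,laes_k,mixing_neighbors metric neighborhood sizes
#' @return list with `datasets`, `truth`, `config`, and `evaluate(emb)`
#'   returning `laes_by_type`, `mean_abs_laes`, `modality_mixing`, and
#'   `macro_f1` computed on the blinded types
#' @export
make_blinded_benchmark <- function(config, transfer_k = 15, laes_k = 30,
                                   mixing_neighbors = 50) {
  stopifnot(inherits(config, "SimulationConfig"))
  types <- paste0("type", seq_len(config$n_cell_types))
  stop_if(length(config$blinded_cell_types) >= length(types),
          "cannot blind every cell type: no anchors would remain")
  sim <- simulate_multiome(config)
  blinded <- config$blinded_cell_types
  evaluate <- function(emb) {
    stop_if(is.null(emb$cell_type_labels), "embedding must carry labels")
    mods <- if ("modality" %in% colnames(emb$covariates))
      as.character(emb$covariates$modality) else emb$source_dataset
    laes_by_type <- vapply(blinded, function(tp) {
      laes(emb, tp, modality_labels = mods, k_neighbors = laes_k)$value
    }, 0)
    bsel <- emb$cell_type_labels %in% blinded
    bemb <- subset_embedding(emb, bsel)
    mix <- mixing_score(bemb, "modality",
                        n_neighbors = mixing_neighbors,
                        n_samples = min(100, sum(bsel)), reps = 20,
                        seed = derive_seed(config$seed, "hookmix"))$value
    mod_names <- unique(mods)
    ref_sel <- mods == mod_names[1]
    qry_sel <- mods != mod_names[1] & bsel
    tf <- transfer_labels(subset_embedding(emb, ref_sel),
                          subset_embedding(emb, qry_sel), k = transfer_k)
    f1 <- mean(tf$per_class_f1[intersect(names(tf$per_class_f1), blinded)])
    list(laes_by_type = laes_by_type,
         mean_abs_laes = mean(abs(laes_by_type)),
         modality_mixing = mix, macro_f1 = f1)
  }
  c(sim, list(evaluate = evaluate, blinded = blinded))
}
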