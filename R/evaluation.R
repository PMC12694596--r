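metric_result <- function(name, value, parameters = list(),
                          breakdown = NULL) {
  stop_if(!is.finite(value), "metric '", name, "' is not finite")
  structure(list(name = name, value = value, parameters = parameters,
                 breakdown = breakdown),
            class = "MetricResult")
}

#' @export
print.MetricResult <- function(x, ...) {
  cat(sprintf("%s = %.4f\n", x$name, x$value))
  invisible(x)
}

group_vector <- function(emb, group_label) {
  if (group_label %in% colnames(emb$covariates)) {
    as.character(emb$covariates[[group_label]])
  } else if (group_label == "source_dataset") {
    emb$source_dataset
  } else {
    stop("group label '", group_label, "' not found in covariates",
         call. = FALSE)
  }
}

#' Entropy-based batch / modality mixing score
#'
#' Repeatedly draws a random sample of `n_samples` cells from each group,
#' finds each sampled cell's `n_neighbors` nearest neighbors within the
#' pooled sample, computes the Shannon entropy of the neighborhood group
#' proportions `E(n) = -sum_i p_i(n) log p_i(n)`, and averages over cells
#' and repetitions. Higher is better mixed; the maximum for G balanced
#' groups is `log(G)`.
#'
#' @param emb an [embedding_table()]
#' @param group_label covariate column holding the group (e.g. `"batch"` or
#'   `"modality"`), or `"source_dataset"`
#' @param n_neighbors neighborhood size (default 100; clamped to the pooled
#'   sample size minus one)
#' @param n_samples cells sampled per group per repetition (default 100)
#' @param reps repetitions (default 100)
#' @param seed sampling seed
#' @return a `MetricResult`
#' @export
mixing_score <- function(emb, group_label = "batch", n_neighbors = 100,
                         n_samples = 100, reps = 100, seed = 1) {
  groups <- group_vector(emb, group_label)
  lev <- unique(groups)
  stop_if(length(lev) < 2, "mixing score needs at least 2 groups")
  z <- emb$z
  per_rep <- with_seed(derive_seed(seed, "mixing"), vapply(seq_len(reps),
    function(r) {
      sel <- unlist(lapply(lev, function(g) {
        idx <- which(groups == g)
        if (length(idx) > n_samples) sample(idx, n_samples) else idx
      }))
      zs <- z[sel, , drop = FALSE]
      gs <- groups[sel]
      kk <- min(n_neighbors, length(sel) - 1)
      d2 <- cross_dist2(zs, zs)
      diag(d2) <- Inf
      ent <- vapply(seq_along(sel), function(i) {
        nb <- order(d2[i, ])[seq_len(kk)]
        p <- table(factor(gs[nb], levels = lev)) / kk
        p <- p[p > 0]
        -sum(p * log(p))
      }, 0)
      mean(ent)
    }, 0))
  metric_result(paste0("mixing_", group_label), mean(per_rep),
                list(n_neighbors = n_neighbors, n_samples = n_samples,
                     reps = reps, seed = seed),
                breakdown = per_rep)
}

silhouette_asw <- function(z, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(z))
  mean(sil[, "sil_width"])
}

#' Cell-type silhouette score, rescaled to [0, 1]
#'
#' Classical average silhouette width on cell-type labels, mapped to
#' `(ASW_c + 1) / 2` so that 1 means perfectly compact, well-separated
#' types and 0.5 is the structureless level.
#'
#' @param emb an [embedding_table()]
#' @param labels per-cell labels (default: the table's cell-type labels)
#' @return a `MetricResult`
#' @export
asw_cell_type <- function(emb, labels = emb$cell_type_labels) {
  stop_if(is.null(labels), "cell-type labels required")
  tab <- table(labels)
  stop_if(length(tab) < 2, "need at least 2 label classes")
  stop_if(any(tab < 2), "every class needs at least 2 cells")
  metric_result("asw_cell_type", (silhouette_asw(emb$z, labels) + 1) / 2)
}

#' Within-cell-type modality silhouette score
#'
#' For each cell type j containing at least two modalities, computes the
#' silhouette of modality labels within that type and scores it
#' `1 - |ASW_m(j)|`; the final score is the average over cell types. 1 means
#' modalities are perfectly mixed within every type; 0 means perfectly
#' separated.
#'
#' @param emb an [embedding_table()]
#' @param cell_type_labels per-cell types (default from the table)
#' @param modality_labels per-cell modality (default covariate `"modality"`,
#'   falling back to `source_dataset`)
#' @return a `MetricResult` with a per-type breakdown
#' @export
asw_modality <- function(emb, cell_type_labels = emb$cell_type_labels,
                         modality_labels = NULL) {
  stop_if(is.null(cell_type_labels), "cell-type labels required")
  if (is.null(modality_labels)) {
    modality_labels <- if ("modality" %in% colnames(emb$covariates))
      as.character(emb$covariates$modality) else emb$source_dataset
  }
  types <- unique(cell_type_labels)
  scores <- c()
  for (tp in types) {
    sel <- cell_type_labels == tp
    mods <- modality_labels[sel]
    if (length(unique(mods)) < 2 || any(table(mods) < 2)) {
      warning("cell type '", tp, "' skipped (single modality)",
              call. = FALSE)
      next
    }
    asw_m <- silhouette_asw(emb$z[sel, , drop = FALSE], mods)
    scores[tp] <- 1 - abs(asw_m)
  }
  stop_if(length(scores) == 0, "no cell type contains >= 2 modalities")
  metric_result("asw_modality", mean(scores), breakdown = scores)
}

#' Local annotation enrichment score (LAES)
#'
#' For every cell n of a given cell type (population size N pooled over all
#' modalities), with `N_A` cells of the cell's own modality A and
#' `N_nonA = N - N_A` others, and counting the composition of its k nearest
#' neighbors within the type:
#' `LAES_n = (N_A(k)/N_A - N_nonA(k)/N_nonA) * (N/k)`.
#' Scores are averaged per modality and pooled over all cells of the type.
#' Values near 0 indicate the modalities are locally well mixed; positive
#' values indicate neighborhoods enriched for the cell's own modality.
#'
#' @param emb an [embedding_table()]
#' @param cell_type the cell type to score
#' @param modality_labels per-cell modality (default covariate `"modality"`,
#'   falling back to `source_dataset`)
#' @param cell_type_labels per-cell types (default from the table)
#' @param k_neighbors neighborhood size (must be below the type population)
#' @return a `MetricResult` (pooled mean) with a per-modality breakdown
#' @export
laes <- function(emb, cell_type, modality_labels = NULL,
                 cell_type_labels = emb$cell_type_labels, k_neighbors = 30) {
  stop_if(is.null(cell_type_labels), "cell-type labels required")
  if (is.null(modality_labels)) {
    modality_labels <- if ("modality" %in% colnames(emb$covariates))
      as.character(emb$covariates$modality) else emb$source_dataset
  }
  sel <- which(cell_type_labels == cell_type)
  stop_if(length(sel) == 0, "cell type not present: ", cell_type)
  mods <- modality_labels[sel]
  stop_if(length(unique(mods)) < 2,
          "cell type must be present in >= 2 modalities")
  N <- length(sel)
  stop_if(k_neighbors >= N,
          "k_neighbors must be below the cell-type population (", N, ")")
  z <- emb$z[sel, , drop = FALSE]
  d2 <- cross_dist2(z, z)
  diag(d2) <- Inf
  per_cell <- vapply(seq_len(N), function(i) {
    nb <- order(d2[i, ])[seq_len(k_neighbors)]
    na_k <- sum(mods[nb] == mods[i])
    n_a <- sum(mods == mods[i])
    (na_k / n_a - (k_neighbors - na_k) / (N - n_a)) * (N / k_neighbors)
  }, 0)
  by_mod <- tapply(per_cell, mods, mean)
  metric_result(paste0("laes_", cell_type), mean(per_cell),
                list(k_neighbors = k_neighbors),
                breakdown = by_mod)
}

#' k-nearest-neighbor label transfer
#'
#' Predicts each query cell's label by majority vote among its k nearest
#' labeled reference cells (Euclidean distance in latent space); ties are
#' broken by the summed inverse distance to each tied class. When the query
#' carries true labels, overall accuracy and macro F1 (F1 averaged over the
#' true classes with equal weight) are reported.
#'
#' @param ref labeled reference [embedding_table()]
#' @param query query [embedding_table()] in the same latent space
#' @param k neighborhood size (default 15)
#' @param ref_labels,query_labels label overrides (defaults: the tables'
#'   cell-type labels)
#' @return list with `predicted`, and `accuracy`, `macro_f1`, `per_class_f1`
#'   when query truth is available
#' @export
transfer_labels <- function(ref, query, k = 15,
                            ref_labels = ref$cell_type_labels,
                            query_labels = query$cell_type_labels) {
  stop_if(is.null(ref_labels) || length(ref_labels) == 0,
          "reference must be labeled")
  stop_if(nrow(ref$z) == 0, "empty reference")
  k <- min(k, nrow(ref$z))
  d2 <- cross_dist2(query$z, ref$z)
  pred <- vapply(seq_len(nrow(query$z)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    votes <- table(ref_labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    invd <- vapply(top, function(cl) {
      sum(1 / pmax(sqrt(d2[i, nb[ref_labels[nb] == cl]]), 1e-12))
    }, 0)
    top[which.max(invd)]
  }, "")
  out <- list(predicted = pred, k = k)
  if (!is.null(query_labels)) {
    out$accuracy <- mean(pred == query_labels)
    classes <- unique(query_labels)
    f1 <- vapply(classes, function(cl) {
      tp <- sum(pred == cl & query_labels == cl)
      fp <- sum(pred == cl & query_labels != cl)
      fn <- sum(pred != cl & query_labels == cl)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, 0)
    out$per_class_f1 <- setNames(f1, classes)
    out$macro_f1 <- mean(f1)
  }
  out
}

#' Query nearest reference cells
#'
#' Returns, for each query cell, the ids and source-dataset tags of its k
#' nearest reference cells by Euclidean distance in the latent space.
#'
#' @param query,reference [embedding_table()] objects
#' @param k neighbors per query (default 15; clamped to the reference size
#'   with a warning)
#' @return data.frame with `query_id`, `rank`, `neighbor_id`,
#'   `neighbor_source`, `distance`
#' @export
query_neighbors <- function(query, reference, k = 15) {
  stop_if(nrow(reference$z) == 0, "empty reference")
  if (k > nrow(reference$z)) {
    warning("k exceeds reference size; clamping to ", nrow(reference$z),
            call. = FALSE)
    k <- nrow(reference$z)
  }
  d2 <- cross_dist2(query$z, reference$z)
  do.call(rbind, lapply(seq_len(nrow(query$z)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    data.frame(query_id = query$cell_ids[i], rank = seq_len(k),
               neighbor_id = reference$cell_ids[nb],
               neighbor_source = reference$source_dataset[nb],
               distance = sqrt(d2[i, nb]), stringsAsFactors = FALSE)
  }))
}

contingency <- function(a, b) table(factor(a), factor(b))

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies; 0 for independent labelings, 1 for a perfect match.
#'
#' @param labels_a,labels_b equal-length label vectors
#' @return scalar in [0, 1]
#' @export
nmi <- function(labels_a, labels_b) {
  stop_if(length(labels_a) != length(labels_b), "label length mismatch")
  ct <- contingency(labels_a, labels_b)
  n <- sum(ct)
  pij <- ct / n
  pi <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  ha <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hb <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (ha + hb == 0) return(1)  # both labelings constant: identical
  denom <- (ha + hb) / 2
  if (denom == 0 || mi <= 0) return(0)
  mi / denom
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement adjusted for chance; 1 for identical labelings,
#' about 0 for random ones.
#'
#' @param labels_a,labels_b equal-length label vectors
#' @return scalar in [-1, 1]
#' @export
ari <- function(labels_a, labels_b) {
  stop_if(length(labels_a) != length(labels_b), "label length mismatch")
  ct <- contingency(labels_a, labels_b)
  n <- sum(ct)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}

#' Default category weights for rank aggregation
#'
#' Batch correction (BCS) 0.2, modality alignment (MAS) 0.2, cell-type
#' preservation (CPS) 0.3, cross-modality mapping (CMS) 0.3; biological
#' categories carry more weight.
#'
#' @return named numeric vector summing to 1
#' @export
rank_weights <- function(BCS = 0.2, MAS = 0.2, CPS = 0.3, CMS = 0.3) {
  w <- c(BCS = BCS, MAS = MAS, CPS = CPS, CMS = CMS)
  stop_if(abs(sum(w) - 1) > 1e-8, "rank weights must sum to 1")
  w
}

#' Weighted rank aggregation of benchmark scores
#'
#' Ranks methods within each metric (best score = rank 1, ties averaged),
#' averages ranks within each of the four evaluation categories, and
#' combines the category ranks with the given weights. Lower R is better; a
#' method ranked first on every metric gets R = 1.
#'
#' @param scores methods x metrics numeric matrix (higher = better; rownames
#'   are methods, colnames metrics); no missing values allowed
#' @param category_map named character vector mapping each metric (column)
#'   to one of `names(weights)`
#' @param weights a [rank_weights()] vector
#' @return named numeric vector of R_i per method (ascending = better)
#' @export
rank_methods <- function(scores, category_map, weights = rank_weights()) {
  scores <- as.matrix(scores)
  stop_if(any(is.na(scores)), "every method must be scored on every metric")
  stop_if(is.null(colnames(scores)), "scores needs metric column names")
  stop_if(!all(colnames(scores) %in% names(category_map)),
          "category_map must cover every metric")
  ranks <- apply(scores, 2, function(s) rank(-s, ties.method = "average"))
  cats <- category_map[colnames(scores)]
  stop_if(!all(cats %in% names(weights)),
          "unknown category in category_map")
  cat_rank <- sapply(names(weights), function(cc) {
    cols <- which(cats == cc)
    if (length(cols) == 0) return(rep(NA_real_, nrow(scores)))
    rowMeans(ranks[, cols, drop = FALSE])
  })
  used <- !is.na(cat_rank[1, ])
  w <- weights[used] / sum(weights[used])
  R <- as.numeric(cat_rank[, used, drop = FALSE] %*% w)
  setNames(R, rownames(scores))
}
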