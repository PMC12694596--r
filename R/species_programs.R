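#' Cluster shared homologous genes from the translator's B factor
#'
#' Shared genes are embedded as the columns of the d x g factor B learned in
#' phase 2; gene groups are found by Louvain community detection on a
#' k-nearest-neighbor graph built from cosine similarity between the column
#' vectors. Fully seeded.
#'
#' @param B d x g matrix (columns = shared genes; colnames used as ids)
#' @param resolution Louvain resolution (default 1)
#' @param knn neighbors in the gene graph (default 15)
#' @param seed clustering seed
#' @return integer cluster label per shared gene (named)
#' @export
cluster_shared_genes <- function(B, resolution = 1, knn = 15, seed = 1) {
  B <- as_dense(B)
  g <- ncol(B)
  stop_if(g < 1, "no shared genes")
  ids <- colnames(B) %||% paste0("gene", seq_len(g))
  if (g == 1) return(setNames(1L, ids))
  V <- t(B)
  nrm <- sqrt(rowSums(V^2))
  degenerate <- sd(as.numeric(V)) == 0 || all(nrm == 0)
  S <- NULL
  if (!degenerate) {
    Vn <- V / pmax(nrm, 1e-12)
    S <- tcrossprod(Vn)
    if (max(S[upper.tri(S)]) - min(S[upper.tri(S)]) < 1e-12) {
      degenerate <- TRUE
    }
  }
  if (degenerate) {
    warning("all shared-gene vectors are identical; returning one cluster",
            call. = FALSE)
    return(setNames(rep(1L, g), ids))
  }
  kk <- min(knn, g - 1)
  diag(S) <- -Inf
  edges <- do.call(rbind, lapply(seq_len(g), function(i) {
    nb <- order(S[i, ], decreasing = TRUE)[seq_len(kk)]
    cbind(i, nb, pmax(S[i, nb], 0))
  }))
  gr <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               weight = edges[, 3] + 1e-9),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g)))
  gr <- igraph::simplify(gr, edge.attr.comb = "max")
  cl <- with_seed(seed,
                  igraph::cluster_louvain(gr, resolution = resolution))
  memb <- igraph::membership(cl)
  setNames(as.integer(memb[as.character(seq_len(g))]), ids)
}

#' Categorize gene clusters by cell-type expression pattern
#'
#' For each gene cluster, averages gene-scaled (z-scored across cell types)
#' expression per cell type and marks cell types whose cluster-mean scaled
#' expression exceeds `z_threshold` as enriched.
#'
#' @param clusters named cluster labels from [cluster_shared_genes()]
#' @param expression cell types x genes matrix of average expression
#'   (rownames = cell types, colnames = genes)
#' @param z_threshold enrichment cutoff on the scaled means (default 1)
#' @return list per cluster with `enriched` cell types, the `profile` of
#'   scaled means, and the member `genes`
#' @export
categorize_clusters_by_celltype <- function(clusters, expression,
                                            z_threshold = 1) {
  expression <- as_dense(expression)
  genes <- intersect(names(clusters), colnames(expression))
  missing <- setdiff(names(clusters), colnames(expression))
  if (length(missing) > 0) {
    warning(length(missing), " clustered gene(s) missing from expression; ",
            "dropped", call. = FALSE)
  }
  stop_if(length(genes) == 0, "expression covers none of the clustered genes")
  ex <- expression[, genes, drop = FALSE]
  mu <- colMeans(ex)
  s <- apply(ex, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  scaled <- sweep(sweep(ex, 2, mu, "-"), 2, s, "/")
  out <- list()
  for (cl in sort(unique(clusters[genes]))) {
    gsel <- genes[clusters[genes] == cl]
    profile <- rowMeans(scaled[, gsel, drop = FALSE])
    out[[as.character(cl)]] <- list(
      enriched = rownames(expression)[profile > z_threshold],
      profile = setNames(profile, rownames(expression)),
      genes = gsel)
  }
  out
}

#' Reconstruct a species' gene-to-shared-gene map from translator factors
#'
#' Multiplies the species-specific factor A (species genes x d) by the
#' shared factor B (d x shared genes) to recover the effective linear map
#' from that species' genes to the conserved shared genes.
#'
#' @param A_s f_s x d species factor
#' @param B d x g shared factor
#' @return f_s x g matrix
#' @export
reconstruct_species_map <- function(A_s, B) {
  A_s <- as_dense(A_s); B <- as_dense(B)
  stop_if(ncol(A_s) != nrow(B),
          "inner dimensions do not match (", ncol(A_s), " vs ", nrow(B), ")")
  A_s %*% B
}

#' Call species-specific genes linked to shared genes of interest
#'
#' All weights `w[f, g]` restricted to the shared genes of interest are
#' z-scored over that whole weight population (within one species). A
#' species gene is called significant when at least `min_links` of its
#' weights to genes of interest exceed `z_threshold` (one-sided: only
#' positive associations qualify). The default threshold 2.3263 is the
#' one-sided standard-normal quantile at p = 0.01 (see
#' [species_z_cutoff()]).
#'
#' @param w species genes x shared genes matrix (from
#'   [reconstruct_species_map()]); dimnames used as ids
#' @param shared_genes_of_interest character subset of `colnames(w)`
#' @param z_threshold z-score cutoff (default 2.3263)
#' @param min_links minimum number of shared genes of interest a species
#'   gene must be linked to (default 5)
#' @param species,cell_type_context tags recorded in the calls
#' @return data.frame of gene-program calls: `species`,
#'   `cell_type_context`, `gene`, `z_score` (max over genes of interest),
#'   `n_shared_links` (links with z above threshold), `significant`
#' @export
call_species_specific_genes <- function(w, shared_genes_of_interest,
                                        z_threshold = 2.3263, min_links = 5,
                                        species = NA_character_,
                                        cell_type_context = NA_character_) {
  w <- as_dense(w)
  stop_if(length(shared_genes_of_interest) == 0, "empty shared gene set")
  stop_if(is.null(colnames(w)), "w needs shared-gene column names")
  missing <- setdiff(shared_genes_of_interest, colnames(w))
  stop_if(length(missing) > 0,
          "shared genes of interest absent from w: ",
          paste(head(missing, 3), collapse = ", "))
  sub <- w[, shared_genes_of_interest, drop = FALSE]
  zz <- (sub - mean(sub)) / sd(sub)
  links <- rowSums(zz > z_threshold)
  gene_ids <- rownames(w) %||% paste0("g", seq_len(nrow(w)))
  data.frame(species = species, cell_type_context = cell_type_context,
             gene = gene_ids,
             z_score = apply(zz, 1, max),
             n_shared_links = as.integer(links),
             significant = links >= min_links,
             stringsAsFactors = FALSE)
}

#' The significance cutoff used for species-specific gene calls
#'
#' One-sided standard-normal quantile at the given p-value; at p = 0.01 this
#' is 2.3263 (4 dp).
#'
#' @param p one-sided tail probability (default 0.01)
#' @return the z cutoff
#' @export
species_z_cutoff <- function(p = 0.01) qnorm(1 - p)

#' Classify a gene module's species specificity
#'
#' Given per-species significance calls for a module, the module is
#' `species_specific:<s>` when significant in exactly one species,
#' `conserved` when significant in all, `clade_specific:<...>` for an
#' intermediate subset (e.g. NHP-specific when significant in macaque and
#' marmoset but not human), and `none` when significant nowhere.
#'
#' @param calls named logical vector: species -> significant in that species
#' @return character classification
#' @export
classify_program_speciesness <- function(calls) {
  stop_if(length(calls) < 2, "calls for at least 2 species required")
  sig <- names(calls)[as.logical(calls)]
  if (length(sig) == 0) return("none")
  if (length(sig) == length(calls)) return("conserved")
  if (length(sig) == 1) return(paste0("species_specific:", sig))
  paste0("clade_specific:", paste(sort(sig), collapse = "+"))
}
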