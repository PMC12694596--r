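#' Normalize an RNA count matrix
#'
#' The standard pipeline for expression counts: per-cell total-count scaling
#' to 10,000, `log1p`, then per-gene standardization to zero mean and unit
#' variance (zero-variance genes standardize to all zeros). Cells whose total
#' count is zero are left as zero rows and flagged.
#'
#' @param counts cells x genes non-negative matrix (dense or sparse)
#' @param target_sum library-size target (default 10000)
#' @return list with `x` (standardized dense matrix), `params`
#'   ([standardize_features()] parameters), and `zero_cells` (logical flag
#'   per cell)
#' @export
normalize_rna <- function(counts, target_sum = 10000) {
  counts <- as_dense(counts)
  stop_if(any(counts < 0), "counts must be non-negative")
  totals <- rowSums(counts)
  zero_cells <- totals == 0
  scaled <- counts
  if (any(!zero_cells)) {
    scaled[!zero_cells, ] <- counts[!zero_cells, , drop = FALSE] *
      (target_sum / totals[!zero_cells])
  }
  lg <- log1p(scaled)
  std <- standardize_features(lg)
  std$x[zero_cells, ] <- 0
  list(x = std$x, params = std$params, zero_cells = zero_cells)
}

#' TF-IDF transform of a peak accessibility matrix
#'
#' For peak p in cell n with raw count `x[n, p]`:
#' `TF(p, n) = x[n, p] / sum_p' x[n, p']`, `N_p` is the number of cells in
#' which peak p is detected, and the transformed value is
#' `t[n, p] = TF(p, n) * IDF(p)`. Two IDF dialects are provided:
#' `smoothed_plus1` (default), `IDF(p) = log((1 + N) / (1 + N_p)) + 1`, and
#' `log1p_ratio`, `IDF(p) = log(1 + N / N_p)`. The transformed matrix is then
#' standardized per peak.
#'
#' @param peak_counts cells x peaks non-negative matrix
#' @param idf one of `"smoothed_plus1"`, `"log1p_ratio"`
#' @return list with `x` (standardized dense matrix) and `intermediate`
#'   (list `tf`, `idf`, `t`, `n_cells_with_peak`)
#' @export
tfidf_transform <- function(peak_counts, idf = c("smoothed_plus1",
                                                 "log1p_ratio")) {
  idf <- match.arg(idf)
  x <- as_dense(peak_counts)
  stop_if(any(x < 0), "peak counts must be non-negative")
  stop_if(all(x == 0), "all-zero accessibility matrix")
  n <- nrow(x)
  totals <- rowSums(x)
  tf <- x
  nz <- totals > 0
  tf[nz, ] <- x[nz, , drop = FALSE] / totals[nz]
  np <- colSums(x > 0)
  w <- switch(idf,
              smoothed_plus1 = log((1 + n) / (1 + np)) + 1,
              log1p_ratio = log1p(n / pmax(np, 1)))
  w[np == 0] <- 0
  t_mat <- sweep(tf, 2, w, "*")
  std <- standardize_features(t_mat)
  list(x = std$x,
       intermediate = list(tf = tf, idf = w, t = t_mat,
                           n_cells_with_peak = np),
       params = std$params)
}

#' Aggregate histone-mark peak counts into fixed genomic bins
#'
#' Peaks are assigned to the non-overlapping `bin_bp` window containing
#' their midpoint (half-open bins, so a midpoint exactly on a boundary falls
#' in the next bin); counts are summed per bin, `log1p`-transformed, and
#' standardized per bin.
#'
#' @param peak_counts cells x peaks non-negative matrix
#' @param peak_intervals `GRanges` with one interval per peak column
#' @param bin_bp bin width in bp (default 10000)
#' @return list with `x` (cells x bins standardized matrix), `bin_ids`
#'   (encoded "chrom:start-end"), and `bin_counts` (raw summed counts)
#' @export
bin_histone_features <- function(peak_counts, peak_intervals,
                                 bin_bp = 10000) {
  x <- as_dense(peak_counts)
  stop_if(length(peak_intervals) != ncol(x),
          "one interval required per peak column (got ",
          length(peak_intervals), " for ", ncol(x), " peaks)")
  chrom <- as.character(GenomicRanges::seqnames(peak_intervals))
  start0 <- GenomicRanges::start(peak_intervals) - 1L
  end0 <- GenomicRanges::end(peak_intervals)
  mid <- floor((start0 + end0) / 2)
  bin_start <- (mid %/% bin_bp) * bin_bp
  bin_id <- sprintf("%s:%d-%d", chrom, bin_start, bin_start + bin_bp)
  bins <- unique(bin_id[order(chrom, bin_start)])
  agg <- matrix(0, nrow(x), length(bins), dimnames = list(rownames(x), bins))
  for (j in seq_along(bin_id)) {
    agg[, bin_id[j]] <- agg[, bin_id[j]] + x[, j]
  }
  std <- standardize_features(log1p(agg))
  list(x = std$x, bin_ids = bins, bin_counts = agg, params = std$params)
}

#' Select highly variable genes across one or more RNA datasets
#'
#' Genes are ranked by normalized dispersion of log1p CP10K expression
#' (variance / mean of the log-normalized values, z-scored within 20 mean
#' bins, the usual dispersion-based recipe). With several datasets the
#' per-dataset ranks of genes present everywhere are combined by median
#' rank. Deterministic given input.
#'
#' @param rna_datasets a single [omics_dataset()] / matrix or a list of them
#'   (raw counts)
#' @param n_genes number of genes to keep (default 2000)
#' @return character vector of gene ids, ordered from most variable
#' @export
select_hvg <- function(rna_datasets, n_genes = 2000) {
  if (inherits(rna_datasets, "OmicsDataset") || is.matrix(rna_datasets) ||
      is(rna_datasets, "Matrix")) {
    rna_datasets <- list(rna_datasets)
  }
  stop_if(length(rna_datasets) == 0, "at least one RNA dataset required")
  get_mat <- function(d) if (inherits(d, "OmicsDataset")) d$matrix else d
  disp_rank <- function(counts) {
    counts <- as_dense(counts)
    totals <- rowSums(counts)
    nz <- totals > 0
    norm <- counts
    norm[nz, ] <- counts[nz, , drop = FALSE] * (10000 / totals[nz])
    lg <- log1p(norm)
    mu <- colMeans(lg)
    v <- apply(lg, 2, var)
    disp <- ifelse(mu > 0, v / mu, 0)
    # z-score dispersion within bins of similar mean expression
    nbin <- max(1, min(20, floor(length(mu) / 5)))
    bins <- cut(rank(mu, ties.method = "first"), breaks = nbin,
                labels = FALSE)
    nd <- disp
    for (b in unique(bins)) {
      sel <- bins == b
      s <- sd(disp[sel])
      nd[sel] <- if (is.na(s) || s == 0) 0 else
        (disp[sel] - mean(disp[sel])) / s
    }
    r <- rank(-nd, ties.method = "first")
    setNames(r, colnames(counts))
  }
  ranks <- lapply(rna_datasets, function(d) disp_rank(get_mat(d)))
  shared <- Reduce(intersect, lapply(ranks, names))
  stop_if(length(shared) == 0, "datasets share no genes")
  med <- apply(do.call(cbind, lapply(ranks, function(r) r[shared])), 1,
               stats::median)
  ord <- shared[order(med, shared)]
  if (length(ord) < n_genes) {
    warning("only ", length(ord), " genes available; returning all",
            call. = FALSE)
    return(ord)
  }
  ord[seq_len(n_genes)]
}

#' Create a stochastic augmented view of a standardized matrix
#'
#' Because every modality is standardized to unit variance, one universal
#' augmentation applies: i.i.d. Gaussian noise with mean 0 and variance 1
#' added to every entry. Fully determined by `seed`.
#'
#' @param x cells x features standardized matrix (finite)
#' @param seed integer seed for the noise draw
#' @param sd noise standard deviation (default 1)
#' @return matrix of the same shape, `x + eps`
#' @export
augment <- function(x, seed, sd = 1) {
  x <- as_dense(x)
  stop_if(any(!is.finite(x)), "augment requires a finite matrix")
  eps <- with_seed(seed, matrix(rnorm(length(x), 0, sd), nrow(x), ncol(x)))
  x + eps
}
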