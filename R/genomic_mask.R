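#' Build a GenomicRanges object from BED-style coordinates
#'
#' Coordinates are 0-based half-open (BED convention) throughout the package;
#' this helper converts them to the 1-based closed convention GRanges uses
#' internally.
#'
#' @param chrom character vector of chromosome names
#' @param start 0-based start positions
#' @param end end positions (exclusive); must exceed `start`
#' @param strand optional strand (`"+"`, `"-"`, `"."`); ignored by the mask
#' @param ids optional interval names
#' @return a `GRanges`
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ids = NULL) {
  stop_if(length(chrom) == 0, "no intervals given")
  stop_if(any(nchar(as.character(chrom)) == 0), "empty chromosome name")
  stop_if(any(end <= start), "interval end must be greater than start")
  stop_if(any(start < 0), "negative start coordinate")
  strand <- strand %||% rep("*", length(chrom))
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = strand)
  if (!is.null(ids)) names(gr) <- ids
  gr
}

#' Encode intervals as "chrom:start-end" feature ids (0-based half-open)
#' @param gr a `GRanges`
#' @return character vector
#' @export
interval_ids <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' Parse "chrom:start-end" feature ids back into intervals
#' @param ids character vector of encoded ids
#' @return a `GRanges`
#' @export
parse_interval_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4
  stop_if(any(bad), "malformed interval id: ", ids[bad][1])
  genomic_intervals(vapply(m, `[`, "", 2),
                    as.integer(vapply(m, `[`, "", 3)),
                    as.integer(vapply(m, `[`, "", 4)),
                    ids = ids)
}

#' Read peak intervals from a BED file
#' @param path BED file (>= 3 columns, 0-based half-open)
#' @return a `GRanges` named by encoded interval ids
#' @export
read_peaks_bed <- function(path) {
  stop_if(!file.exists(path), "input file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% colnames(mc) && !all(is.na(mc$name))) {
    names(gr) <- as.character(mc$name)
  } else if (is.null(names(gr)) || all(is.na(names(gr)))) {
    names(gr) <- interval_ids(gr)
  }
  gr
}

#' Read gene intervals from GFF3/GTF or BED
#'
#' For GFF/GTF only `gene` records are kept (falling back to all records if
#' none are typed `gene`); gene ids are taken from `gene_id`, `Name` or `ID`
#' attributes in that order. GFF/GTF 1-based coordinates are handled by the
#' import layer.
#'
#' @param path annotation file
#' @param format `"auto"` (by extension), `"gff"`, `"gtf"`, or `"bed"`
#' @return a `GRanges` named by gene id
#' @export
read_genes <- function(path, format = c("auto", "gff", "gtf", "bed")) {
  format <- match.arg(format)
  stop_if(!file.exists(path), "input file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = "gff", gff3 = "gff", gtf = "gtf",
                     bed = "bed",
                     stop("cannot guess annotation format from extension '",
                          ext, "'", call. = FALSE))
  }
  gr <- rtracklayer::import(path, format = toupper(format))
  if (format %in% c("gff", "gtf") && "type" %in%
      colnames(S4Vectors::mcols(gr))) {
    genes <- gr[as.character(gr$type) == "gene"]
    if (length(genes) > 0) gr <- genes
  }
  mc <- S4Vectors::mcols(gr)
  id_col <- intersect(c("gene_id", "Name", "name", "ID"), colnames(mc))
  if (length(id_col) > 0) {
    names(gr) <- as.character(mc[[id_col[1]]])
  } else if (is.null(names(gr))) {
    names(gr) <- interval_ids(gr)
  }
  gr
}

#' Build a biologically informed peak-to-gene translator mask
#'
#' Entry `[f, g]` is 1 iff peak `f` overlaps the gene body of gene `g`
#' extended by `window_bp` on both sides (half-open overlap test on 0-based
#' half-open coordinates). Distal peaks get all-zero rows. Strand is ignored.
#' The resulting binary matrix constrains the masked-dense translator so
#' that, during the first training phase, a chromatin feature can only feed
#' genes it plausibly regulates by genomic proximity.
#'
#' @param peaks `GRanges` of peaks (rows of the mask), named, or an object
#'   accepted by [genomic_intervals()]
#' @param genes `GRanges` of genes (columns of the mask), named by gene id
#' @param window_bp non-negative extension of the gene body on each side
#'   (default 2000)
#' @return a `MaskMatrix`: sparse binary features x shared-genes matrix with
#'   `feature_ids` and `shared_gene_ids` attributes
#' @export
build_gene_proximity_mask <- function(peaks, genes, window_bp = 2000) {
  stop_if(length(genes) == 0, "empty gene annotation")
  stop_if(window_bp < 0, "window_bp must be non-negative")
  peak_ids <- names(peaks) %||% interval_ids(peaks)
  gene_ids <- names(genes) %||% interval_ids(genes)
  pk_chrom <- as.character(GenomicRanges::seqnames(peaks))
  missing_chrom <- setdiff(unique(pk_chrom),
                           unique(as.character(GenomicRanges::seqnames(genes))))
  if (length(missing_chrom) > 0) {
    warning("peak chromosome(s) absent from gene annotation: ",
            paste(missing_chrom, collapse = ", "),
            "; their mask rows are all zero", call. = FALSE)
  }
  ext <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::resize(
      genes, GenomicRanges::width(genes) + 2L * as.integer(window_bp),
      fix = "center")))
  hits <- GenomicRanges::findOverlaps(peaks, ext, ignore.strand = TRUE)
  mask <- Matrix::sparseMatrix(
    i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits),
    x = 1, dims = c(length(peaks), length(genes)),
    dimnames = list(peak_ids, gene_ids))
  mask@x[] <- 1  # collapse duplicate hits to binary
  structure(mask, class = c(class(mask)),
            feature_ids = peak_ids, shared_gene_ids = gene_ids)
}

#' Write a mask to a MatrixMarket file with id companions
#' @param mask output of [build_gene_proximity_mask()]
#' @param dir output directory
#' @export
write_mask <- function(mask, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(as(mask, "CsparseMatrix"), file.path(dir, "mask.mtx"))
  writeLines(rownames(mask), file.path(dir, "mask_features.tsv"))
  writeLines(colnames(mask), file.path(dir, "mask_genes.tsv"))
  invisible(dir)
}
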