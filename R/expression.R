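# --- RPKM, log matrices, tissue partitions and 2^-ddCt ---------------------

#' RPKM normalization of a read-count matrix
#'
#' `rpkm[g, s] = 1e9 * counts[g, s] / (library_sizes[s] * gene_lengths[g])`
#' (reads per kilobase of transcript per million mapped reads).
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param gene_lengths positive lengths in bp, one per gene (row).
#' @param library_sizes positive total mapped reads, one per sample
#'   (column).
#' @return numeric matrix of RPKM values, same dimnames as `counts`.
#' @examples
#' rpkm(matrix(10), gene_lengths = 1000, library_sizes = 1e6)  # 10
#' @export
rpkm <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths must have one entry per gene")
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per sample")
  if (any(counts < 0)) stop("negative counts")
  bad_g <- which(gene_lengths <= 0)
  if (length(bad_g))
    stop("non-positive gene length for gene ",
         (rownames(counts) %||% seq_len(nrow(counts)))[bad_g[1]])
  bad_s <- which(library_sizes <= 0)
  if (length(bad_s))
    stop("non-positive library size for sample ",
         (colnames(counts) %||% seq_len(ncol(counts)))[bad_s[1]])
  1e9 * sweep(sweep(counts, 2, library_sizes, "/"), 1, gene_lengths, "/")
}

#' Log2 transform of an RPKM matrix
#'
#' @param rpkm_matrix non-negative matrix.
#' @param pseudocount positive offset (default 1, so RPKM 0 maps to 0).
#' @return `log2(rpkm + pseudocount)`.
#' @export
log_matrix <- function(rpkm_matrix, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (any(rpkm_matrix < 0)) stop("negative RPKM values")
  log2(rpkm_matrix + pseudocount)
}

#' Row/column orderings by average-linkage hierarchical clustering
#'
#' Euclidean distance, average linkage — the ordering convention of the
#' usual expression-heatmap tools.
#'
#' @param mat numeric matrix (e.g. a [log_matrix()] result).
#' @return list with integer `rows` and `cols` orderings.
#' @export
expression_order <- function(mat) {
  ord <- function(d) if (nrow(d) > 2)
    hclust(dist(d), method = "average")$order else seq_len(nrow(d))
  list(rows = ord(mat), cols = ord(t(mat)))
}

#' Expressed-gene partition across samples (Venn cells)
#'
#' A gene is expressed in a sample when its RPKM strictly exceeds the
#' threshold. Returns per-sample expressed sets, their union and
#' intersection, per-sample exclusive sets, and the full membership-pattern
#' cell counts, whose sizes sum to the union size.
#'
#' @param rpkm_matrix genes x samples RPKM matrix with dimnames.
#' @param threshold expression cutoff (default 0; the analysis carries the
#'   threshold used in its output).
#' @return list with `expressed` (list per sample), `union`,
#'   `intersection`, `exclusive` (list per sample), `venn` (named integer;
#'   names are sample membership patterns like `"leaf+pl16"`), `threshold`.
#' @export
expression_partition <- function(rpkm_matrix, threshold = 0) {
  stopifnot(threshold >= 0)
  m <- as.matrix(rpkm_matrix)
  genes <- rownames(m) %||% as.character(seq_len(nrow(m)))
  samples <- colnames(m) %||% paste0("S", seq_len(ncol(m)))
  on <- m > threshold
  expressed <- lapply(seq_along(samples), function(j) genes[on[, j]])
  names(expressed) <- samples
  in_union <- rowSums(on) > 0
  pattern <- apply(on, 1, function(r)
    paste(samples[r], collapse = "+"))
  venn_tab <- table(pattern[in_union])
  exclusive <- lapply(seq_along(samples), function(j)
    genes[on[, j] & rowSums(on) == 1])
  names(exclusive) <- samples
  list(expressed = expressed,
       union = genes[in_union],
       intersection = genes[rowSums(on) == ncol(m)],
       exclusive = exclusive,
       venn = setNames(as.integer(venn_tab), names(venn_tab)),
       threshold = threshold)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = mean(Ct_target) - mean(Ct_reference)` over
#' replicates; `ddCt = dCt_sample - dCt_calibrator`;
#' `fold = 2^(-ddCt)`. The calibrator's fold is exactly 1.
#'
#' @param ct_table data.frame with columns `sample`, `gene`, `role`
#'   (`"target"` or `"reference"`), `replicate`, `ct` (cycles, in (0, 45)).
#' @param calibrator sample id used as the calibrator.
#' @return data.frame with `sample`, `delta_ct`, `delta_delta_ct`, `fold`.
#' @examples
#' ct <- data.frame(sample = rep(c("leaf", "pl16"), each = 2),
#'                  gene = rep(c("ANK", "TUB"), 2),
#'                  role = rep(c("target", "reference"), 2),
#'                  replicate = 1, ct = c(30, 26, 28, 26))
#' ddct(ct, calibrator = "leaf")
#' @export
ddct <- function(ct_table, calibrator) {
  need <- c("sample", "gene", "role", "replicate", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  if (any(ct_table$ct <= 0 | ct_table$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  if (!calibrator %in% ct_table$sample)
    stop("calibrator sample '", calibrator, "' not in table")
  samples <- unique(ct_table$sample)
  dct <- vapply(samples, function(s) {
    sub <- ct_table[ct_table$sample == s, , drop = FALSE]
    tgt <- sub$ct[sub$role == "target"]
    ref <- sub$ct[sub$role == "reference"]
    if (!length(ref))
      stop("missing reference gene for sample '", s, "'")
    if (!length(tgt))
      stop("missing target gene for sample '", s, "'")
    mean(tgt) - mean(ref)
  }, numeric(1))
  ddct_v <- dct - dct[[calibrator]]
  data.frame(sample = samples,
             delta_ct = unname(dct),
             delta_delta_ct = unname(ddct_v),
             fold = unname(2^(-ddct_v)),
             stringsAsFactors = FALSE)
}
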