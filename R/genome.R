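#' Construct a validated gene model
#'
#' Coordinates are 1-based inclusive throughout (GFF3 convention); exports
#' to BED convert to 0-based half-open.
#'
#' @param gene_id gene identifier.
#' @param seq_id chromosome or scaffold name.
#' @param strand "+" or "-".
#' @param exons two-column matrix or data.frame of exon `start`, `end`
#'   (1-based inclusive); must be sortable into a non-overlapping chain.
#' @return object of class `gene_model`: list with `gene_id`, `seq_id`,
#'   `strand`, `start`, `end` (the span covered by the exons) and `exons`
#'   (sorted matrix).
#' @export
gene_model <- function(gene_id, seq_id, strand, exons) {
  stopifnot(strand %in% c("+", "-"))
  ex <- as.matrix(exons)
  if (ncol(ex) != 2L || nrow(ex) < 1L)
    stop("exons must be a two-column matrix with at least one row")
  storage.mode(ex) <- "integer"
  colnames(ex) <- c("start", "end")
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  if (any(ex[, 2] < ex[, 1]))
    stop("exon with end < start in gene '", gene_id, "'")
  if (nrow(ex) > 1L && any(ex[-1L, 1] <= ex[-nrow(ex), 2]))
    stop("overlapping exons in gene '", gene_id, "'")
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 start = ex[1L, 1], end = ex[nrow(ex), 2], exons = ex),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d(%s) %d exon(s)\n",
              x$gene_id, x$seq_id, x$start, x$end, x$strand, nrow(x$exons)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`/`transcript` and `exon` features (via
#' \pkg{rtracklayer}) into a list of [gene_model()] objects. When a gene has
#' several transcripts the first one in file order is taken as the
#' representative, which keeps exon chains non-overlapping; a gene with no
#' exon rows becomes a single-exon model over its span.
#'
#' @param path GFF3 file.
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parents <- vapply(seq_along(gr), function(i) {
    p <- meta$Parent[[i]]
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))

  gene_idx <- which(type == "gene")
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  exon_idx <- which(type == "exon")
  tx2gene <- setNames(parents[tx_idx], ids[tx_idx])

  models <- list()
  for (g in gene_idx) {
    gid <- ids[g]
    gtx <- ids[tx_idx][!is.na(tx2gene) & tx2gene == gid]
    ex <- integer(0)
    if (length(gtx)) {
      # representative transcript = first in file order
      ex <- exon_idx[parents[exon_idx] %in% gtx[1]]
    }
    if (!length(ex)) ex <- exon_idx[parents[exon_idx] %in% gid]
    exons <- if (length(ex)) {
      cbind(start = BiocGenerics::start(gr)[ex],
            end = BiocGenerics::end(gr)[ex])
    } else {
      cbind(start = BiocGenerics::start(gr)[g],
            end = BiocGenerics::end(gr)[g])
    }
    models[[gid]] <- gene_model(
      gid,
      as.character(GenomeInfoDb::seqnames(gr)[g]),
      as.character(BiocGenerics::strand(gr)[g]),
      exons)
  }
  models
}

#' Tally gene models per chromosome, with scaffolds set aside
#'
#' @param models list of [gene_model()] objects.
#' @param chromosomes declared chromosome names of the assembly; any other
#'   `seq_id` counts as a scaffold. When `NULL`, seq ids containing
#'   "scaffold"/"contig"/"ctg" (case-insensitive) are treated as scaffolds.
#' @return list with `counts` (named integer per chromosome),
#'   `scaffold_genes` (tally) and `total` (grand total, conserved).
#' @export
map_to_chromosomes <- function(models, chromosomes = NULL) {
  if (!length(models))
    return(list(counts = setNames(integer(0), character(0)),
                scaffold_genes = 0L, total = 0L))
  seqs <- vapply(models, function(m) m$seq_id, character(1))
  is_scaf <- if (!is.null(chromosomes)) !(seqs %in% chromosomes)
             else grepl("scaffold|contig|ctg", seqs, ignore.case = TRUE)
  tab <- table(seqs[!is_scaf])
  list(counts = setNames(as.integer(tab), names(tab)),
       scaffold_genes = sum(is_scaf),
       total = length(models))
}

#' Detect gene-density clusters by sliding windows
#'
#' Slides windows of `window_bp` every `step_bp` along each sequence (grid
#' anchored at position 1), flags windows holding at least `min_genes` gene
#' midpoints, and merges overlapping flagged windows into maximal cluster
#' intervals.
#'
#' @param models list of [gene_model()] objects.
#' @param window_bp window width (>= `step_bp`).
#' @param step_bp grid step (> 0).
#' @param min_genes minimum gene midpoints per window (>= 2).
#' @return data.frame with `seq_id`, `start`, `end`, `count`, `gene_ids`
#'   (comma-joined members whose midpoints fall in the merged window).
#' @export
density_clusters <- function(models, window_bp = 2e6, step_bp = 1e5,
                             min_genes = 3L) {
  stopifnot(window_bp >= step_bp, step_bp > 0, min_genes >= 2)
  out <- data.frame(seq_id = character(0), start = numeric(0),
                    end = numeric(0), count = integer(0),
                    gene_ids = character(0), stringsAsFactors = FALSE)
  if (!length(models)) return(out)
  seqs <- vapply(models, function(m) m$seq_id, character(1))
  mids <- vapply(models, function(m) (m$start + m$end) / 2, numeric(1))
  ids <- vapply(models, function(m) m$gene_id, character(1))

  for (sq in unique(seqs)) {
    m <- mids[seqs == sq]; gid <- ids[seqs == sq]
    starts <- seq(1, max(m), by = step_bp)
    n_in <- vapply(starts, function(s)
      sum(m >= s & m <= s + window_bp - 1), integer(1))
    ok <- starts[n_in >= min_genes]
    if (!length(ok)) next
    # merge overlapping flagged windows
    iv <- cbind(ok, ok + window_bp - 1)
    merged <- iv[1, , drop = FALSE]
    if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= merged[nrow(merged), 2])
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
      else merged <- rbind(merged, iv[i, ])
    }
    for (i in seq_len(nrow(merged))) {
      inside <- m >= merged[i, 1] & m <= merged[i, 2]
      out <- rbind(out, data.frame(
        seq_id = sq, start = merged[i, 1], end = merged[i, 2],
        count = sum(inside),
        gene_ids = paste(gid[inside], collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Exon/intron architecture of one gene model
#'
#' Introns are the gaps between consecutive exons. On the minus strand the
#' ordinal numbering (exon 1, intron 1, ...) runs from the transcription
#' start, so the reported length vectors are in transcription order.
#'
#' @param model a [gene_model()] object.
#' @return list with `gene_id`, `exon_count`, `intron_count`,
#'   `exon_lengths`, `intron_lengths` (transcription order), `total_span`
#'   (first to last exonic base, inclusive).
#' @export
structure_summary <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  exon_len <- ex[, 2] - ex[, 1] + 1L
  intron_len <- if (nrow(ex) > 1L)
    ex[-1L, 1] - ex[-nrow(ex), 2] - 1L else integer(0)
  if (model$strand == "-") {
    exon_len <- rev(exon_len)
    intron_len <- rev(intron_len)
  }
  list(gene_id = model$gene_id,
       exon_count = nrow(ex),
       intron_count = nrow(ex) - 1L,
       exon_lengths = unname(exon_len),
       intron_lengths = unname(intron_len),
       total_span = unname(ex[nrow(ex), 2] - ex[1L, 1] + 1L))
}

#' Structure summaries for a set of models, one row per gene
#'
#' @param models list of [gene_model()] objects.
#' @return data.frame with `gene_id`, `seq_id`, `strand`, `exon_count`,
#'   `intron_count`, `total_span`, `exon_lengths`/`intron_lengths`
#'   (comma-joined, transcription order).
#' @export
structure_table <- function(models) {
  rows <- lapply(models, function(m) {
    s <- structure_summary(m)
    data.frame(gene_id = s$gene_id, seq_id = m$seq_id, strand = m$strand,
               exon_count = s$exon_count, intron_count = s$intron_count,
               total_span = s$total_span,
               exon_lengths = paste(s$exon_lengths, collapse = ","),
               intron_lengths = paste(s$intron_lengths, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export models or clusters as BED (0-based half-open)
#'
#' @param models list of [gene_model()] objects.
#' @return data.frame with `chrom`, `start` (0-based), `end`, `name`,
#'   `strand`.
#' @export
models_as_bed <- function(models) {
  rows <- lapply(models, function(m)
    data.frame(chrom = m$seq_id, start = m$start - 1L, end = m$end,
               name = m$gene_id, strand = m$strand,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
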