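# --- promoter extraction and IUPAC cis-element scanning --------------------

.validate_iupac <- function(pattern, element = NULL) {
  bad <- setdiff(chars(toupper(pattern)), names(IUPAC_NT))
  if (length(bad))
    stop("invalid IUPAC character(s) '", paste(bad, collapse = ""),
         "' in element ", element %||% "pattern")
  toupper(pattern)
}

#' Reverse complement of an IUPAC nucleotide pattern
#'
#' @param pattern IUPAC string.
#' @return reverse-complemented IUPAC string.
#' @export
revcomp_iupac <- function(pattern) {
  paste(rev(IUPAC_COMPLEMENT[chars(toupper(pattern))]), collapse = "")
}

#' Extract a fixed-width promoter window upstream of the start codon
#'
#' Returns the `window` nucleotides immediately 5' of the CDS start, in the
#' gene's coding orientation (reverse-complemented for minus-strand genes).
#' Windows running off the contig edge are truncated and flagged.
#'
#' @param genome named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param model a [gene_model()]; the CDS start defaults to the model's
#'   most 5' coordinate on its strand.
#' @param window promoter width in bp (default 1500).
#' @param cds_start optional genomic coordinate of the `A` of the start
#'   codon, overriding the model span.
#' @return list with `gene_id`, `sequence` (possibly empty), `truncated`.
#' @export
extract_promoter <- function(genome, model, window = 1500L,
                             cds_start = NULL) {
  if (inherits(genome, "XStringSet")) genome <- as.character(genome)
  if (!model$seq_id %in% names(genome))
    stop("genome has no sequence named '", model$seq_id, "'")
  contig <- genome[[model$seq_id]]
  len <- nchar(contig)
  if (model$strand == "+") {
    s <- cds_start %||% model$start
    from <- max(1L, s - window)
    to <- s - 1L
    truncated <- s - window < 1L
    seqn <- if (to >= from) substr(contig, from, to) else ""
  } else {
    s <- cds_start %||% model$end
    from <- s + 1L
    to <- min(len, s + window)
    truncated <- s + window > len
    seqn <- if (to >= from) {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(contig, from, to))))
    } else ""
  }
  list(gene_id = model$gene_id, sequence = seqn,
       truncated = unname(truncated))
}

#' Scan one promoter for degenerate cis-elements on both strands
#'
#' Exact IUPAC matching (no mismatches, no scores), the convention of
#' plant cis-element catalogs. A plus-strand hit means the pattern matches
#' the promoter as written; a minus-strand hit means the pattern's reverse
#' complement matches. Positions are 1-based offsets of the leftmost
#' matched base within the promoter (5' -> 3' in coding orientation);
#' overlapping matches are all reported.
#'
#' @param promoter nucleotide string over ACGT (N allowed).
#' @param elements data.frame with `name` and `pattern` (IUPAC) columns.
#' @param dedup_palindromes drop the minus-strand duplicate hits of
#'   self-reverse-complementary patterns (default FALSE: palindromes yield
#'   one hit per strand).
#' @return data.frame with `element`, `position`, `strand`.
#' @examples
#' scan_elements("AATTGACC", data.frame(name = "WBOX", pattern = "TTGAC"))
#' @export
scan_elements <- function(promoter, elements, dedup_palindromes = FALSE) {
  stopifnot(all(c("name", "pattern") %in% names(elements)))
  subj <- Biostrings::DNAString(toupper(promoter))
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    nm <- elements$name[i]
    pat <- .validate_iupac(elements$pattern[i], nm)
    if (nchar(pat) > length(subj)) next
    fwd <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(pat), subj, fixed = "subject"))
    rc <- revcomp_iupac(pat)
    rev_hits <- if (dedup_palindromes && rc == pat) integer(0)
      else Biostrings::start(Biostrings::matchPattern(
        Biostrings::DNAString(rc), subj, fixed = "subject"))
    if (length(fwd))
      rows[[length(rows) + 1L]] <- data.frame(
        element = nm, position = fwd, strand = "+",
        stringsAsFactors = FALSE)
    if (length(rev_hits))
      rows[[length(rows) + 1L]] <- data.frame(
        element = nm, position = rev_hits, strand = "-",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(element = character(0), position = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$element, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters
#'
#' @param promoters named character vector of promoter sequences.
#' @inheritParams scan_elements
#' @return data.frame with `gene_id`, `element`, `position`, `strand`.
#' @export
scan_promoters <- function(promoters, elements, dedup_palindromes = FALSE) {
  stopifnot(!is.null(names(promoters)))
  out <- lapply(names(promoters), function(g) {
    h <- scan_elements(promoters[[g]], elements, dedup_palindromes)
    if (nrow(h)) cbind(gene_id = g, h, stringsAsFactors = FALSE)
    else data.frame(gene_id = character(0), element = character(0),
                    position = integer(0), strand = character(0),
                    stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Census of cis-elements across gene promoters
#'
#' "Common" elements are present (>= 1 hit) in every gene of the universe;
#' since that reading of "common" is one of two sensible ones, the census
#' also reports per-element gene counts (sorted descending) so recurrent-
#' but-not-universal elements remain visible.
#'
#' @param hits data.frame with `gene_id` and `element` (from
#'   [scan_promoters()]).
#' @param gene_ids universe of genes; defaults to the genes present in
#'   `hits`.
#' @return list with `common` (character vector), `counts` (data.frame
#'   `element`, `n_genes`, descending), `n_genes`.
#' @export
element_census <- function(hits, gene_ids = NULL) {
  gene_ids <- gene_ids %||% unique(hits$gene_id)
  if (!length(gene_ids))
    return(list(common = character(0),
                counts = data.frame(element = character(0),
                                    n_genes = integer(0),
                                    stringsAsFactors = FALSE),
                n_genes = 0L))
  hits <- hits[hits$gene_id %in% gene_ids, , drop = FALSE]
  pres <- unique(hits[, c("gene_id", "element")])
  tab <- table(pres$element)
  counts <- data.frame(element = names(tab), n_genes = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_genes, counts$element), , drop = FALSE]
  rownames(counts) <- NULL
  list(common = sort(counts$element[counts$n_genes == length(gene_ids)]),
       counts = counts,
       n_genes = length(gene_ids))
}
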