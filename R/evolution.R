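# --- duplication-pair detection, selection and dating ----------------------

# global protein alignment stats for one pair
.pair_alignment_stats <- function(a, b, substitution_matrix = "BLOSUM62",
                                  gap_opening = 10, gap_extension = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  p <- chars(as.character(Biostrings::alignedPattern(pa)))
  s <- chars(as.character(Biostrings::alignedSubject(pa)))
  alen <- length(p)
  both <- p != "-" & s != "-"
  n_both <- sum(both)
  coverage <- 100 * n_both / alen
  identity <- if (n_both) 100 * sum(p[both] == s[both]) / n_both else 0
  list(coverage = coverage, identity = identity,
       aligned_pattern = paste(p, collapse = ""),
       aligned_subject = paste(s, collapse = ""))
}

#' Detect duplicated gene pairs by alignment coverage and identity
#'
#' Every pair of input proteins is globally aligned (BLOSUM-class scores,
#' affine gaps). A pair qualifies when coverage (non-gap-in-both columns /
#' alignment length) and identity (identical / aligned columns) both exceed
#' their thresholds. Qualifying pairs form a graph; only pairs inside
#' connected components carrying at least `min_events` qualifying edges are
#' kept (the "minimum number of duplication events" rule).
#'
#' @param proteins named character vector of >= 2 protein sequences.
#' @param min_coverage,min_identity percentage thresholds (strictly
#'   exceeded; defaults 70/70).
#' @param min_events minimum qualifying edges in a pair's connected
#'   component (default 2).
#' @param substitution_matrix,gap_opening,gap_extension alignment scoring
#'   (defaults BLOSUM62, 10, 0.5).
#' @param keep_all return all scored pairs with `qualifies`/`kept` flags
#'   instead of only the kept ones.
#' @return data.frame with `gene_a`, `gene_b` (lexicographically ordered
#'   within each pair), `coverage`, `identity` and, when `keep_all`,
#'   logical `qualifies` and `kept`.
#' @export
detect_paralogs <- function(proteins, min_coverage = 70, min_identity = 70,
                            min_events = 2L,
                            substitution_matrix = "BLOSUM62",
                            gap_opening = 10, gap_extension = 0.5,
                            keep_all = FALSE) {
  stopifnot(length(proteins) >= 2L, !is.null(names(proteins)))
  ids <- sort(names(proteins))
  pairs <- combn(ids, 2)
  stats <- apply(pairs, 2, function(pr)
    .pair_alignment_stats(proteins[[pr[1]]], proteins[[pr[2]]],
                          substitution_matrix, gap_opening, gap_extension))
  out <- data.frame(
    gene_a = pairs[1, ], gene_b = pairs[2, ],
    coverage = vapply(stats, `[[`, numeric(1), "coverage"),
    identity = vapply(stats, `[[`, numeric(1), "identity"),
    stringsAsFactors = FALSE)
  out$qualifies <- out$coverage > min_coverage & out$identity > min_identity

  out$kept <- FALSE
  q <- out[out$qualifies, , drop = FALSE]
  if (nrow(q)) {
    g <- igraph::graph_from_data_frame(q[, c("gene_a", "gene_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)$membership
    edge_counts <- table(comp[q$gene_a])   # each edge counted at one end
    big <- as.integer(names(edge_counts)[edge_counts >= min_events])
    out$kept <- out$qualifies &
      comp[out$gene_a] %in% big & !is.na(comp[out$gene_a])
  }
  rownames(out) <- NULL
  if (keep_all) out else {
    kept <- out[out$kept, c("gene_a", "gene_b", "coverage", "identity"),
                drop = FALSE]
    rownames(kept) <- NULL
    kept
  }
}

#' Classify a duplication as tandem or segmental
#'
#' Tandem means both genes sit on the same sequence with at most
#' `max_intervening_genes` family members between them in genomic order;
#' anything else (including cross-chromosome pairs) is segmental.
#'
#' @param gene_a,gene_b gene ids of the pair.
#' @param models list of [gene_model()] objects for all family members.
#' @param max_intervening_genes tandem distance cap (default 5).
#' @return `"tandem"` or `"segmental"`.
#' @export
classify_duplication <- function(gene_a, gene_b, models,
                                 max_intervening_genes = 5L) {
  ids <- vapply(models, function(m) m$gene_id, character(1))
  ia <- match(gene_a, ids); ib <- match(gene_b, ids)
  if (is.na(ia) || is.na(ib))
    stop("missing gene model for ",
         paste(c(gene_a, gene_b)[c(is.na(ia), is.na(ib))], collapse = ", "))
  ma <- models[[ia]]; mb <- models[[ib]]
  if (ma$seq_id != mb$seq_id) return("segmental")
  mids <- vapply(models, function(m) (m$start + m$end) / 2, numeric(1))
  on_seq <- vapply(models, function(m) m$seq_id == ma$seq_id, logical(1))
  lo <- min(mids[ia], mids[ib]); hi <- max(mids[ia], mids[ib])
  between <- sum(on_seq & mids > lo & mids < hi &
                   !(ids %in% c(gene_a, gene_b)))
  if (between <= max_intervening_genes) "tandem" else "segmental"
}

#' Thread CDS pairs through their protein alignment (back-translation)
#'
#' Aligns the translated proteins globally and projects the gaps back onto
#' the coding sequences, producing a codon alignment in which every gap is
#' a whole `---` codon. Trailing stop codons are removed first.
#'
#' @param cds_a,cds_b coding sequences with lengths divisible by 3.
#' @inheritParams detect_paralogs
#' @return list with gapped codon strings `a` and `b` of equal length.
#' @export
align_codons <- function(cds_a, cds_b, substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5) {
  thread <- function(aligned_prot, codons) {
    out <- character(length(aligned_prot))
    j <- 0L
    for (i in seq_along(aligned_prot)) {
      if (aligned_prot[i] == "-") out[i] <- "---"
      else { j <- j + 1L; out[i] <- codons[j] }
    }
    paste(out, collapse = "")
  }
  ca <- .check_codons(split_codons(cds_a), "cds_a")
  cb <- .check_codons(split_codons(cds_b), "cds_b")
  pa <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(ca, collapse = "")), no.init.codon = TRUE))
  pb <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(cb, collapse = "")), no.init.codon = TRUE))
  al <- .pair_alignment_stats(pa, pb, substitution_matrix,
                              gap_opening, gap_extension)
  list(a = thread(chars(al$aligned_pattern), ca),
       b = thread(chars(al$aligned_subject), cb))
}

#' Ka/Ks for a CDS pair via protein-guided codon alignment
#'
#' Convenience wrapper: [align_codons()] then [kaks_ng86()].
#'
#' @inheritParams align_codons
#' @return a `kaks_result`, see [kaks_ng86()].
#' @export
kaks_pair <- function(cds_a, cds_b, ...) {
  al <- align_codons(cds_a, cds_b, ...)
  kaks_ng86(al$a, al$b)
}

#' Selection regime from an omega (Ka/Ks) ratio
#'
#' `omega < 1 - band` is purifying, `> 1 + band` positive, in between
#' neutral. Vectorized.
#'
#' @param omega non-negative Ka/Ks ratio(s); NA (undefined) is an error.
#' @param neutral_band half-width of the neutral band around 1 (default 0).
#' @return character vector of "purifying", "positive" or "neutral".
#' @examples
#' classify_selection(c(0.85, 1.05))
#' @export
classify_selection <- function(omega, neutral_band = 0) {
  if (any(is.na(omega)))
    stop("undefined omega: selection cannot be classified")
  if (any(omega < 0)) stop("omega must be >= 0")
  ifelse(omega < 1 - neutral_band, "purifying",
         ifelse(omega > 1 + neutral_band, "positive", "neutral"))
}

#' Date a duplication from synonymous divergence
#'
#' Applies the molecular-clock formula `T = Ks / (2 * lambda)` with lambda
#' in synonymous substitutions per site per year (default 6.96e-9).
#'
#' @param ks synonymous substitutions per synonymous site (>= 0; vector ok).
#' @param lambda clock rate (> 0).
#' @return list with `years` and `mya` (millions of years ago).
#' @examples
#' estimate_divergence_time(0.33)$mya  # 23.71
#' @export
estimate_divergence_time <- function(ks, lambda = DEFAULT_CLOCK_LAMBDA) {
  if (any(ks < 0, na.rm = TRUE)) stop("negative Ks")
  stopifnot(lambda > 0)
  years <- ks / (2 * lambda)
  list(years = years, mya = years / 1e6)
}

#' Summarize a table of paralog-pair Ka/Ks results
#'
#' @param results data.frame with columns `omega` and `t_mya` (one row per
#'   pair); rows with undefined omega are not allowed.
#' @param neutral_band passed to [classify_selection()].
#' @return list (class `pair_table_summary`) with `n_pairs`, `omega_min`,
#'   `omega_max`, `omega_mean`, `t_min`, `t_max`, `t_mean` and
#'   `selection_counts` (named: purifying/neutral/positive; sums to
#'   `n_pairs`).
#' @export
pair_table_summary <- function(results, neutral_band = 0) {
  if (!nrow(results)) stop("empty results table")
  sel <- classify_selection(results$omega, neutral_band)
  counts <- vapply(c("purifying", "neutral", "positive"),
                   function(s) sum(sel == s), integer(1))
  structure(
    list(n_pairs = nrow(results),
         omega_min = min(results$omega), omega_max = max(results$omega),
         omega_mean = mean(results$omega),
         t_min = min(results$t_mya), t_max = max(results$t_mya),
         t_mean = mean(results$t_mya),
         selection_counts = counts),
    class = "pair_table_summary")
}

#' @export
print.pair_table_summary <- function(x, ...) {
  cat(sprintf(
    "%d pairs | omega %.2f-%.2f (mean %.2f) | T %.2f-%.2f MYA (mean %.2f)\n",
    x$n_pairs, x$omega_min, x$omega_max, x$omega_mean,
    x$t_min, x$t_max, x$t_mean))
  print(x$selection_counts)
  invisible(x)
}
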