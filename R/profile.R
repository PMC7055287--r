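#' Build a log-odds repeat profile from a gapless seed alignment
#'
#' Converts a fixed-width, gapless alignment of repeat instances into a
#' position-specific log-odds score table. Cell `[i, a]` is
#' `log2((count(a at i) + pseudocount * background[a]) / (rows + pseudocount)
#' / background[a])`, i.e. a pseudocount-smoothed estimate of how enriched
#' residue `a` is at position `i` relative to the background.
#'
#' @param seed_alignment character vector (or `AAStringSet`) of equal-width
#'   rows over the 20 canonical amino acids.
#' @param pseudocount positive smoothing weight added as
#'   `pseudocount * background[a]` to every count.
#' @param background named residue frequency vector summing to 1; defaults
#'   to uniform (1/20).
#' @return An object of class `repeat_profile`: a list with `width`,
#'   `log_odds` (width x 20 matrix, columns in canonical residue order),
#'   `background`, `consensus` (string of per-column argmax residues) and
#'   `max_score` (the consensus self-score, i.e. the sum of column maxima).
#' @examples
#' prof <- build_profile(c("ACDE", "ACDF", "ACEE"))
#' prof$consensus
#' @export
build_profile <- function(seed_alignment, pseudocount = 1, background = NULL) {
  if (inherits(seed_alignment, "XStringSet"))
    seed_alignment <- as.character(seed_alignment)
  seed_alignment <- toupper(as.character(seed_alignment))
  if (length(seed_alignment) < 1L) stop("seed alignment needs at least one row")
  w <- unique(nchar(seed_alignment))
  if (length(w) != 1L) stop("ragged seed alignment: rows differ in width")
  if (w < 2L) stop("profile width must be >= 2")
  rows <- do.call(rbind, strsplit(seed_alignment, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(rows)), AA_ALPHABET20)
  if (length(bad))
    stop("non-residue character(s) in seed alignment: ",
         paste(bad, collapse = ", "))

  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET20)
  } else {
    background <- background[AA_ALPHABET20]
    if (anyNA(background) || abs(sum(background) - 1) > 1e-9)
      stop("background must cover all 20 residues and sum to 1")
  }

  n <- nrow(rows)
  counts <- t(apply(rows, 2, function(col)
    tabulate(match(col, AA_ALPHABET20), nbins = 20L)))
  colnames(counts) <- AA_ALPHABET20
  bg <- matrix(background, nrow = w, ncol = 20, byrow = TRUE)
  log_odds <- log2(((counts + pseudocount * bg) / (n + pseudocount)) / bg)
  dimnames(log_odds) <- list(NULL, AA_ALPHABET20)

  cons_idx <- apply(log_odds, 1, which.max)
  structure(
    list(width = w,
         log_odds = log_odds,
         background = background,
         consensus = paste(AA_ALPHABET20[cons_idx], collapse = ""),
         max_score = sum(apply(log_odds, 1, max))),
    class = "repeat_profile")
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat("repeat_profile: width", x$width,
      "| consensus", x$consensus,
      "| max self-score", round(x$max_score, 2), "bits\n")
  invisible(x)
}

# score every window of an integer-encoded sequence against the profile
score_windows <- function(seq_int, profile) {
  w <- profile$width
  n_win <- length(seq_int) - w + 1L
  if (n_win < 1L) return(numeric(0))
  sc <- numeric(n_win)
  M <- profile$log_odds
  for (i in seq_len(w))
    sc <- sc + unname(M[i, seq_int[i:(i + n_win - 1L)]])
  sc
}

# greedy selection of non-overlapping windows: descending score, ties broken
# by the smaller start coordinate.
greedy_select <- function(starts, scores, width, seq_len) {
  ord <- order(-scores, starts)
  occupied <- logical(seq_len)
  keep <- integer(0)
  for (k in ord) {
    span <- starts[k]:(starts[k] + width - 1L)
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      keep <- c(keep, k)
    }
  }
  sort(keep)
}

#' Scan a protein for tandem repeat hits with a log-odds profile
#'
#' Scores every length-`width` window as the sum of per-position log-odds
#' lookups, then greedily keeps non-overlapping windows in descending score
#' order among those at or above the threshold. Hits are returned sorted by
#' start, in 1-based inclusive coordinates.
#'
#' Significance (optional) is an expectation-style value: an empirical
#' rank-based tail probability of the hit score among `n_null` windows of
#' shuffled copies of the same sequence, multiplied by the number of windows
#' scanned. When a score exceeds every null score the empirical rank floors
#' at 1/(n_null+1), so the tail is extended with a normal approximation
#' fitted to the null score moments.
#'
#' @param protein a single named character string (name = protein id), or an
#'   unnamed string (id defaults to `"protein"`).
#' @param profile a [build_profile()] result.
#' @param score_threshold minimum window score in bits; default half the
#'   profile's maximum attainable self-score.
#' @param compute_significance logical; add the shuffled-window expectation
#'   value per hit (slower).
#' @param n_null number of shuffled-sequence windows for the null.
#' @param null_seed seed for the shuffling stream, so scans are reproducible.
#' @return data.frame with columns `protein_id`, `label` ("ANK"), `start`,
#'   `end`, `score`, `significance` (NA unless requested).
#' @export
scan_protein <- function(protein, profile,
                         score_threshold = NULL,
                         compute_significance = FALSE,
                         n_null = 1000L, null_seed = 1L) {
  stopifnot(inherits(profile, "repeat_profile"))
  id <- names(protein) %||% "protein"
  if (is.null(names(protein)) || !nzchar(id)) id <- "protein"
  sq <- toupper(as.character(protein[[1]]))
  if (is.null(score_threshold)) score_threshold <- profile$max_score / 2

  empty <- data.frame(protein_id = character(0), label = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), significance = numeric(0),
                      stringsAsFactors = FALSE)
  if (nchar(sq) < profile$width) {
    warning("protein '", id, "' shorter than profile width; no hits")
    return(empty)
  }
  seq_int <- match(chars(sq), AA_ALPHABET20)
  if (anyNA(seq_int))
    stop("protein '", id, "' contains non-canonical residues")

  scores <- score_windows(seq_int, profile)
  cand <- which(scores >= score_threshold)
  if (!length(cand)) return(empty)

  keep <- greedy_select(cand, scores[cand], profile$width, length(seq_int))
  starts <- cand[keep]
  hit_scores <- scores[cand][keep]

  signif <- rep(NA_real_, length(starts))
  if (compute_significance) {
    null_scores <- withr::with_seed(null_seed, {
      out <- numeric(0)
      while (length(out) < n_null)
        out <- c(out, score_windows(sample(seq_int), profile))
      out[seq_len(n_null)]
    })
    mu <- mean(null_scores)
    sdev <- max(sd(null_scores), .Machine$double.eps)
    n_win <- length(scores)
    signif <- vapply(hit_scores, function(s) {
      r <- sum(null_scores >= s)
      p <- if (r > 0) (r + 1) / (n_null + 1)
           else min(1 / (n_null + 1), pnorm(s, mu, sdev, lower.tail = FALSE))
      p * n_win
    }, numeric(1))
  }

  out <- data.frame(protein_id = id, label = "ANK",
                    start = as.integer(starts),
                    end = as.integer(starts + profile$width - 1L),
                    score = unname(hit_scores), significance = signif,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scan a whole proteome
#'
#' Applies [scan_protein()] to each sequence of a named vector and binds the
#' hit tables.
#'
#' @param proteins named character vector of protein sequences.
#' @inheritParams scan_protein
#' @return combined hit data.frame (possibly 0 rows).
#' @export
scan_proteome <- function(proteins, profile, score_threshold = NULL,
                          compute_significance = FALSE,
                          n_null = 1000L, null_seed = 1L) {
  stopifnot(!is.null(names(proteins)))
  out <- lapply(names(proteins), function(id)
    scan_protein(setNames(proteins[id], id), profile,
                 score_threshold = score_threshold,
                 compute_significance = compute_significance,
                 n_null = n_null, null_seed = null_seed))
  do.call(rbind, out)
}

#' Filter scanned candidates by hit significance and sequence redundancy
#'
#' Drops proteins whose best (smallest) hit significance exceeds the cutoff,
#' or that have no repeat hit at all; then collapses exact sequence
#' duplicates, keeping the lexicographically smallest id. The operation is
#' idempotent.
#'
#' @param proteins named character vector of candidate sequences.
#' @param hits hit data.frame as returned by [scan_proteome()] (must carry
#'   `protein_id`, `label`, `significance`).
#' @param significance_cutoff expectation-value retention cutoff (default
#'   1e-5; candidates with best significance above it are deleted).
#' @return list with `retained` (named character vector) and `dropped`
#'   (data.frame of `protein_id`, `reason`).
#' @export
filter_candidates <- function(proteins, hits, significance_cutoff = 1e-5) {
  if (!length(proteins))
    return(list(retained = setNames(character(0), character(0)),
                dropped = data.frame(protein_id = character(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE)))
  stopifnot(!is.null(names(proteins)))
  ank <- hits[hits$label == "ANK", , drop = FALSE]
  best <- vapply(names(proteins), function(id) {
    s <- ank$significance[ank$protein_id == id]
    if (!length(s)) NA_real_ else min(s)
  }, numeric(1))

  dropped <- data.frame(protein_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  no_hit <- names(proteins)[is.na(best)]
  too_weak <- names(proteins)[!is.na(best) & best > significance_cutoff]
  keep <- setdiff(names(proteins), c(no_hit, too_weak))
  if (length(no_hit))
    dropped <- rbind(dropped, data.frame(protein_id = no_hit,
                                         reason = "no repeat hit",
                                         stringsAsFactors = FALSE))
  if (length(too_weak))
    dropped <- rbind(dropped, data.frame(
      protein_id = too_weak,
      reason = sprintf("best significance above %g", significance_cutoff),
      stringsAsFactors = FALSE))

  # redundancy: identical sequences keep the lexicographically smallest id
  keep <- keep[order(keep)]
  seqs <- proteins[keep]
  first <- !duplicated(unname(seqs))
  redundant <- keep[!first]
  if (length(redundant)) {
    kept_for <- vapply(redundant, function(id)
      keep[first][match(proteins[[id]], unname(seqs[first]))], character(1))
    dropped <- rbind(dropped, data.frame(
      protein_id = redundant,
      reason = sprintf("redundant sequence (kept %s)", kept_for),
      stringsAsFactors = FALSE))
  }
  retained <- proteins[keep[first]]
  list(retained = retained,
       dropped = dropped[order(dropped$protein_id), , drop = FALSE])
}

#' Histogram of repeat counts per protein
#'
#' @param hits hit data.frame (`protein_id`, `label`); only `"ANK"` rows are
#'   counted.
#' @param protein_ids optional universe of proteins, so proteins without hits
#'   contribute a zero bin.
#' @return list with `histogram` (named integer vector, names = repeat
#'   counts) and `mode` (modal repeat count; smallest on ties; NA when
#'   empty).
#' @export
repeat_count_histogram <- function(hits, protein_ids = NULL) {
  ank <- hits[hits$label == "ANK", , drop = FALSE]
  ids <- protein_ids %||% unique(ank$protein_id)
  if (!length(ids))
    return(list(histogram = setNames(integer(0), character(0)),
                mode = NA_integer_))
  per_protein <- vapply(ids, function(id)
    sum(ank$protein_id == id), integer(1))
  tab <- table(per_protein)
  hist <- setNames(as.integer(tab), names(tab))
  mode <- as.integer(names(hist)[which.max(hist)])
  list(histogram = hist, mode = mode)
}

#' Export repeat hits as 0-based half-open (BED-like) intervals
#'
#' @param hits 1-based inclusive hit data.frame from [scan_proteome()].
#' @return data.frame with `chrom` (protein id), `start` (0-based), `end`
#'   (exclusive), `name`, `score`.
#' @export
hits_as_bed <- function(hits) {
  data.frame(chrom = hits$protein_id,
             start = hits$start - 1L,
             end = hits$end,
             name = hits$label,
             score = hits$score,
             stringsAsFactors = FALSE)
}
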