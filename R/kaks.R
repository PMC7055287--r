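# --- Nei-Gojobori (1986) codon counting with Jukes-Cantor correction -------

genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0)
    stop("coding sequence length not divisible by 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# all permutations of a short vector (<= 3 elements needed here)
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# per-codon fractional synonymous/non-synonymous site counts; changes to
# stop codons count as non-synonymous.
.build_site_table <- function() {
  gc <- genetic_code()
  codons <- sense_codons()
  # syn3 = integer count of synonymous single-base neighbors (sites in
  # thirds); keeping the integer lets S + N = 3L hold exactly in floats.
  syn3 <- vapply(codons, function(cod) {
    cc <- chars(cod)
    syn <- 0L
    for (p in 1:3) for (b in setdiff(DNA_BASES, cc[p])) {
      alt <- cc; alt[p] <- b
      alt <- paste(alt, collapse = "")
      if (gc[[alt]] != "*" && gc[[alt]] == gc[[cod]]) syn <- syn + 1L
    }
    syn
  }, integer(1))
  cbind(syn3 = syn3, S = syn3 / 3, N = 3 - syn3 / 3)
}

site_table <- function() {
  if (is.null(.ankfam_cache$site_table))
    .ankfam_cache$site_table <- .build_site_table()
  .ankfam_cache$site_table
}

# pathway-averaged synonymous/non-synonymous difference counts for one
# codon pair. Pathways through stop codons are excluded; if every pathway
# is blocked, all pathways are used and stop-passing steps count as
# non-synonymous (the stop "amino acid" differs from any residue).
.pathway_counts <- function(c1, c2) {
  gc <- genetic_code()
  pos <- which(chars(c1) != chars(c2))
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  paths <- .perms(pos)
  walk <- function(ord) {
    cur <- chars(c1); tgt <- chars(c2)
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- tgt[p]
      a1 <- gc[[paste(cur, collapse = "")]]
      a2 <- gc[[paste(nxt, collapse = "")]]
      if (a2 == "*") blocked <- TRUE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  res <- lapply(paths, walk)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  c(Sd = mean(vapply(res[ok], `[[`, numeric(1), "sd")),
    Nd = mean(vapply(res[ok], `[[`, numeric(1), "nd")))
}

# 61x61 pathway-count matrices over sense codons, built once per session.
pathway_matrices <- function() {
  if (is.null(.ankfam_cache$SD)) {
    codons <- sense_codons()
    n <- length(codons)
    SD <- matrix(0, n, n, dimnames = list(codons, codons))
    ND <- SD
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      pc <- .pathway_counts(codons[i], codons[j])
      SD[i, j] <- pc[["Sd"]]
      ND[i, j] <- pc[["Nd"]]
    }
    .ankfam_cache$SD <- SD
    .ankfam_cache$ND <- ND
  }
  list(SD = .ankfam_cache$SD, ND = .ankfam_cache$ND)
}

# validate codons of one sequence: returns codons with ambiguity flags;
# errors on internal stops, silently drops a trailing stop.
.check_codons <- function(codons, label) {
  gc <- genetic_code()
  known <- codons %in% names(gc)
  aa <- rep(NA_character_, length(codons))
  aa[known] <- gc[codons[known]]
  stops <- which(!is.na(aa) & aa == "*")
  if (length(stops)) {
    if (any(stops < length(codons)))
      stop("internal stop codon in ", label, " at codon ",
           stops[stops < length(codons)][1])
    codons <- codons[-length(codons)]   # trailing stop dropped
  }
  codons
}

#' Fractional synonymous and non-synonymous site counts (NG86)
#'
#' For each codon, each of the nine possible single-nucleotide changes is
#' classified against the standard genetic code; changes creating a stop
#' codon count as non-synonymous. The synonymous fraction per position is
#' summed into S; N = 3 - S per codon, so S + N = 3L exactly.
#'
#' @param cds coding sequence (length divisible by 3, no internal stop). A
#'   trailing stop codon is dropped. Codons with non-ACGT characters are
#'   skipped with a warning.
#' @return named numeric `c(S, N)` of fractional site counts.
#' @examples
#' count_sites_ng86("TGG")  # Trp: S = 0, N = 3
#' @export
count_sites_ng86 <- function(cds) {
  codons <- .check_codons(split_codons(cds), "cds")
  ambig <- !codons %in% sense_codons()
  if (any(ambig)) {
    warning(sum(ambig), " codon(s) with ambiguous/non-ACGT bases skipped")
    codons <- codons[!ambig]
  }
  st <- site_table()
  s3 <- sum(st[codons, "syn3"])
  n <- length(codons)
  c(S = s3 / 3, N = (9 * n - s3) / 3)
}

jc_correct <- function(p) abs(-3 / 4 * log(1 - 4 * p / 3))

#' NG86 Ka/Ks for a pairwise codon alignment
#'
#' Site counts are averaged over the two sequences; synonymous and
#' non-synonymous differences are counted per codon with equal-weight
#' averaging over all minimal substitution pathways (pathways through stop
#' codons excluded); proportions `ps = Sd/S`, `pn = Nd/N` receive the
#' Jukes-Cantor multiple-hit correction `d = -(3/4) ln(1 - 4p/3)`.
#'
#' @param cds_a,cds_b aligned coding sequences of equal length divisible by
#'   3. Codon pairs in which either codon contains a gap (`-`) or ambiguous
#'   base are dropped pairwise.
#' @return object of class `kaks_result`: list with `n_codons` (compared),
#'   `S_sites`, `N_sites`, `Sd`, `Nd`, `ps`, `pn`, `Ka`, `Ks`, `omega`
#'   (NA when Ks = 0) and `omega_defined`.
#' @examples
#' kaks_ng86("TTTAAA", "TTCAAA")  # one synonymous difference
#' @export
kaks_ng86 <- function(cds_a, cds_b) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  if (length(ca) != length(cb))
    stop("aligned sequences differ in length")
  usable <- ca %in% names(genetic_code()) & cb %in% names(genetic_code())
  n_dropped <- sum(!usable)
  if (n_dropped)
    warning(n_dropped, " codon pair(s) with gaps/ambiguity dropped")
  ca <- .check_codons(ca[usable], "first sequence")
  cb <- .check_codons(cb[usable], "second sequence")
  n <- min(length(ca), length(cb))
  ca <- ca[seq_len(n)]; cb <- cb[seq_len(n)]
  if (!n) stop("no comparable codons")

  st <- site_table()
  s3 <- sum(st[ca, "syn3"]) + sum(st[cb, "syn3"])
  S <- s3 / 6
  N <- (18 * n - s3) / 6
  pm <- pathway_matrices()
  Sd <- sum(pm$SD[cbind(ca, cb)])
  Nd <- sum(pm$ND[cbind(ca, cb)])

  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else 0
  if ((!is.na(ps) && ps >= 3 / 4) || pn >= 3 / 4)
    stop("divergence saturates JC correction (p >= 3/4)")
  Ks <- if (is.na(ps)) NA_real_ else jc_correct(ps)
  Ka <- jc_correct(pn)
  omega_defined <- !is.na(Ks) && Ks > 0
  structure(
    list(n_codons = n, S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
         ps = ps, pn = pn, Ka = Ka, Ks = Ks,
         omega = if (omega_defined) Ka / Ks else NA_real_,
         omega_defined = omega_defined,
         dropped_codons = n_dropped),
    class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "NG86: %d codons | S=%.2f N=%.2f | Ka=%.4f Ks=%.4f | omega=%s\n",
    x$n_codons, x$S_sites, x$N_sites, x$Ka,
    ifelse(is.na(x$Ks), NaN, x$Ks),
    if (x$omega_defined) sprintf("%.4f", x$omega) else "undefined"))
  invisible(x)
}
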