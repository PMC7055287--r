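# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, seqinr's genetic code, base regex.

# --- profile scanning -------------------------------------------------------

# score one window by looping over per-position table lookups
oracle_window_score <- function(sequence, start, profile) {
  cc <- strsplit(sequence, "")[[1]]
  s <- 0
  for (i in seq_len(profile$width))
    s <- s + profile$log_odds[i, cc[start + i - 1]]
  unname(s)
}

# score every window with the loop scorer
oracle_all_scores <- function(sequence, profile) {
  n <- nchar(sequence) - profile$width + 1
  vapply(seq_len(n), function(s) oracle_window_score(sequence, s, profile),
         numeric(1))
}

# exhaustive maximum-weight selection of non-overlapping fixed-width windows
oracle_best_subset <- function(starts, scores, width) {
  n <- length(starts)
  best <- list(score = 0, idx = integer(0))
  for (k in 0:n) for (sub in if (k == 0) list(integer(0))
                       else utils::combn(n, k, simplify = FALSE)) {
    st <- sort(starts[sub])
    if (length(st) > 1 && any(diff(st) < width)) next
    sc <- sum(scores[sub])
    if (sc > best$score) best <- list(score = sc, idx = sub)
  }
  best
}

# --- NG86 -------------------------------------------------------------------

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

# recursive pathway enumeration between two codons; returns equal-weight
# mean syn/nonsyn step counts over stop-free pathways (all pathways if
# every one is blocked, stop steps counted non-synonymous).
oracle_pathways <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  recurse <- function(cur, sd, nd, blocked) {
    pos <- which(cur != b)
    if (!length(pos))
      return(list(list(sd = sd, nd = nd, blocked = blocked)))
    out <- list()
    for (p in pos) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- oracle_translate(paste(cur, collapse = ""))
      aa2 <- oracle_translate(paste(nxt, collapse = ""))
      step_syn <- identical(aa1, aa2)
      out <- c(out, recurse(nxt,
                            sd + as.integer(step_syn),
                            nd + as.integer(!step_syn),
                            blocked || aa2 == "*"))
    }
    out
  }
  res <- recurse(a, 0, 0, FALSE)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  c(Sd = mean(vapply(res[ok], `[[`, numeric(1), "sd")),
    Nd = mean(vapply(res[ok], `[[`, numeric(1), "nd")))
}

# fractional sites per codon by direct enumeration of the 9 mutations
oracle_codon_sites <- function(codon) {
  cc <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), cc[p])) {
    alt <- cc; alt[p] <- b
    aa <- oracle_translate(paste(alt, collapse = ""))
    if (aa != "*" && aa == oracle_translate(codon)) syn <- syn + 1
  }
  c(S = syn / 3, N = 3 - syn / 3)
}

oracle_sense_codons <- function() {
  all <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                           c("A","C","G","T")), 1, paste, collapse = "")
  all[vapply(all, function(cd) oracle_translate(cd) != "*", logical(1))]
}

# --- IUPAC scanning ---------------------------------------------------------

iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
           M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
           N = "[ACGT]")
  paste(map[strsplit(pattern, "")[[1]]], collapse = "")
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# all (overlapping) match starts of an IUPAC pattern via regex lookahead
oracle_iupac_hits <- function(sequence, pattern) {
  fwd <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), sequence,
                  perl = TRUE)[[1]]
  rev <- gregexpr(paste0("(?=", iupac_regex(oracle_revcomp(pattern)), ")"),
                  sequence, perl = TRUE)[[1]]
  list(fwd = as.integer(fwd[fwd > 0]), rev = as.integer(rev[rev > 0]))
}

# --- misc -------------------------------------------------------------------

random_protein <- function(n) paste(sample(AA_ALPHABET20, n,
                                           replace = TRUE), collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# a random valid gene model on a given seq
random_gene_model <- function(id, seq_id = "chr1") {
  n_ex <- sample(1:8, 1)
  ex_len <- sample(50:400, n_ex, replace = TRUE)
  int_len <- if (n_ex > 1) sample(30:1500, n_ex - 1, replace = TRUE)
             else integer(0)
  start <- sample(1:1e6, 1)
  starts <- start + cumsum(c(0, head(ex_len, -1) + int_len))
  gene_model(id, seq_id, sample(c("+", "-"), 1),
             cbind(starts, starts + ex_len - 1))
}
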