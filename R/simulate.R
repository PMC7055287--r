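# --- seeded synthetic-data generators with planted truth -------------------

# default repeat-count distribution over 1..19 copies: 2-5 copies are the
# most common, with a long thin tail up to 19.
default_repeat_probs <- function() {
  w <- c(2, 5, 5, 5, 4, 2, 1.5, 1, 0.8, 0.6, 0.5, 0.4, 0.3, 0.25,
         0.2, 0.15, 0.12, 0.1, 0.08)
  setNames(w / sum(w), 1:19)
}

# default subfamily mixture: mostly repeat-only (U) and transmembrane (TM)
# proteins, a sprinkle of the rarer architectures, ~7% "other".
default_subfamily_probs <- function() {
  c("ANK-U" = 0.50, "ANK-TM" = 0.33, "ANK-ZnF" = 0.02, "ANK-BTB" = 0.02,
    "ANK-ACBP" = 0.01, "ANK-GPCR" = 0.01, "ANK-PK" = 0.02,
    "ANK-BPA" = 0.01, "ANK-IQ" = 0.01, "ANK-O" = 0.07)
}

.subfamily_evidence <- c(
  "ANK-TM" = "TM", "ANK-PK" = "PK", "ANK-ZnF" = "ZnF", "ANK-BTB" = "BTB",
  "ANK-ACBP" = "ACBP", "ANK-GPCR" = "GPCR", "ANK-BPA" = "BPA",
  "ANK-IQ" = "IQ", "ANK-RF" = "RF", "ANK-TPR" = "TPR", "ANK-O" = "BROMO")

#' Simulate a repeat-protein family with planted truth
#'
#' Members carry `k` tandem copies of the profile consensus (k drawn from
#' `repeat_probs`), each copy independently mutated at `substitution_rate`
#' per position, flanked by random background sequence. Decoys are
#' per-sequence shuffles of members (same composition, repeats destroyed).
#' Extra non-ANK domains implied by each member's subfamily label are
#' recorded as annotations only. Byte-identical output under the same seed.
#'
#' @param n_members,n_decoys numbers of family members and decoys (>= 0).
#' @param repeat_probs named probability vector over repeat counts 1..19.
#' @param flank_length residues of random flank on each side.
#' @param profile [build_profile()] result; default the packaged repeat
#'   seed.
#' @param substitution_rate per-position probability that a planted repeat
#'   position deviates from the consensus (default 0.1).
#' @param subfamily_probs named probabilities over subfamily labels.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return list with `proteins` (named character: members then decoys),
#'   `domains` (data.frame `protein_id`, `label`, `start`, `end`: planted
#'   ANK repeats plus one extra domain per non-U member) and `truth` (list:
#'   `repeats` data.frame, `repeat_counts` named integer, `subfamilies`
#'   data.frame, `member_ids`, `decoy_ids`).
#' @export
simulate_family <- function(n_members = 200L, n_decoys = 200L,
                            repeat_probs = default_repeat_probs(),
                            flank_length = 60L,
                            profile = NULL,
                            substitution_rate = 0.1,
                            subfamily_probs = default_subfamily_probs(),
                            seed = 1L) {
  stopifnot(n_members >= 0, n_decoys >= 0, flank_length >= 0,
            substitution_rate >= 0, substitution_rate < 1)
  if (abs(sum(repeat_probs) - 1) > 1e-9)
    stop("repeat_probs must sum to 1")
  if (abs(sum(subfamily_probs) - 1) > 1e-9)
    stop("subfamily_probs must sum to 1")
  profile <- profile %||% build_profile(ank_seed_alignment())
  if (profile$width < 2) stop("impossible spec: zero-width profile")
  cons <- chars(profile$consensus)
  w <- profile$width
  bg <- profile$background

  withr::with_seed(seed, {
    proteins <- character(0)
    repeats <- list()
    subfam <- list()
    domains <- list()
    counts <- integer(0)
    member_ids <- if (n_members)
      sprintf("FAM%04d", seq_len(n_members)) else character(0)

    for (i in seq_len(n_members)) {
      id <- member_ids[i]
      k <- as.integer(sample(names(repeat_probs), 1, prob = repeat_probs))
      counts[id] <- k
      copies <- vapply(seq_len(k), function(j) {
        cc <- cons
        mut <- runif(w) < substitution_rate
        if (any(mut))
          cc[mut] <- vapply(cc[mut], function(orig)
            sample(setdiff(AA_ALPHABET20, orig), 1,
                   prob = bg[setdiff(AA_ALPHABET20, orig)]), character(1))
        paste(cc, collapse = "")
      }, character(1))
      flankL <- paste(sample(AA_ALPHABET20, flank_length, TRUE, bg),
                      collapse = "")
      flankR <- paste(sample(AA_ALPHABET20, flank_length, TRUE, bg),
                      collapse = "")
      proteins[id] <- paste0(flankL, paste(copies, collapse = ""), flankR)
      starts <- flank_length + (seq_len(k) - 1L) * w + 1L
      repeats[[id]] <- data.frame(protein_id = id, start = starts,
                                  end = starts + w - 1L,
                                  stringsAsFactors = FALSE)
      sf <- sample(names(subfamily_probs), 1, prob = subfamily_probs)
      subfam[[id]] <- data.frame(protein_id = id, subfamily = sf,
                                 stringsAsFactors = FALSE)
      dom <- data.frame(protein_id = id, label = "ANK",
                        start = starts, end = starts + w - 1L,
                        stringsAsFactors = FALSE)
      if (sf != "ANK-U") {
        extra_end <- max(2L, min(flank_length, 20L))
        dom <- rbind(dom, data.frame(
          protein_id = id, label = unname(.subfamily_evidence[sf]),
          start = 1L, end = extra_end, stringsAsFactors = FALSE))
      }
      domains[[id]] <- dom
    }

    decoy_ids <- if (n_decoys)
      sprintf("DEC%04d", seq_len(n_decoys)) else character(0)
    for (i in seq_len(n_decoys)) {
      src <- if (n_members) proteins[[((i - 1L) %% n_members) + 1L]]
             else paste(sample(AA_ALPHABET20, flank_length + 3L * w, TRUE,
                               bg), collapse = "")
      proteins[decoy_ids[i]] <- paste(sample(chars(src)), collapse = "")
    }

    list(proteins = proteins,
         domains = if (length(domains)) do.call(rbind, c(domains,
             list(make.row.names = FALSE)))
           else data.frame(protein_id = character(0), label = character(0),
                           start = integer(0), end = integer(0),
                           stringsAsFactors = FALSE),
         truth = list(
           repeats = if (length(repeats)) do.call(rbind, c(repeats,
               list(make.row.names = FALSE)))
             else data.frame(protein_id = character(0), start = integer(0),
                             end = integer(0), stringsAsFactors = FALSE),
           repeat_counts = counts,
           subfamilies = if (length(subfam)) do.call(rbind, c(subfam,
               list(make.row.names = FALSE)))
             else data.frame(protein_id = character(0),
                             subfamily = character(0),
                             stringsAsFactors = FALSE),
           member_ids = member_ids,
           decoy_ids = decoy_ids))
  })
}

#' Simulate a diverged paralogous CDS pair with known omega and Ks
#'
#' An ancestral CDS of `n_codons` sense codons is mutated by a
#' proposal/acceptance scheme: point mutations are proposed uniformly over
#' positions and alternative bases at a total rate tuned so that the
#' expected number of synonymous substitutions per synonymous site equals
#' `ks`; proposals creating stop codons are rejected; non-synonymous
#' proposals are accepted with probability `min(omega, 1)`, synonymous ones
#' always. The truth omega is therefore the acceptance ratio, which NG86
#' estimates consistently at low divergence.
#'
#' @param n_codons codons in the alignment (>= 10).
#' @param omega true Ka/Ks acceptance ratio (>= 0).
#' @param ks true expected synonymous substitutions per synonymous site
#'   (>= 0).
#' @param seed integer seed.
#' @return list with `ancestor`, `derived` (codon strings) and `truth`
#'   (list `omega`, `ks`, `n_events` accepted substitutions).
#' @export
simulate_paralog_pair <- function(n_codons = 300L, omega = 0.5, ks = 0.3,
                                  seed = 1L) {
  stopifnot(n_codons >= 10L, omega >= 0, ks >= 0)
  gc <- genetic_code()
  acc <- min(omega, 1)
  withr::with_seed(seed, {
    anc <- sample(sense_codons(), n_codons, replace = TRUE)
    der <- anc
    n_prop <- rpois(1, ks * 3 * n_codons)
    accepted <- 0L
    for (m in seq_len(n_prop)) {
      pos <- sample.int(3L * n_codons, 1L)
      ci <- (pos - 1L) %/% 3L + 1L
      off <- (pos - 1L) %% 3L + 1L
      cod <- chars(der[ci])
      alt <- sample(setdiff(DNA_BASES, cod[off]), 1L)
      new <- cod; new[off] <- alt
      new <- paste(new, collapse = "")
      if (gc[[new]] == "*") next                       # no stops introduced
      syn <- gc[[new]] == gc[[der[ci]]]
      if (syn || runif(1) < acc) {
        der[ci] <- new
        accepted <- accepted + 1L
      }
    }
    list(ancestor = paste(anc, collapse = ""),
         derived = paste(der, collapse = ""),
         truth = list(omega = omega, ks = ks, n_events = accepted))
  })
}

#' Simulate a count table with known RPKM truth
#'
#' Counts are drawn from a negative binomial (gamma-mixed Poisson) whose
#' mean matches the truth RPKM given the gene lengths and library sizes:
#' `mu = true_rpkm * length * library_size / 1e9`.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples.
#' @param true_rpkm truth expression per gene (scalar or length-`n_genes`;
#'   zeros allowed and preserved exactly).
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`);
#'   0 gives Poisson counts.
#' @param length_range gene length sampling range in bp.
#' @param library_size scalar or per-sample totals of mapped reads.
#' @param seed integer seed.
#' @return list with `counts` (matrix), `gene_lengths`, `library_sizes`,
#'   `truth` (data.frame `gene_id`, `true_rpkm`).
#' @export
simulate_counts <- function(n_genes = 1000L, n_samples = 4L,
                            true_rpkm = 50, dispersion = 0.3,
                            length_range = c(500L, 5000L),
                            library_size = 2e7, seed = 1L) {
  stopifnot(n_genes > 0, n_samples > 0, all(true_rpkm >= 0),
            dispersion >= 0, all(length_range > 0), all(library_size > 0))
  true_rpkm <- rep_len(true_rpkm, n_genes)
  library_size <- rep_len(library_size, n_samples)
  withr::with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    samples <- sprintf("S%02d", seq_len(n_samples))
    lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    mu <- outer(true_rpkm * lens, library_size) / 1e9
    counts <- matrix(0L, n_genes, n_samples, dimnames = list(genes, samples))
    pos <- mu > 0
    counts[pos] <- if (dispersion > 0)
      rnbinom(sum(pos), mu = mu[pos], size = 1 / dispersion)
    else rpois(sum(pos), mu[pos])
    list(counts = counts,
         gene_lengths = setNames(lens, genes),
         library_sizes = setNames(library_size, samples),
         truth = data.frame(gene_id = genes, true_rpkm = true_rpkm,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate promoter windows with planted cis-elements
#'
#' Background sequence at the requested GC content with concrete
#' realizations of IUPAC elements spliced in at truth positions (random
#' non-overlapping placements per gene unless `positions` supplies them);
#' minus-strand plants insert the reverse complement of the realization.
#'
#' @param n_genes number of promoters.
#' @param window promoter width in bp.
#' @param elements data.frame `name`, `pattern` to plant (each once per
#'   gene); defaults to three defense-related elements from the packaged
#'   catalog.
#' @param positions optional data.frame `gene_id`, `element`, `position`,
#'   `strand` of explicit plants; overlapping plants are an error.
#' @param gc background GC fraction.
#' @param seed integer seed.
#' @return list with `promoters` (named character) and `truth` (data.frame
#'   `gene_id`, `element`, `position`, `strand`).
#' @export
simulate_promoters <- function(n_genes = 100L, window = 1500L,
                               elements = NULL, positions = NULL,
                               gc = 0.4, seed = 1L) {
  stopifnot(n_genes >= 0, window > 0, gc > 0, gc < 1)
  elements <- elements %||% {
    cat_df <- cis_element_catalog()
    cat_df[cat_df$name %in% c("WBOXATNPR1", "ASF1MOTIFCAMV", "GCCCORE"), ]
  }
  for (i in seq_len(nrow(elements)))
    .validate_iupac(elements$pattern[i], elements$name[i])
  if (any(nchar(elements$pattern) > window))
    stop("planted element longer than the window")
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  realize <- function(pattern)
    paste(vapply(chars(pattern), function(ch) {
      opts <- IUPAC_NT[[ch]]
      if (length(opts) == 1) opts else sample(opts, 1)
    }, character(1)), collapse = "")

  withr::with_seed(seed, {
    genes <- sprintf("PRM%04d", seq_len(n_genes))
    promoters <- setNames(vapply(genes, function(g)
      paste(sample(DNA_BASES, window, TRUE, base_probs), collapse = ""),
      character(1)), genes)
    truth <- list()
    occupied <- lapply(genes, function(g) logical(window))
    names(occupied) <- genes

    plant_one <- function(g, nm, pat, pos, strand) {
      len <- nchar(pat)
      span <- pos:(pos + len - 1L)
      if (any(occupied[[g]][span]))
        stop("overlapping planted elements in ", g)
      occupied[[g]][span] <<- TRUE
      insert <- realize(pat)
      if (strand == "-")
        insert <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(insert)))
      s <- promoters[[g]]
      promoters[[g]] <<- paste0(substr(s, 1, pos - 1L), insert,
                                substr(s, pos + len, window))
      truth[[length(truth) + 1L]] <<- data.frame(
        gene_id = g, element = nm, position = pos, strand = strand,
        stringsAsFactors = FALSE)
    }

    if (!is.null(positions)) {
      pat_of <- setNames(elements$pattern, elements$name)
      for (i in seq_len(nrow(positions)))
        plant_one(positions$gene_id[i], positions$element[i],
                  pat_of[[positions$element[i]]],
                  positions$position[i], positions$strand[i])
    } else {
      for (g in genes) for (i in seq_len(nrow(elements))) {
        len <- nchar(elements$pattern[i])
        for (try in 1:200) {
          pos <- sample.int(window - len + 1L, 1L)
          if (!any(occupied[[g]][pos:(pos + len - 1L)])) break
          if (try == 200) stop("could not place element without overlap")
        }
        plant_one(g, elements$name[i], elements$pattern[i], pos,
                  sample(c("+", "-"), 1))
      }
    }
    list(promoters = promoters,
         truth = if (length(truth)) do.call(rbind, c(truth,
             list(make.row.names = FALSE)))
           else data.frame(gene_id = character(0), element = character(0),
                           position = integer(0), strand = character(0),
                           stringsAsFactors = FALSE))
  })
}

#' Simulate gene placements across chromosomes and scaffolds
#'
#' Random gene models (placement, strand, exon chain) for exercising the
#' chromosome mapping, clustering and structure summaries against planted
#' truth.
#'
#' @param n_genes number of genes.
#' @param chromosomes chromosome names.
#' @param chrom_length chromosome length in bp.
#' @param scaffold_fraction fraction of genes placed on scaffolds.
#' @param max_exons maximum exons per gene.
#' @param seed integer seed.
#' @return list with `models` (list of [gene_model()]) and `truth`
#'   (data.frame `gene_id`, `seq_id`, `is_scaffold`).
#' @export
simulate_gene_models <- function(n_genes = 100L,
                                 chromosomes = paste0("chr", 1:12),
                                 chrom_length = 5e7,
                                 scaffold_fraction = 0.1,
                                 max_exons = 10L, seed = 1L) {
  stopifnot(n_genes >= 0, scaffold_fraction >= 0, scaffold_fraction < 1)
  withr::with_seed(seed, {
    models <- list()
    truth <- list()
    for (i in seq_len(n_genes)) {
      gid <- sprintf("SIMG%04d", i)
      on_scaf <- runif(1) < scaffold_fraction
      sq <- if (on_scaf) sprintf("scaffold_%d", sample.int(50, 1))
            else sample(chromosomes, 1)
      n_ex <- sample.int(max_exons, 1)
      ex_len <- sample(100:500, n_ex, replace = TRUE)
      intron_len <- if (n_ex > 1) sample(80:2000, n_ex - 1, replace = TRUE)
                    else integer(0)
      start <- sample.int(chrom_length - sum(ex_len) - sum(intron_len), 1)
      starts <- start + cumsum(c(0L, ex_len[-n_ex] + intron_len))
      ends <- starts + ex_len - 1L
      models[[gid]] <- gene_model(gid, sq, sample(c("+", "-"), 1),
                                  cbind(starts, ends))
      truth[[gid]] <- data.frame(gene_id = gid, seq_id = sq,
                                 is_scaffold = on_scaf,
                                 stringsAsFactors = FALSE)
    }
    list(models = models,
         truth = if (length(truth)) do.call(rbind, c(truth,
             list(make.row.names = FALSE)))
           else data.frame(gene_id = character(0), seq_id = character(0),
                           is_scaffold = logical(0),
                           stringsAsFactors = FALSE))
  })
}
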