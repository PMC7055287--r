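# --- packaged reference tables and seed data -------------------------------

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "ankfam", mustWork = TRUE)
  path
}

#' Packaged seed alignment for the ~33-residue ankyrin repeat
#'
#' A small synthetic, gapless width-33 alignment of repeat instances built
#' around a canonical ankyrin-repeat consensus (helix-turn-helix +
#' beta-hairpin motif vocabulary). It is constructed, not extracted from
#' any database, and exists to give [build_profile()] a sensible default.
#'
#' @return character vector of aligned rows.
#' @export
ank_seed_alignment <- function() {
  x <- Biostrings::readAAStringSet(.extdata("ank_repeat_seed_synthetic.fasta"))
  setNames(as.character(x), names(x))
}

#' Packaged catalog of plant cis-regulatory elements
#'
#' ~30 PLACE-style degenerate elements (IUPAC patterns) commonly surveyed
#' in plant promoter analyses (W-box, as-1, GCC-box, I-box, GT-1, MYB/MYC
#' cores, light- and hormone-response motifs, ...). Users with full catalog
#' needs should supply their own table in the same two-column format.
#'
#' @return data.frame with `name` and `pattern`.
#' @export
cis_element_catalog <- function() {
  read.delim(.extdata("place_cis_elements.tsv"),
             stringsAsFactors = FALSE)
}

#' Published Ka/Ks table for syntenic pepper ankyrin paralog pairs
#'
#' The 23 printed paralog-pair rows (synonymous and non-synonymous site
#' counts, Ka, Ks, omega, selection call, duplication time in MYA) carried
#' as a fixture for the downstream classification and summary operations.
#' The printed values are reproduced as printed, at their original 2-decimal
#' precision; they are inputs here, not recomputed quantities.
#'
#' @return data.frame with `gene_a`, `gene_b`, `s_sites`, `n_sites`, `ka`,
#'   `ks`, `omega`, `selection`, `t_mya`.
#' @export
capsicum_paralog_table <- function() {
  read.delim(.extdata("capsicum_ank_paralogs.tsv"),
             stringsAsFactors = FALSE)
}

#' Published family-size census across plant species
#'
#' Family member counts, annotated proteome sizes and the printed
#' percent-of-proteome for the three pepper species and seven comparison
#' plants, as carried in the comparative census table.
#'
#' @return data.frame with `species`, `members`, `proteome`,
#'   `percent_printed`.
#' @export
ank_family_census_table <- function() {
  read.delim(.extdata("ank_family_counts.tsv"),
             stringsAsFactors = FALSE)
}
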