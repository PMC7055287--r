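#' Assign a family member to a subfamily from its domain composition
#'
#' A protein with at least one repeat ("ANK") hit and no other domain is
#' `ANK-U`. Otherwise its set of non-ANK domain labels is matched against a
#' fixed priority order (`TM > PK > ZnF > BTB > ACBP > GPCR > BPA > IQ >
#' RF > TPR`); the highest-priority recognized label wins. A protein whose
#' non-ANK domains contain none of the recognized labels falls into `ANK-O`.
#'
#' @param protein_id protein identifier.
#' @param domain_hits character vector of domain labels, or a data.frame
#'   with a `label` column (e.g. from [scan_proteome()] plus external
#'   annotations).
#' @param priority recognized non-ANK labels in decreasing priority.
#' @return list (class `subfamily_assignment`) with `protein_id`,
#'   `subfamily` and `evidence` (the non-ANK labels observed).
#' @examples
#' classify_subfamily("p1", c("ANK", "ANK", "TM"))$subfamily
#' @export
classify_subfamily <- function(protein_id, domain_hits,
                               priority = SUBFAMILY_PRIORITY) {
  labels <- if (is.data.frame(domain_hits)) domain_hits$label
            else as.character(domain_hits)
  if (!any(labels == "ANK"))
    stop("not a family member: '", protein_id, "' has no ANK hit")
  evidence <- setdiff(unique(labels), "ANK")
  subfam <- if (!length(evidence)) {
    "ANK-U"
  } else {
    hit <- priority[priority %in% evidence]
    if (length(hit)) paste0("ANK-", hit[1]) else "ANK-O"
  }
  structure(list(protein_id = protein_id, subfamily = subfam,
                 evidence = evidence),
            class = "subfamily_assignment")
}

#' Classify every protein in a domain-hit table
#'
#' @param hits data.frame with `protein_id` and `label` columns.
#' @param priority see [classify_subfamily()].
#' @return data.frame with `protein_id`, `subfamily`, `evidence`
#'   (comma-joined non-ANK labels).
#' @export
classify_family <- function(hits, priority = SUBFAMILY_PRIORITY) {
  ids <- unique(hits$protein_id)
  rows <- lapply(ids, function(id) {
    a <- classify_subfamily(id, hits[hits$protein_id == id, ], priority)
    data.frame(protein_id = id, subfamily = a$subfamily,
               evidence = paste(a$evidence, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subfamily census with percent of proteome
#'
#' Counts members per subfamily over the full closed vocabulary and reports
#' the family's share of the annotated proteome, as
#' `100 * family_size / proteome_size` rounded half-away-from-zero to two
#' decimals on exact integer arithmetic.
#'
#' @param assignments data.frame from [classify_family()], or a character
#'   vector of subfamily labels.
#' @param proteome_size number of annotated proteins in the proteome (> 0).
#' @return list (class `subfamily_census`) with `counts` (named integer over
#'   `SUBFAMILY_VOCAB`), `family_size`, `proteome_size`,
#'   `percent_of_proteome`.
#' @examples
#' subfamily_census(c("ANK-U", "ANK-U", "ANK-TM"), proteome_size = 1000)
#' @export
subfamily_census <- function(assignments, proteome_size) {
  if (length(proteome_size) != 1L || is.na(proteome_size) ||
      proteome_size <= 0)
    stop("proteome_size must be a single positive number")
  labels <- if (is.data.frame(assignments)) assignments$subfamily
            else as.character(assignments)
  bad <- setdiff(unique(labels), SUBFAMILY_VOCAB)
  if (length(bad))
    stop("unknown subfamily label(s): ", paste(bad, collapse = ", "))
  counts <- vapply(SUBFAMILY_VOCAB, function(s) sum(labels == s), integer(1))
  fam <- length(labels)
  if (proteome_size < fam)
    warning("family size exceeds proteome size")
  structure(
    list(counts = counts, family_size = fam,
         proteome_size = as.integer(proteome_size),
         percent_of_proteome = round2_ratio(fam, as.integer(proteome_size))),
    class = "subfamily_census")
}

#' @export
print.subfamily_census <- function(x, ...) {
  cat("subfamily census:", x$family_size, "members /",
      x$proteome_size, "proteins (", sprintf("%.2f", x$percent_of_proteome),
      "% )\n")
  print(x$counts[x$counts > 0])
  invisible(x)
}
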