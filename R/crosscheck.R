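## Crosscheck predicted novel miRNAs against a known-miRNA catalogue:
## a candidate is reported when its seed (mature positions 2-8) is identical
## to a known miRNA's seed and/or its mature sequence exceeds an identity
## threshold under global alignment.

#' Seed of a mature miRNA (positions 2-8, 1-based)
#'
#' @param mature Mature sequence (>= 8 nt, RNA or DNA alphabet).
#' @return 7-nt seed, U/T-normalized (DNA form).
#' @examples
#' seed_of("UGAGGUAGUAGGUUGUAUAGUU") # let-7: "GAGGTAG"
#' @export
seed_of <- function(mature) {
  mature <- normalize_nt(mature, "mature")
  short <- nchar(mature) < 8L
  if (any(short)) stopf("mature sequence shorter than 8 nt: '%s'", mature[short][1L])
  substr(mature, 2L, 8L)
}

#' Global-alignment identity of two mature sequences
#'
#' Needleman-Wunsch alignment with match 1, mismatch 0, gap -1 (scoring used
#' for alignment only); identity is matches over alignment columns.
#'
#' @param a,b Sequences (>= 18 nt each).
#' @return Identity fraction in `[0, 1]`.
#' @export
mature_identity <- function(a, b) {
  a <- normalize_nt(a, "sequence"); b <- normalize_nt(b, "sequence")
  if (nchar(a) < 18L || nchar(b) < 18L) stopf("mature sequences must be >= 18 nt")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  pal <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(pal))
  ps <- as.character(Biostrings::alignedSubject(pal))
  cmp <- count_substitutions(pa, ps)
  cmp$matches / nchar(pa)
}

#' Catalogue of mature miRNA records
#'
#' @param id Record identifiers (miRBase style, species-prefixed).
#' @param sequence Mature sequences (>= 18 nt).
#' @param species Optional species tags (derived from the id prefix before
#'   the first "-" when missing).
#' @return A `mature_records` data.frame with `id`, `species`, `sequence`
#'   (DNA form) and `seed` columns.
#' @export
mature_records <- function(id, sequence, species = NULL) {
  sequence <- normalize_nt(sequence, "mature")
  short <- nchar(sequence) < 18L
  if (any(short)) stopf("mature sequence shorter than 18 nt: %s", id[short][1L])
  if (is.null(species)) species <- sub("-.*$", "", id)
  df <- data.frame(id = as.character(id), species = as.character(species),
                   sequence = sequence, seed = seed_of(sequence),
                   stringsAsFactors = FALSE)
  class(df) <- c("mature_records", "data.frame")
  df
}

#' Crosscheck candidate miRNAs against a known catalogue
#'
#' Reports every (candidate, known) pair where the seeds are identical or
#' the mature identity exceeds `identity_min` (inclusive OR; `rule_fired`
#' records which condition held so stricter filtering remains possible
#' downstream).
#'
#' @param candidates,known `mature_records` catalogues.
#' @param identity_min Mature-identity threshold (exceeded strictly).
#' @return Data.frame of hits: `candidate_id`, `known_id`, `seed_identical`,
#'   `mature_identity`, `rule_fired` ("seed", "identity" or "both").
#' @export
crosscheck <- function(candidates, known, identity_min = 0.8) {
  if (nrow(candidates) == 0L || nrow(known) == 0L)
    stopf("candidate and known catalogues must be non-empty")
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_len(nrow(known))) {
      seed_id <- candidates$seed[i] == known$seed[j]
      ident <- mature_identity(candidates$sequence[i], known$sequence[j])
      by_ident <- ident > identity_min
      if (!seed_id && !by_ident) next
      out[[length(out) + 1L]] <- data.frame(
        candidate_id = candidates$id[i], known_id = known$id[j],
        seed_identical = seed_id, mature_identity = ident,
        rule_fired = if (seed_id && by_ident) "both" else if (seed_id) "seed" else "identity",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(list(data.frame(candidate_id = character(), known_id = character(),
                                   seed_identical = logical(), mature_identity = numeric(),
                                   rule_fired = character(), stringsAsFactors = FALSE)),
                   out))
}
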