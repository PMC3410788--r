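## Kimura two-parameter (K2P) evolutionary distances on miRNA regions.
## K = -1/2 ln((1 - 2P - Q) * sqrt(1 - 2Q)), with P and Q the transition and
## transversion proportions over compared columns. Gap and ambiguous columns
## are excluded from numerator and denominator (pairwise complete deletion).

TRANSITIONS <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

#' Count substitution classes between two aligned rows
#'
#' Per column: both bases ACGT gives a match, transition (A<->G, C<->T) or
#' transversion; any gap gives a gap column; any other character (N etc.)
#' an ambiguous column.
#'
#' @param rowA,rowB Gapped sequences of equal length.
#' @return A `substitution_counts` list: `matches`, `transitions`,
#'   `transversions`, `gap_columns`, `ambiguous_columns`, `compared_columns`.
#' @export
count_substitutions <- function(rowA, rowB) {
  a <- strsplit(toupper(rowA), "")[[1L]]
  b <- strsplit(toupper(rowB), "")[[1L]]
  if (length(a) != length(b))
    stopf("aligned rows differ in length (%d vs %d)", length(a), length(b))
  gap <- a == "-" | b == "-"
  acgt <- c("A", "C", "G", "T")
  amb <- !gap & (!(a %in% acgt) | !(b %in% acgt))
  cmp <- !gap & !amb
  eq <- cmp & a == b
  ts <- cmp & !eq & !is.na(TRANSITIONS[paste0(a, b)])
  tv <- cmp & !eq & !ts
  structure(list(matches = sum(eq), transitions = sum(ts),
                 transversions = sum(tv), gap_columns = sum(gap),
                 ambiguous_columns = sum(amb), compared_columns = sum(cmp)),
            class = "substitution_counts")
}

#' Kimura two-parameter distance from transition/transversion proportions
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return list(kmir = numeric distance (NA when saturated), saturated =
#'   logical). Saturation occurs when `1 - 2P - Q <= 0` or `1 - 2Q <= 0`,
#'   where the log transform leaves its domain.
#' @examples
#' k2p(0.25, 0) # -0.5 * log(0.5)
#' @export
k2p <- function(P, Q) {
  if (P < 0 || Q < 0) stopf("P and Q must be non-negative")
  if (P + Q > 1) stopf("P + Q must not exceed 1")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(list(kmir = NA_real_, saturated = TRUE))
  list(kmir = -0.5 * log(w1 * sqrt(w2)), saturated = FALSE)
}

## One DistanceEstimate row from counts.
distance_row <- function(precursor_id, species_a, species_b, region, sc) {
  cc <- sc$compared_columns
  if (cc == 0L) {
    return(data.frame(precursor_id = precursor_id, species_a = species_a,
                      species_b = species_b, region = region,
                      P = NA_real_, Q = NA_real_, kmir = NA_real_,
                      identity = NA_real_, coverage = 0L, saturated = NA,
                      stringsAsFactors = FALSE))
  }
  P <- sc$transitions / cc
  Q <- sc$transversions / cc
  k <- k2p(P, Q)
  data.frame(precursor_id = precursor_id, species_a = species_a,
             species_b = species_b, region = region, P = P, Q = Q,
             kmir = k$kmir, identity = sc$matches / cc, coverage = cc,
             saturated = k$saturated, stringsAsFactors = FALSE)
}

## Map an ungapped reference interval [s, e) (0-based) to the enclosing
## alignment column range, interior reference-gap columns included.
ref_interval_columns <- function(ref_row, s, e) {
  chars <- strsplit(ref_row, "")[[1L]]
  nongap <- chars != "-"
  pos0 <- cumsum(nongap) - 1L
  sel <- which(nongap & pos0 >= s & pos0 < e)
  if (length(sel) == 0L) return(NULL)
  c(sel[1L], max(sel))
}

#' Region-wise pairwise distances over a homolog set
#'
#' Computes identity and K2P distance for the whole precursor, each mature
#' arm and each seed (mature positions 2-8, 1-based) region, mapping each
#' region's ungapped reference interval through the gapped reference row.
#'
#' @param hs A `homolog_set` with the reference species present.
#' @param arms Optional `precursor_annotation` row for this precursor (arm
#'   intervals on the ungapped reference precursor); without it only the
#'   precursor region is computed.
#' @param all_pairs Compute all species pairs instead of reference-vs-other.
#' @param seed_span 1-based inclusive positions of the seed on the mature
#'   sequence.
#' @return A data.frame of `DistanceEstimate` rows: `precursor_id`,
#'   `species_a`, `species_b`, `region`, `P`, `Q`, `kmir`, `identity`,
#'   `coverage`, `saturated`.
#' @export
region_distances <- function(hs, arms = NULL, all_pairs = FALSE,
                             seed_span = c(2L, 8L)) {
  stopifnot(inherits(hs, "homolog_set"))
  ref <- hs$ref_species
  if (is.na(ref) || !(ref %in% names(hs$alignment)))
    stopf("homolog set has no reference row")
  ref_row <- hs$alignment[[ref]]
  n <- nchar(gsub("-", "", ref_row, fixed = TRUE))

  regions <- list(precursor = c(0L, n))
  if (!is.null(arms)) {
    a <- as.data.frame(arms)
    if ("precursor_id" %in% names(a) && nrow(a) > 1L)
      a <- a[a$precursor_id == hs$precursor_id, , drop = FALSE]
    if (nrow(a) == 1L) {
      add_arm <- function(s, e, label) {
        if (is.na(s)) return()
        if (s < 0L || e > n) stopf("%s region outside precursor", label)
        regions[[paste0("mature_", label)]] <<- c(s, e)
        ss <- s + seed_span[1L] - 1L; se <- s + seed_span[2L]
        if (se <= e) regions[[paste0("seed_", label)]] <<- c(ss, se)
      }
      add_arm(a$arm5_start, a$arm5_end, "5p")
      add_arm(a$arm3_start, a$arm3_end, "3p")
    }
  }

  present <- hs$species[hs$status[hs$species] != "absent"]
  pairs <- if (all_pairs) {
    if (length(present) < 2L) matrix(character(0), 2L) else utils::combn(present, 2L)
  } else {
    others <- setdiff(present, ref)
    rbind(rep(ref, length(others)), others)
  }

  out <- list()
  for (rg in names(regions)) {
    cols <- ref_interval_columns(ref_row, regions[[rg]][1L], regions[[rg]][2L])
    if (is.null(cols)) next
    for (pi in seq_len(ncol(pairs))) {
      sa <- pairs[1L, pi]; sb <- pairs[2L, pi]
      sc <- count_substitutions(substr(hs$alignment[[sa]], cols[1L], cols[2L]),
                                substr(hs$alignment[[sb]], cols[1L], cols[2L]))
      out[[length(out) + 1L]] <- distance_row(hs$precursor_id, sa, sb, rg, sc)
    }
  }
  do.call(rbind, c(list(distance_row("x", "a", "b", "r",
                                     count_substitutions("A", "A"))[0, ]), out))
}

#' Ratio of miRNA divergence to synonymous divergence
#'
#' A ratio below 1 against the genome-wide synonymous divergence (Ks, the
#' neutral yardstick) suggests functional constraint on the miRNA.
#'
#' @param kmir K2P distance of the miRNA region.
#' @param ks Synonymous-site divergence (user-supplied, > 0).
#' @return kmir / ks.
#' @export
kmir_ks_ratio <- function(kmir, ks) {
  if (any(ks <= 0)) stopf("ks must be positive")
  kmir / ks
}
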