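#' Evolutionary filter parameters
#'
#' Cutoffs of the evolutionary filter. A position passes for a subfamily
#' pair when at least one of three conditions holds: (1) both columns are
#' conserved (base-21 Shannon entropy strictly below `entropy_cutoff`) and
#' differ in identity; (2) the biophysical-property percent difference
#' strictly exceeds `property_cutoff`; (3) the size-class percent difference
#' strictly exceeds `size_cutoff`.
#'
#' @param entropy_cutoff Conservation threshold on the base-21 entropy;
#'   default 0.23 (a 50/50 two-residue column scores log21(2) = 0.2277,
#'   just inside it).
#' @param property_cutoff Percent cutoff for the property condition
#'   (default 90; strict `>`).
#' @param size_cutoff Percent cutoff for the size condition (default 90).
#' @param renormalize If `TRUE`, frequencies are renormalized over the 20
#'   amino acids (excluding the gap) before the percent-difference sums. The
#'   default `FALSE` leaves gap mass in place, so gap-rich columns cannot
#'   reach the percent cutoffs (fail-safe for constraint calling).
#' @return A list of class `EvoFilterParams`.
#' @export
evo_filter_params <- function(entropy_cutoff = 0.23,
                              property_cutoff = 90,
                              size_cutoff = 90,
                              renormalize = FALSE) {
  stopifnot(is.numeric(entropy_cutoff), length(entropy_cutoff) == 1L,
            entropy_cutoff > 0, entropy_cutoff <= 1,
            is.numeric(property_cutoff), property_cutoff > 0,
            property_cutoff <= 100,
            is.numeric(size_cutoff), size_cutoff > 0, size_cutoff <= 100,
            is.logical(renormalize))
  structure(list(entropy_cutoff = entropy_cutoff,
                 property_cutoff = property_cutoff,
                 size_cutoff = size_cutoff,
                 renormalize = renormalize),
            class = "EvoFilterParams")
}

#' Base-21 Shannon entropy of a column profile
#'
#' \eqn{S = -\sum_i f_i \log_{21} f_i} over the 21-symbol alphabet (20 amino
#' acids plus gap), with \eqn{0 \log 0 \equiv 0}. The base 21 normalizes the
#' score to \[0, 1\]: 0 for a fully conserved column, 1 for a column uniform
#' over all 21 symbols.
#'
#' @param profile A `FrequencyProfile` (see [column_frequency_profile()]).
#' @return Entropy in \[0, 1\].
#' @export
#' @examples
#' shannon_entropy(frequency_profile(c(A = 1)))           # 0
#' shannon_entropy(frequency_profile(c(A = 0.5, V = 0.5)))  # log21(2) = 0.2277
shannon_entropy <- function(profile) {
  f <- as_profile_vector(profile)
  nz <- f[f > 0]
  -sum(nz * log(nz, base = 21))
}

as_profile_vector <- function(profile) {
  if (inherits(profile, "FrequencyProfile")) return(unclass(profile))
  if (is.numeric(profile) && !is.null(names(profile))) {
    return(unclass(frequency_profile(profile)))
  }
  stop("expected a FrequencyProfile or a named frequency vector")
}

#' Modal residues of a column profile
#'
#' The set of amino acids attaining the maximum frequency in the column,
#' gap excluded. Used by the identity condition: two conserved columns are
#' "different in identity" when their modal-residue sets are disjoint.
#'
#' @param profile A `FrequencyProfile`.
#' @return Character vector of modal residues (empty for an all-gap column).
#' @export
modal_residues <- function(profile) {
  f <- as_profile_vector(profile)[aa_residues]
  top <- max(f)
  if (top <= 0) return(character(0))
  names(f)[f >= top - 1e-12]
}

#' Identity condition of the evolutionary filter
#'
#' True when both columns are conserved (entropy strictly below the cutoff)
#' and differ in identity, i.e. their modal-residue sets are disjoint.
#'
#' @param profile_i,profile_j `FrequencyProfile`s of the two subfamilies at
#'   the same family position.
#' @param params An [evo_filter_params()] object.
#' @return Logical.
#' @export
identity_condition <- function(profile_i, profile_j,
                               params = evo_filter_params()) {
  s_i <- shannon_entropy(profile_i)
  s_j <- shannon_entropy(profile_j)
  if (s_i >= params$entropy_cutoff || s_j >= params$entropy_cutoff) {
    return(FALSE)
  }
  length(intersect(modal_residues(profile_i), modal_residues(profile_j))) == 0L
}

percent_sum <- function(profile_i, profile_j, mask_fn, renormalize) {
  fi <- as_profile_vector(profile_i)[aa_residues]
  fj <- as_profile_vector(profile_j)[aa_residues]
  if (renormalize) {
    if (sum(fi) > 0) fi <- fi / sum(fi)
    if (sum(fj) > 0) fj <- fj / sum(fj)
  }
  w <- outer(fi, fj)       # 20 x 20 occurrence weights f_aa_i * f_aa_j
  sum(w * mask_fn()) * 100
}

#' Biophysical-property percent difference between two columns
#'
#' For every amino-acid pair (one residue observed in subfamily i, one in
#' subfamily j) whose property classes differ, the pair contributes its
#' occurrence weight \eqn{f_{aa_i} \times f_{aa_j} \times 100\%}; same-class
#' pairs contribute nothing. The sum over contributing pairs is the total
#' property difference in percent. Gap frequency contributes to no pair
#' (and, by default, is not renormalized away; see [evo_filter_params()]).
#'
#' @param profile_i,profile_j `FrequencyProfile`s at the same position.
#' @param scheme A property scheme ([property_scheme()]).
#' @param renormalize See [evo_filter_params()].
#' @return Percent in \[0, 100\].
#' @export
#' @examples
#' property_difference(frequency_profile(c(K = 1)),
#'                     frequency_profile(c(E = 1)))  # 100: positive vs negative
property_difference <- function(profile_i, profile_j,
                                scheme = property_scheme(),
                                renormalize = FALSE) {
  prop <- aa_property_map(scheme)
  percent_sum(profile_i, profile_j,
              function() outer(prop, prop, "!="),
              renormalize)
}

#' Size-class percent difference between two columns
#'
#' Two directional sums are computed with the same occurrence weighting as
#' [property_difference()]: one over pairs where the subfamily-i residue
#' falls in a strictly larger size class than the subfamily-j residue, and
#' one where it falls in a strictly smaller class
#' (tiny < small < medium < large < bulky). The reported size difference is
#' the maximum of the two, so a position only scores high when one subgroup
#' is consistently larger (or consistently smaller) than the other;
#' mixed-direction differences split between the sums and cannot reach the
#' cutoff. Same-class pairs and gaps contribute to neither sum.
#'
#' @inheritParams property_difference
#' @param scheme A size scheme ([size_scheme()]).
#' @return Percent in \[0, 100\].
#' @export
#' @examples
#' size_difference(frequency_profile(c(G = 1)),
#'                 frequency_profile(c(W = 1)))  # 100: tiny vs bulky
#' size_difference(frequency_profile(c(G = 0.5, W = 0.5)),
#'                 frequency_profile(c(E = 1)))  # 50: directions split
size_difference <- function(profile_i, profile_j,
                            scheme = size_scheme(),
                            renormalize = FALSE) {
  rank <- aa_size_rank(scheme)
  larger <- percent_sum(profile_i, profile_j,
                        function() outer(rank, rank, ">"), renormalize)
  smaller <- percent_sum(profile_i, profile_j,
                         function() outer(rank, rank, "<"), renormalize)
  max(larger, smaller)
}

#' Evaluate the evolutionary filter at one family position
#'
#' Compares the columns of two subfamily alignments (both already restricted
#' to family-wide interfacial columns in the same order, so family position
#' *p* is column *p*) and returns an `EvoVerdict` row: both entropies, the
#' identity condition, both percent differences, and the acceptance flag
#' (the OR of the three conditions). A pure function of the two column
#' profiles.
#'
#' @param msa_i,msa_j `AlignedSubfamily` objects of the two compared
#'   subfamilies (same side, equal widths).
#' @param family_position 1-based family position / column index.
#' @param params An [evo_filter_params()] object.
#' @return A one-row data frame with columns `family_position`,
#'   `subgroup_i`, `subgroup_j`, `entropy_i`, `entropy_j`,
#'   `identity_condition`, `property_percent`, `size_percent`, `accepted`.
#' @export
evaluate_evo_filter <- function(msa_i, msa_j, family_position,
                                params = evo_filter_params()) {
  stopifnot(inherits(msa_i, "AlignedSubfamily"),
            inherits(msa_j, "AlignedSubfamily"))
  if (ncol_msa(msa_i) != ncol_msa(msa_j)) {
    stop(sprintf("alignment widths differ: %d vs %d",
                 ncol_msa(msa_i), ncol_msa(msa_j)))
  }
  p_i <- column_frequency_profile(msa_i, family_position)
  p_j <- column_frequency_profile(msa_j, family_position)
  evo_verdict_from_profiles(p_i, p_j, family_position,
                            msa_i$subgroup_id, msa_j$subgroup_id, params)
}

evo_verdict_from_profiles <- function(p_i, p_j, family_position,
                                      subgroup_i, subgroup_j, params) {
  ident <- identity_condition(p_i, p_j, params)
  prop <- property_difference(p_i, p_j, renormalize = params$renormalize)
  size <- size_difference(p_i, p_j, renormalize = params$renormalize)
  data.frame(
    family_position = as.integer(family_position),
    subgroup_i = subgroup_i,
    subgroup_j = subgroup_j,
    entropy_i = shannon_entropy(p_i),
    entropy_j = shannon_entropy(p_j),
    identity_condition = ident,
    property_percent = prop,
    size_percent = size,
    accepted = ident || prop > params$property_cutoff ||
      size > params$size_cutoff,
    stringsAsFactors = FALSE)
}

#' Evolutionary filter verdicts for many positions
#'
#' Applies [evaluate_evo_filter()] to a set of family positions and binds
#' the verdict rows into one table.
#'
#' @inheritParams evaluate_evo_filter
#' @param positions Integer vector of family positions; defaults to all
#'   columns.
#' @return A data frame with one `EvoVerdict` row per position.
#' @export
evo_filter_table <- function(msa_i, msa_j, positions = NULL,
                             params = evo_filter_params()) {
  if (is.null(positions)) positions <- seq_len(ncol_msa(msa_i))
  do.call(rbind, lapply(positions, function(p) {
    evaluate_evo_filter(msa_i, msa_j, p, params)
  }))
}
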