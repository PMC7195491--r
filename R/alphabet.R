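#' The 21-symbol alignment alphabet
#'
#' Ordered alphabet used throughout the package: the 20 standard amino-acid
#' one-letter codes plus the gap character `"-"`. Column frequency profiles
#' ([column_frequency_profile()]) are indexed by this alphabet, and the
#' Shannon entropy of a column is taken in base 21 so that a uniform column
#' scores exactly 1 (see [shannon_entropy()]).
#'
#' @format `aa_alphabet` is a character vector of length 21; `aa_gap` is the
#'   gap character; `aa_residues` are the 20 amino acids (no gap).
#' @export
aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

#' @rdname aa_alphabet
#' @export
aa_gap <- "-"

#' @rdname aa_alphabet
#' @export
aa_residues <- aa_alphabet[aa_alphabet != "-"]

#' Biophysical property classes of the 20 amino acids
#'
#' Four classes partitioning the amino acids by biophysical property:
#' hydrophobic (I, V, L, M, F, W, A, C, G, P), polar (S, T, Q, N, H, Y),
#' positively charged (K, R), and negatively charged (E, D). The gap symbol
#' belongs to no class. Used by [property_difference()] to score whether two
#' subfamilies present residues of different character at a position.
#'
#' @return A named list of character vectors, one per class. The four sets
#'   partition `aa_residues`.
#' @seealso [size_scheme()] for the five volume classes.
#' @export
#' @examples
#' property_scheme()
property_scheme <- function() {
  scheme <- list(
    hydrophobic = c("I", "V", "L", "M", "F", "W", "A", "C", "G", "P"),
    polar       = c("S", "T", "Q", "N", "H", "Y"),
    positive    = c("K", "R"),
    negative    = c("E", "D")
  )
  validate_partition(scheme, "property")
  scheme
}

#' Size classes of the 20 amino acids
#'
#' Five classes ordered by amino-acid volume:
#' tiny (G, A, S) < small (C, D, P, N, T) < medium (E, V, Q, H) <
#' large (M, I, L, K, R) < bulky (F, Y, W). The list order encodes the strict
#' total order on classes used by [size_difference()].
#'
#' @return A named list of character vectors in increasing size order; the
#'   five sets partition `aa_residues`.
#' @export
#' @examples
#' names(size_scheme())  # tiny .. bulky
size_scheme <- function() {
  scheme <- list(
    tiny   = c("G", "A", "S"),
    small  = c("C", "D", "P", "N", "T"),
    medium = c("E", "V", "Q", "H"),
    large  = c("M", "I", "L", "K", "R"),
    bulky  = c("F", "Y", "W")
  )
  validate_partition(scheme, "size")
  scheme
}

validate_partition <- function(scheme, what) {
  members <- unlist(scheme, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop(sprintf("%s scheme assigns a residue to more than one class", what))
  }
  if (!setequal(members, aa_residues)) {
    stop(sprintf("%s scheme must partition the 20 amino acids", what))
  }
  invisible(scheme)
}

#' Map residues to their property class or size rank
#'
#' `aa_property_map()` returns a named character vector mapping each amino
#' acid to its property-class label; `aa_size_rank()` returns a named integer
#' vector mapping each amino acid to its size rank (tiny = 1 .. bulky = 5).
#'
#' @param scheme A scheme list as returned by [property_scheme()] or
#'   [size_scheme()].
#' @return A named vector over the 20 amino acids.
#' @export
#' @examples
#' aa_property_map()[["K"]]  # "positive"
#' aa_size_rank()[["W"]]     # 5
aa_property_map <- function(scheme = property_scheme()) {
  validate_partition(scheme, "property")
  map <- rep(names(scheme), lengths(scheme))
  names(map) <- unlist(scheme, use.names = FALSE)
  map[aa_residues]
}

#' @rdname aa_property_map
#' @export
aa_size_rank <- function(scheme = size_scheme()) {
  validate_partition(scheme, "size")
  rank <- rep(seq_along(scheme), lengths(scheme))
  names(rank) <- unlist(scheme, use.names = FALSE)
  rank[aa_residues]
}
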