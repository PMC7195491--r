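#' Construct an aligned subfamily
#'
#' An `AlignedSubfamily` is a gap-aware amino-acid multiple sequence
#' alignment tagged with the family side it belongs to (`"DIP"` or `"Dpr"`)
#' and a subgroup (specificity-subfamily) label. It is the unit the
#' evolutionary filter compares: for a non-cognate pair the filter contrasts
#' the column composition of two subfamilies on the same side.
#'
#' @param rows Character vector of aligned sequences, all the same length,
#'   over the 21-symbol alphabet ([aa_alphabet]); lowercase is accepted and
#'   uppercased.
#' @param sequence_ids Unique sequence labels, one per row.
#' @param family_side `"DIP"` or `"Dpr"`.
#' @param subgroup_id Subgroup label.
#' @param reference_id Optional id of the reference sequence used for
#'   interfacial-column mapping; must be one of `sequence_ids`.
#' @return An object of class `AlignedSubfamily`.
#' @seealso [read_aligned_fasta()], [extract_interfacial_columns()],
#'   [column_frequency_profile()]
#' @export
#' @examples
#' msa <- aligned_subfamily(c(s1 = "LKQA", s2 = "LKQS"),
#'                          family_side = "Dpr", subgroup_id = "blue")
#' ncol_msa(msa)
aligned_subfamily <- function(rows, sequence_ids = names(rows),
                              family_side = c("DIP", "Dpr"),
                              subgroup_id = "subgroup",
                              reference_id = NULL) {
  family_side <- match.arg(family_side)
  rows <- toupper(as.character(rows))
  if (length(rows) == 0L) stop("alignment has no sequences")
  if (is.null(sequence_ids)) {
    sequence_ids <- paste0("seq", seq_along(rows))
  }
  sequence_ids <- as.character(sequence_ids)
  if (length(sequence_ids) != length(rows)) {
    stop("sequence_ids and rows must have the same length")
  }
  if (anyDuplicated(sequence_ids)) {
    stop("duplicate sequence id: ",
         paste(unique(sequence_ids[duplicated(sequence_ids)]), collapse = ", "))
  }
  widths <- nchar(rows)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf(
      "ragged alignment: record %d ('%s') has length %d, expected %d",
      bad, sequence_ids[bad], widths[bad], widths[1L]))
  }
  if (widths[1L] < 1L) stop("alignment has zero columns")
  check_alphabet(rows, sequence_ids)
  if (!is.null(reference_id) && !reference_id %in% sequence_ids) {
    stop("reference_id '", reference_id, "' is not among the sequence ids")
  }
  structure(
    list(family_side = family_side,
         subgroup_id = as.character(subgroup_id),
         sequence_ids = sequence_ids,
         rows = unname(rows),
         reference_id = reference_id),
    class = "AlignedSubfamily")
}

check_alphabet <- function(rows, ids) {
  for (i in seq_along(rows)) {
    chars <- strsplit(rows[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% aa_alphabet)
    if (length(bad)) {
      stop(sprintf(
        "invalid symbol '%s' in record %d ('%s') at alignment column %d",
        chars[bad[1L]], i, ids[i], bad[1L]))
    }
  }
  invisible(TRUE)
}

#' @export
print.AlignedSubfamily <- function(x, ...) {
  cat(sprintf("AlignedSubfamily: side %s, subgroup '%s'\n",
              x$family_side, x$subgroup_id))
  cat(sprintf("  %d sequences x %d columns\n",
              length(x$rows), nchar(x$rows[1L])))
  if (!is.null(x$reference_id)) cat("  reference:", x$reference_id, "\n")
  invisible(x)
}

#' @export
as.matrix.AlignedSubfamily <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, "", fixed = TRUE))
  rownames(m) <- x$sequence_ids
  m
}

#' Alignment dimensions
#'
#' @param msa An `AlignedSubfamily`.
#' @return Number of alignment columns (`ncol_msa`) or rows (`nrow_msa`).
#' @export
ncol_msa <- function(msa) nchar(msa$rows[1L])

#' @rdname ncol_msa
#' @export
nrow_msa <- function(msa) length(msa$rows)

#' Read an aligned FASTA file as a subfamily alignment
#'
#' Reads a standard aligned FASTA file (gaps as `-`) into an
#' [aligned_subfamily()]. Sequence order is preserved, letters are
#' uppercased, and the file is rejected with an informative error if it is
#' empty, ragged (records of unequal length), contains a symbol outside the
#' 21-letter alphabet, or repeats a sequence id.
#'
#' @param path Path to an aligned FASTA file.
#' @param family_side `"DIP"` or `"Dpr"`.
#' @param subgroup_id Subgroup label to tag the alignment with.
#' @param reference_id Optional reference sequence id (see
#'   [extract_interfacial_columns()]).
#' @return An `AlignedSubfamily`.
#' @export
read_aligned_fasta <- function(path, family_side = c("DIP", "Dpr"),
                               subgroup_id = "subgroup",
                               reference_id = NULL) {
  family_side <- match.arg(family_side)
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  aligned_subfamily(as.character(seqs), sequence_ids = ids,
                    family_side = family_side, subgroup_id = subgroup_id,
                    reference_id = reference_id)
}

#' Write a subfamily alignment to aligned FASTA
#'
#' @param msa An `AlignedSubfamily`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "AlignedSubfamily"))
  set <- Biostrings::BStringSet(msa$rows)
  names(set) <- msa$sequence_ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Assign interfacial positions from per-residue buried-surface changes
#'
#' An interfacial residue is one whose accessible surface area changes upon
#' complex formation. Given a table of per-residue ASA changes, returns, per
#' protein, exactly the residue numbers with `delta_asa > 0` (a strictly
#' positive change encodes "non-zero"; negative values are rejected at
#' parse time).
#'
#' @param asa A data frame with columns `protein_id`, `residue_number`,
#'   `delta_asa` (in square Angstroms), e.g. from [read_asa_table()].
#' @return A named list, one sorted integer vector of residue numbers per
#'   protein id.
#' @export
#' @examples
#' asa <- data.frame(protein_id = "p", residue_number = 5:6,
#'                   delta_asa = c(12.3, 0))
#' assign_interfacial_positions(asa)  # list(p = 5)
assign_interfacial_positions <- function(asa) {
  asa <- validate_asa(asa)
  out <- lapply(split(asa, asa$protein_id), function(d) {
    sort(as.integer(d$residue_number[d$delta_asa > 0]))
  })
  out[order(names(out))]
}

validate_asa <- function(asa) {
  need <- c("protein_id", "residue_number", "delta_asa")
  if (!is.data.frame(asa) || !all(need %in% names(asa))) {
    stop("ASA table must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(asa$delta_asa)) || any(asa$delta_asa < 0)) {
    stop("delta_asa must be non-negative and finite")
  }
  key <- paste(asa$protein_id, asa$residue_number)
  if (anyDuplicated(key)) {
    stop("duplicate (protein_id, residue_number): ",
         key[duplicated(key)][1L])
  }
  asa
}

#' Read per-residue ASA-change and position-map tables
#'
#' Tab-separated with headers. The ASA table has columns `protein_id`,
#' `residue_number`, `delta_asa`. The position map has columns
#' `family_position` (1-based family-wide interfacial numbering, e.g. 1-33),
#' `protein_id`, `residue_number` (protein-specific, UniProt-style), and
#' `alignment_column` (1-based column in that protein's subfamily
#' alignment).
#'
#' @param path File path.
#' @return A validated data frame.
#' @export
read_asa_table <- function(path) {
  validate_asa(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_asa_table
#' @export
read_position_map <- function(path) {
  validate_position_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a position map
#' @param map Position-map data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_position_map <- function(map, path) {
  map <- validate_position_map(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_position_map <- function(map) {
  need <- c("family_position", "protein_id", "residue_number",
            "alignment_column")
  if (!is.data.frame(map) || !all(need %in% names(map))) {
    stop("position map must have columns ", paste(need, collapse = ", "))
  }
  map$family_position <- as.integer(map$family_position)
  map$alignment_column <- as.integer(map$alignment_column)
  map$residue_number <- as.integer(map$residue_number)
  if (any(map$family_position < 1L) || any(map$alignment_column < 1L)) {
    stop("family_position and alignment_column are 1-based and must be >= 1")
  }
  key <- paste(map$protein_id, map$family_position)
  if (anyDuplicated(key)) {
    stop("duplicate (protein_id, family_position): ", key[duplicated(key)][1L])
  }
  for (d in split(map, map$protein_id)) {
    if (anyDuplicated(d$alignment_column)) {
      stop("alignment_column not unique for protein ", d$protein_id[1L])
    }
    pos <- sort(d$family_position)
    if (!identical(pos, seq.int(min(pos), max(pos)))) {
      stop("family positions for protein ", d$protein_id[1L],
           " do not cover a contiguous range")
    }
  }
  map
}

#' Restrict an alignment to its interfacial columns
#'
#' Uses the position-map rows of the alignment's reference sequence to pull
#' out the alignment columns corresponding to family-wide interfacial
#' positions, in ascending family-position order. After extraction, family
#' position *p* is simply column *p* of the result.
#'
#' @param msa An `AlignedSubfamily` with a `reference_id`.
#' @param map A position map (see [read_position_map()]) containing entries
#'   for the reference sequence.
#' @return An `AlignedSubfamily` with one column per mapped family position;
#'   row count unchanged.
#' @export
extract_interfacial_columns <- function(msa, map) {
  stopifnot(inherits(msa, "AlignedSubfamily"))
  map <- validate_position_map(map)
  if (is.null(msa$reference_id)) {
    stop("alignment has no reference_id; cannot map interfacial columns")
  }
  ref <- map[map$protein_id == msa$reference_id, , drop = FALSE]
  if (nrow(ref) == 0L) {
    stop("reference sequence '", msa$reference_id,
         "' absent from position map")
  }
  ref <- ref[order(ref$family_position), , drop = FALSE]
  if (any(ref$alignment_column > ncol_msa(msa))) {
    stop("position map references alignment column beyond width ",
         ncol_msa(msa))
  }
  m <- as.matrix(msa)[, ref$alignment_column, drop = FALSE]
  aligned_subfamily(apply(m, 1L, paste, collapse = ""),
                    sequence_ids = msa$sequence_ids,
                    family_side = msa$family_side,
                    subgroup_id = msa$subgroup_id,
                    reference_id = msa$reference_id)
}

#' Column frequency profile over the 21-symbol alphabet
#'
#' Exact per-column symbol frequencies: the count of each alphabet symbol in
#' the column divided by the number of sequences. The gap is counted as its
#' own symbol. These are the occurrence fractions used by both the entropy
#' formula and the percent-difference formulas of the evolutionary filter.
#'
#' @param msa An `AlignedSubfamily`.
#' @param column 1-based alignment column index.
#' @return A `FrequencyProfile`: named numeric vector of length 21 summing
#'   to 1, with attributes `column` and `n_sequences`.
#' @export
#' @examples
#' msa <- aligned_subfamily(c(a = "K", b = "K", c = "R", d = "-"),
#'                          family_side = "Dpr")
#' column_frequency_profile(msa, 1)
column_frequency_profile <- function(msa, column) {
  stopifnot(inherits(msa, "AlignedSubfamily"))
  column <- as.integer(column)
  if (length(column) != 1L || is.na(column) ||
      column < 1L || column > ncol_msa(msa)) {
    stop("column out of range: ", column, " (alignment has ",
         ncol_msa(msa), " columns)")
  }
  chars <- substring(msa$rows, column, column)
  counts <- vapply(aa_alphabet, function(s) sum(chars == s), integer(1))
  frequency_profile(counts / length(chars), n_sequences = length(chars),
                    column = column)
}

#' Build a frequency profile directly
#'
#' Constructs a `FrequencyProfile` from named frequencies (unnamed symbols
#' get frequency zero). Mainly useful for tests and closed-form examples.
#'
#' @param freqs Named numeric vector; names must be alphabet symbols; values
#'   non-negative and summing to 1 within `1e-9`.
#' @param n_sequences Number of sequences the frequencies derive from.
#' @param column Optional column index annotation.
#' @return A `FrequencyProfile`.
#' @export
#' @examples
#' frequency_profile(c(K = 0.5, R = 0.5))
frequency_profile <- function(freqs, n_sequences = 1L, column = NA_integer_) {
  if (is.null(names(freqs)) || !all(names(freqs) %in% aa_alphabet)) {
    stop("freqs must be named by alphabet symbols")
  }
  full <- stats::setNames(numeric(length(aa_alphabet)), aa_alphabet)
  full[names(freqs)] <- as.numeric(freqs)
  if (any(full < 0)) stop("frequencies must be non-negative")
  if (abs(sum(full) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (got ", format(sum(full)), ")")
  }
  structure(full, column = as.integer(column),
            n_sequences = as.integer(n_sequences),
            class = "FrequencyProfile")
}

#' @export
print.FrequencyProfile <- function(x, ...) {
  nz <- x[x > 0]
  cat(sprintf("FrequencyProfile (column %s, n = %d): %s\n",
              attr(x, "column"), attr(x, "n_sequences"),
              paste(sprintf("%s=%.4g", names(nz), nz), collapse = " ")))
  invisible(x)
}

#' Mean pairwise sequence identity of an alignment
#'
#' Average over all unordered sequence pairs of the percent identity
#' (matching columns / compared columns x 100). Columns where both
#' sequences carry a gap are excluded from both numerator and denominator;
#' a gap aligned to a residue counts as a mismatch. Used to summarize
#' within-subfamily ortholog conservation.
#'
#' @param msa An `AlignedSubfamily` with at least two rows.
#' @return Percent identity in \[0, 100\].
#' @export
#' @examples
#' msa <- aligned_subfamily(c(a = "AAAA", b = "AA--", c = "AAAA"),
#'                          family_side = "Dpr")
#' mean_pairwise_identity(msa)  # 66.67
mean_pairwise_identity <- function(msa) {
  stopifnot(inherits(msa, "AlignedSubfamily"))
  n <- nrow_msa(msa)
  if (n < 2L) stop("mean pairwise identity needs at least 2 sequences")
  m <- as.matrix(msa)
  pairs <- utils::combn(n, 2L)
  ident <- apply(pairs, 2L, function(p) {
    a <- m[p[1L], ]
    b <- m[p[2L], ]
    comparable <- !(a == aa_gap & b == aa_gap)
    if (!any(comparable)) {
      stop(sprintf("sequences '%s' and '%s' share no comparable columns",
                   msa$sequence_ids[p[1L]], msa$sequence_ids[p[2L]]))
    }
    sum(a[comparable] == b[comparable]) / sum(comparable)
  })
  mean(ident) * 100
}
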