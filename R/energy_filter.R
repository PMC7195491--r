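#' Energy filter parameters
#'
#' The energy filter certifies a position as a candidate negative constraint
#' for a non-cognate subgroup pair only if every mutation of a template
#' residue into a non-cognate-subgroup residue is destabilizing,
#' ddG >= `ddg_threshold` (inclusive), on every template complex. The
#' default threshold of 0.05 kcal/mol equals the spread observed when
#' mutating an interfacial residue into itself (self-mutation ddG =
#' 0.00 +/- 0.05 kcal/mol), i.e. the noise floor of the mutational scan.
#'
#' @param ddg_threshold Destabilization threshold in kcal/mol (>= 0).
#' @return A list of class `EnergyFilterParams`.
#' @export
energy_filter_params <- function(ddg_threshold = 0.05) {
  stopifnot(is.numeric(ddg_threshold), length(ddg_threshold) == 1L,
            is.finite(ddg_threshold), ddg_threshold >= 0)
  structure(list(ddg_threshold = ddg_threshold),
            class = "EnergyFilterParams")
}

ddg_columns <- c("template_id", "template_subgroup", "side",
                 "family_position", "wt_residue", "mut_residue",
                 "source_subgroup", "source_member", "ddg")

#' Read a tab-separated binding-ddG table
#'
#' One row per (template complex, family position, mutant residue, source
#' member): the replicate-mean change in binding free energy when the
#' template's wild-type residue at that position is mutated into the residue
#' the source member carries there. The required header columns are
#' `template_id`, `template_subgroup`, `side` (DIP or Dpr),
#' `family_position`, `wt_residue`, `mut_residue`, `source_subgroup`,
#' `source_member`, `ddg` (kcal/mol), plus an optional `run_values` column
#' of semicolon-separated per-run values whose arithmetic mean must equal
#' `ddg`. Tables in this layout are produced externally, e.g. by
#' post-processing a FoldX BuildModel/AnalyseComplex scan (see
#' [foldx_table_notes()]); running the scan engine is outside this package.
#'
#' Self-mutation rows (`wt_residue == mut_residue`) are rejected: a member
#' sharing the template's wild-type residue generates no mutation and no
#' filter requirement. Unknown residue codes and exact duplicate keys
#' (`template_id`, `side`, `family_position`, `mut_residue`,
#' `source_member`) are also hard errors.
#'
#' @param path File path.
#' @return A data frame of validated records, row order preserved;
#'   `run_values` (if present) parsed into a list column.
#' @export
read_ddg_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ddg_records(d)
}

validate_ddg_records <- function(d) {
  missing <- setdiff(ddg_columns, names(d))
  if (length(missing)) {
    stop("ddG table lacks columns: ", paste(missing, collapse = ", "))
  }
  d$wt_residue <- toupper(d$wt_residue)
  d$mut_residue <- toupper(d$mut_residue)
  d$family_position <- as.integer(d$family_position)
  bad_side <- !d$side %in% c("DIP", "Dpr")
  if (any(bad_side)) {
    stop("invalid side '", d$side[bad_side][1L], "' (expected DIP or Dpr)")
  }
  for (col in c("wt_residue", "mut_residue")) {
    bad <- !d[[col]] %in% aa_residues
    if (any(bad)) {
      stop(sprintf("unknown residue code '%s' in column %s (row %d)",
                   d[[col]][bad][1L], col, which(bad)[1L]))
    }
  }
  self <- d$wt_residue == d$mut_residue
  if (any(self)) {
    stop(sprintf(
      "self-mutation row %d (%s position %d, %s->%s): mutations into the wild-type residue are not filter input",
      which(self)[1L], d$template_id[self][1L],
      d$family_position[self][1L], d$wt_residue[self][1L],
      d$mut_residue[self][1L]))
  }
  if (any(!is.finite(d$ddg))) stop("non-finite ddg value")
  key <- paste(d$template_id, d$side, d$family_position, d$mut_residue,
               d$source_member, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate ddG record key: ", key[duplicated(key)][1L])
  }
  if ("run_values" %in% names(d) && !is.list(d$run_values)) {
    runs <- lapply(strsplit(as.character(d$run_values), ";", fixed = TRUE),
                   function(x) as.numeric(x[nzchar(x)]))
    has <- lengths(runs) > 0L
    if (any(has)) {
      means <- vapply(runs, function(x) if (length(x)) mean(x) else NA_real_,
                      numeric(1))
      off <- has & abs(means - d$ddg) > 1e-9
      if (any(off)) {
        stop(sprintf("row %d: ddg %.6f does not equal the mean of run_values (%.6f)",
                     which(off)[1L], d$ddg[off][1L], means[off][1L]))
      }
    }
    d$run_values <- runs
  }
  d
}

#' Write a ddG record table
#'
#' @param records Validated ddG record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ddg_table <- function(records, path) {
  d <- records
  if ("run_values" %in% names(d) && is.list(d$run_values)) {
    flat <- sprintf("%.15g", unlist(d$run_values, use.names = FALSE))
    grp <- factor(rep.int(seq_along(d$run_values), lengths(d$run_values)),
                  levels = seq_along(d$run_values))
    d$run_values <- vapply(split(flat, grp), paste, character(1),
                           collapse = ";")
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average replicate runs of a mutational-scan prediction
#'
#' The scan engine is run several times per mutation (ten in the reference
#' protocol) and the replicate mean defines the binding ddG; the spread
#' across runs is diagnostic only.
#'
#' @param run_values Numeric vector of per-run ddG values (>= 1 value).
#' @return Named numeric vector `c(mean, sd)`; `sd` is the sample standard
#'   deviation, 0 for a single run.
#' @export
#' @examples
#' aggregate_runs(rep(0.1, 10))   # mean 0.1, sd 0
aggregate_runs <- function(run_values) {
  run_values <- as.numeric(run_values)
  if (length(run_values) == 0L || any(!is.finite(run_values))) {
    stop("run_values must contain at least one finite value")
  }
  c(mean = mean(run_values),
    sd = if (length(run_values) > 1L) stats::sd(run_values) else 0)
}

#' Apply the energy filter at one position for one non-cognate pair
#'
#' Certifies the "destabilizing everywhere" requirement: every expected
#' template complex crossed with every expected source member whose residue
#' differs from that template's wild type must have a record, and every
#' present record must have ddG >= threshold. Missing coverage fails closed
#' (the filter cannot certify "every"). If all member/template combinations
#' share the wild-type residue (no mutation is possible), the position is
#' not evaluable and is reported with status `"not_applicable"`, never as
#' passed.
#'
#' @param records Data frame of ddG records already restricted to this
#'   (pair, side, family position); see [read_ddg_table()].
#' @param pair Length-2 character vector `c(dip_subgroup, dpr_subgroup)`
#'   naming the non-cognate combination.
#' @param side `"DIP"` or `"Dpr"`: which side of the interface is scanned.
#' @param family_position 1-based family position.
#' @param expected_templates Character vector of template complex ids that
#'   must each be destabilized.
#' @param expected_members Character vector of source-subgroup member labels
#'   whose residues are mutated in.
#' @param params An [energy_filter_params()] object.
#' @param exempt Optional data frame with columns `template_id`,
#'   `source_member` listing combinations where the member shares the
#'   template's wild-type residue (no mutation, hence no requirement).
#' @return A one-row data frame (`EnergyVerdict`): pair, side, position,
#'   `n_records`, `min_ddg`, `coverage_complete`, `passed`, `status`.
#' @export
energy_filter_position <- function(records, pair, side, family_position,
                                   expected_templates, expected_members,
                                   params = energy_filter_params(),
                                   exempt = NULL) {
  stopifnot(length(pair) == 2L, side %in% c("DIP", "Dpr"))
  family_position <- as.integer(family_position)
  if (nrow(records)) {
    outside <- setdiff(unique(records$template_id), expected_templates)
    if (length(outside)) {
      stop("ddG records reference unexpected template(s): ",
           paste(outside, collapse = ", "))
    }
    if (any(records$side != side) ||
        any(records$family_position != family_position)) {
      stop("records are not restricted to the requested side/position")
    }
  }
  required <- expand.grid(template_id = expected_templates,
                          source_member = expected_members,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(exempt) && nrow(exempt)) {
    drop <- paste(required$template_id, required$source_member) %in%
      paste(exempt$template_id, exempt$source_member)
    required <- required[!drop, , drop = FALSE]
  }
  n_rec <- nrow(records)
  min_ddg <- if (n_rec) min(records$ddg) else NA_real_
  if (nrow(required) == 0L) {
    verdict <- energy_verdict_row(pair, side, family_position, n_rec,
                                  min_ddg, coverage_complete = NA,
                                  passed = FALSE, status = "not_applicable")
    return(verdict)
  }
  have <- paste(records$template_id, records$source_member)
  coverage <- all(paste(required$template_id, required$source_member) %in% have)
  passed <- coverage && n_rec >= 1L && min_ddg >= params$ddg_threshold
  energy_verdict_row(pair, side, family_position, n_rec, min_ddg,
                     coverage, passed, status = "ok")
}

energy_verdict_row <- function(pair, side, family_position, n_records,
                               min_ddg, coverage_complete, passed, status) {
  data.frame(dip_subgroup = pair[1L], dpr_subgroup = pair[2L], side = side,
             family_position = as.integer(family_position),
             n_records = as.integer(n_records), min_ddg = min_ddg,
             coverage_complete = coverage_complete, passed = passed,
             status = status, stringsAsFactors = FALSE)
}

#' Notes on importing a FoldX scan
#'
#' Documentation-only helper describing how the output of a FoldX
#' BuildModel/AnalyseComplex mutational scan maps onto the ddG table read by
#' [read_ddg_table()]; this package never executes FoldX.
#'
#' @return A character vector of notes, invisibly; also printed.
#' @export
foldx_table_notes <- function() {
  notes <- c(
    "Each BuildModel mutation run on a repaired template complex yields one",
    "per-run interaction-energy difference from AnalyseComplex (mutant minus",
    "wild type, between the two protomers). With numberOfRuns = 10, collect",
    "the ten values into the semicolon-separated run_values field; their",
    "arithmetic mean is the ddg field (the replicate mean defines the",
    "binding ddG).",
    "template_id names the repaired complex structure; template_subgroup its",
    "cognate specificity subgroup on the mutated side; side is the protomer",
    "being mutated (DIP or Dpr).",
    "family_position is the family-wide interfacial position (1-33 for",
    "DIP/Dpr Ig1 interfaces), mapped from the template's residue numbering",
    "via the position map.",
    "wt_residue is the template residue, mut_residue the residue observed at",
    "the same family position in source_member (a protein of the non-cognate",
    "source_subgroup). Members sharing the wild-type residue produce no row.")
  cat(paste(notes, collapse = "\n"), "\n")
  invisible(notes)
}
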