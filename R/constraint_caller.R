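#' Enumerate DIP x Dpr subgroup combinations
#'
#' All combinations of DIP subgroups with Dpr subgroups, split into the
#' cognate (strongly binding) pairs of the registry's bijection and the
#' non-cognate remainder. With seven subgroups per side this yields the 49
#' possible subfamily combinations of which 42 are non-cognate — the pairs
#' whose failure to bind must be explained by negative constraints.
#'
#' @param registry A [subgroup_registry()].
#' @return A list with data frames `all_pairs`, `cognate_pairs`,
#'   `noncognate_pairs`, each with columns `dip_subgroup`, `dpr_subgroup`.
#' @export
enumerate_subgroup_pairs <- function(registry) {
  stopifnot(inherits(registry, "SubgroupRegistry"))
  all_pairs <- expand.grid(dip_subgroup = names(registry$dip_subgroups),
                           dpr_subgroup = names(registry$dpr_subgroups),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[order(all_pairs$dip_subgroup,
                               all_pairs$dpr_subgroup), , drop = FALSE]
  rownames(all_pairs) <- NULL
  key <- function(d) paste(d$dip_subgroup, d$dpr_subgroup, sep = "\r")
  cognate <- registry$cognate_map
  noncog <- all_pairs[!key(all_pairs) %in% key(cognate), , drop = FALSE]
  rownames(noncog) <- NULL
  list(all_pairs = all_pairs, cognate_pairs = cognate,
       noncognate_pairs = noncog)
}

#' Intersect energy and evolutionary verdicts into constraint calls
#'
#' The protocol applies the energy filter first and subjects its passing
#' positions to the evolutionary filter; a position is called a negative
#' constraint for a (non-cognate pair, side) only when both filters accept.
#' One call row is produced per key in the energy verdict table. An
#' energy-passing key with no matching evolutionary verdict is a pipeline
#' ordering violation and a hard error; energy-failing keys without an
#' evolutionary verdict are reported with `NA` diagnostics and
#' `accepted = FALSE`.
#'
#' @param energy_verdicts Data frame of energy verdicts (see
#'   [energy_filter_position()]), keyed by (`dip_subgroup`, `dpr_subgroup`,
#'   `side`, `family_position`).
#' @param evo_verdicts Data frame of evolutionary verdicts carrying the same
#'   key columns (as produced by [run_pipeline()]'s evo stage, i.e.
#'   [evo_filter_table()] rows augmented with the pair key).
#' @return A data frame of `ConstraintCall` rows: the key columns, both
#'   filters' diagnostics, `energy_passed`, `evo_accepted`, and `accepted`
#'   (the conjunction).
#' @export
call_negative_constraints <- function(energy_verdicts, evo_verdicts) {
  key_cols <- c("dip_subgroup", "dpr_subgroup", "side", "family_position")
  stopifnot(all(key_cols %in% names(energy_verdicts)),
            all(key_cols %in% names(evo_verdicts)))
  ekey <- do.call(paste, c(energy_verdicts[key_cols], sep = "|"))
  vkey <- do.call(paste, c(evo_verdicts[key_cols], sep = "|"))
  if (anyDuplicated(ekey)) {
    stop("duplicate energy verdict key: ", ekey[duplicated(ekey)][1L])
  }
  if (anyDuplicated(vkey)) {
    stop("duplicate evolutionary verdict key: ", vkey[duplicated(vkey)][1L])
  }
  idx <- match(ekey, vkey)
  orphan <- energy_verdicts$passed & is.na(idx)
  if (any(orphan)) {
    stop("energy-passing key lacks an evolutionary verdict: ",
         ekey[orphan][1L], " (pipeline ordering violated)")
  }
  evo_cols <- c("entropy_i", "entropy_j", "identity_condition",
                "property_percent", "size_percent", "accepted")
  evo_part <- evo_verdicts[idx, evo_cols, drop = FALSE]
  names(evo_part)[names(evo_part) == "accepted"] <- "evo_accepted"
  rownames(evo_part) <- NULL
  calls <- cbind(
    energy_verdicts[c(key_cols, "n_records", "min_ddg",
                      "coverage_complete", "status")],
    energy_passed = energy_verdicts$passed,
    evo_part)
  calls$accepted <- calls$energy_passed & !is.na(calls$evo_accepted) &
    calls$evo_accepted
  calls <- calls[order(calls$dip_subgroup, calls$dpr_subgroup, calls$side,
                       calls$family_position), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Consensus over external specificity-position predictors
#'
#' Combines per-position predictions of several sequence-based
#' specificity-determining-position methods (e.g. GroupSim, SDPpred, SPEER,
#' Multi-Harmony, whose outputs are consumed, not recomputed) by simple
#' vote: a position is retained when at least `min_methods` methods predict
#' it (3 of 4 in the reference analysis).
#'
#' @param predictions Data frame with columns `method` and
#'   `family_position`, one row per (method, predicted position).
#' @param method_names Character vector of all method labels considered
#'   (defaults to those present in `predictions`).
#' @param min_methods Minimum number of agreeing methods (default 3).
#' @return Sorted integer vector of consensus positions.
#' @export
#' @examples
#' preds <- data.frame(method = c("A", "B", "C", "A", "B"),
#'                     family_position = c(7, 7, 7, 12, 12))
#' consensus_combiner(preds, method_names = c("A", "B", "C", "D"))  # 7
consensus_combiner <- function(predictions, method_names = NULL,
                               min_methods = 3L) {
  stopifnot(is.data.frame(predictions),
            all(c("method", "family_position") %in% names(predictions)))
  if (is.null(method_names)) {
    method_names <- sort(unique(as.character(predictions$method)))
  }
  unknown <- setdiff(unique(predictions$method), method_names)
  if (length(unknown)) {
    stop("prediction from unlisted method: ", paste(unknown, collapse = ", "))
  }
  min_methods <- as.integer(min_methods)
  if (min_methods < 1L || min_methods > length(method_names)) {
    stop("min_methods must be between 1 and the number of methods (",
         length(method_names), ")")
  }
  d <- unique(predictions[c("method", "family_position")])
  votes <- table(d$family_position)
  sort(as.integer(names(votes)[votes >= min_methods]))
}

#' Convert a dissociation-constant ratio to a binding free-energy change
#'
#' \eqn{\Delta\Delta G = RT \ln(K_{D,mut}/K_{D,wt})} with
#' R = 1.9872e-3 kcal/(mol K). Positive values mean weakened binding.
#' Any concentration unit cancels in the ratio (the reference SPR values
#' are in micromolar); the default temperature is 298.15 K (25 degrees C,
#' the assay temperature).
#'
#' @param kd_wt,kd_mut Positive dissociation constants (same unit);
#'   vectorized.
#' @param temperature Temperature in Kelvin.
#' @return ddG in kcal/mol.
#' @export
#' @examples
#' kd_to_ddg(7.9, 131)   # ~1.66 kcal/mol
#' kd_to_ddg(10, 500)    # ~2.32 kcal/mol
kd_to_ddg <- function(kd_wt, kd_mut, temperature = 298.15) {
  if (any(!is.finite(kd_wt)) || any(!is.finite(kd_mut)) ||
      any(kd_wt <= 0) || any(kd_mut <= 0)) {
    stop("dissociation constants must be positive and finite")
  }
  stopifnot(is.numeric(temperature), all(temperature > 0))
  R <- 1.9872e-3  # kcal / (mol K)
  R * temperature * log(kd_mut / kd_wt)
}

#' Write the negative-constraint report
#'
#' Tab-separated, one row per (pair, side, position) with both filters'
#' diagnostic values and the final verdict, sorted by pair, side, then
#' position. Non-accepted evaluated positions are included so that both
#' filters can be audited.
#'
#' @param calls Constraint-call data frame from
#'   [call_negative_constraints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constraint_report <- function(calls, path) {
  key_cols <- c("dip_subgroup", "dpr_subgroup", "side", "family_position")
  stopifnot(all(key_cols %in% names(calls)))
  key <- do.call(paste, c(calls[key_cols], sep = "|"))
  if (anyDuplicated(key)) {
    stop("duplicate constraint-call key: ", key[duplicated(key)][1L])
  }
  cols <- c(key_cols, "min_ddg", "entropy_i", "entropy_j",
            "property_percent", "size_percent", "accepted")
  extra <- setdiff(names(calls), cols)
  out <- calls[c(cols, extra)]
  out <- out[order(out$dip_subgroup, out$dpr_subgroup, out$side,
                   out$family_position), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
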