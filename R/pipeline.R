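#' Run the negative-constraint pipeline end to end
#'
#' Executes the protocol stages in order: (optionally) generate a synthetic
#' scenario, enumerate non-cognate subgroup pairs, apply the energy filter
#' to every (pair, side, position), apply the evolutionary filter to the
#' same keys, intersect the verdicts into constraint calls, and write the
#' verdict tables, the constraint report, and a run summary. Byte-
#' reproducible given the scenario seed; re-running from the intermediate
#' files of a previous run (via `input_dir`) reproduces the same report.
#'
#' @param out_dir Output directory for reports (created if absent).
#' @param scenario Optional [scenario_config()]; when given, a synthetic
#'   scenario is generated under `file.path(out_dir, "scenario")` and used
#'   as input.
#' @param input_dir Directory holding existing input files in the layout
#'   written by [generate_scenario()] (registry.txt, position_map.tsv,
#'   templates.tsv, ddg_table.tsv, msa_*.fasta, optional
#'   truth_manifest.tsv). Exactly one of `scenario`, `input_dir` must be
#'   given.
#' @param energy_params An [energy_filter_params()].
#' @param evo_params An [evo_filter_params()].
#' @param quiet Suppress per-stage messages.
#' @return A list of class `PipelineRun`: `summary` (named counts),
#'   `calls`, `energy_verdicts`, `evo_verdicts`, `pairs`, `recovery`
#'   (precision/recall against the truth manifest, when present), and
#'   `paths` of the written files.
#' @export
run_pipeline <- function(out_dir, scenario = NULL, input_dir = NULL,
                         energy_params = energy_filter_params(),
                         evo_params = evo_filter_params(),
                         quiet = TRUE) {
  if (is.null(scenario) == is.null(input_dir)) {
    stop("give exactly one of 'scenario' or 'input_dir'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(scenario)) {
    input_dir <- file.path(out_dir, "scenario")
    say("stage simulate: writing scenario to %s", input_dir)
    generate_scenario(scenario, input_dir)
  }
  inputs <- load_pipeline_inputs(input_dir)
  say("stage load: %d subfamily alignments, %d ddG records",
      length(inputs$msas), nrow(inputs$records))

  pairs <- enumerate_subgroup_pairs(inputs$registry)
  say("stage pairs: %d total, %d non-cognate",
      nrow(pairs$all_pairs), nrow(pairs$noncognate_pairs))

  energy <- energy_filter_stage(inputs, pairs$noncognate_pairs,
                                energy_params)
  say("stage energy-filter: %d keys evaluated, %d passed",
      nrow(energy), sum(energy$passed))

  evo <- evo_filter_stage(inputs, pairs$noncognate_pairs, evo_params)
  say("stage evo-filter: %d keys evaluated, %d accepted",
      nrow(evo), sum(evo$accepted))

  calls <- call_negative_constraints(energy, evo)
  say("stage call: %d negative constraints accepted", sum(calls$accepted))

  paths <- list(
    report = file.path(out_dir, "constraint_report.tsv"),
    energy = file.path(out_dir, "energy_verdicts.tsv"),
    evo = file.path(out_dir, "evo_verdicts.tsv"),
    summary = file.path(out_dir, "run_summary.tsv"))
  write_constraint_report(calls, paths$report)
  utils::write.table(energy, paths$energy, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(evo, paths$evo, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  recovery <- NULL
  if (!is.null(inputs$truth)) {
    recovery <- evaluate_recovery(calls, inputs$truth)
    say("stage evaluate: precision %.3f recall %.3f",
        recovery$precision, recovery$recall)
  }
  summary <- c(
    dip_subgroups = length(inputs$registry$dip_subgroups),
    dpr_subgroups = length(inputs$registry$dpr_subgroups),
    pairs_total = nrow(pairs$all_pairs),
    pairs_noncognate = nrow(pairs$noncognate_pairs),
    ddg_records = nrow(inputs$records),
    keys_evaluated = nrow(energy),
    keys_not_applicable = sum(energy$status == "not_applicable"),
    energy_pass = sum(energy$passed),
    evo_pass = sum(evo$accepted),
    accepted = sum(calls$accepted))
  utils::write.table(
    data.frame(key = names(summary), value = unname(summary)),
    paths$summary, sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(summary = summary, calls = calls, energy_verdicts = energy,
                 evo_verdicts = evo, pairs = pairs, recovery = recovery,
                 paths = paths, input_dir = input_dir),
            class = "PipelineRun")
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat("PipelineRun\n")
  for (k in names(x$summary)) cat(sprintf("  %-20s %s\n", k, x$summary[k]))
  if (!is.null(x$recovery)) {
    cat(sprintf("  precision %.3f, recall %.3f (vs truth manifest)\n",
                x$recovery$precision, x$recovery$recall))
  }
  invisible(x)
}

load_pipeline_inputs <- function(input_dir) {
  need <- function(f) {
    p <- file.path(input_dir, f)
    if (!file.exists(p)) stop("missing pipeline input: ", p)
    p
  }
  registry <- read_subgroup_registry(need("registry.txt"))
  position_map <- read_position_map(need("position_map.tsv"))
  templates <- utils::read.delim(need("templates.tsv"),
                                 stringsAsFactors = FALSE)
  records <- read_ddg_table(need("ddg_table.tsv"))
  msas <- list()
  for (side in c("DIP", "Dpr")) {
    subs <- names(if (side == "DIP") registry$dip_subgroups
                  else registry$dpr_subgroups)
    for (sg in subs) {
      fp <- need(msa_file_name(side, sg))
      members <- if (side == "DIP") registry$dip_subgroups[[sg]]
                 else registry$dpr_subgroups[[sg]]
      msa <- read_aligned_fasta(fp, family_side = side, subgroup_id = sg,
                                reference_id = members[1L])
      msas[[paste0(side, ":", sg)]] <- extract_interfacial_columns(
        msa, position_map)
    }
  }
  truth_path <- file.path(input_dir, "truth_manifest.tsv")
  truth <- if (file.exists(truth_path)) read_truth_manifest(truth_path)
           else NULL
  list(registry = registry, position_map = position_map,
       templates = templates, records = records, msas = msas,
       truth = truth,
       member_residues = member_residue_lookup(registry, msas))
}

# Residues of each registry member at each family position, taken from the
# member's own row of its subfamily alignment (restricted to interfacial
# columns). Used to derive the energy filter's coverage requirements.
member_residue_lookup <- function(registry, msas) {
  out <- list()
  for (side in c("DIP", "Dpr")) {
    groups <- if (side == "DIP") registry$dip_subgroups
              else registry$dpr_subgroups
    mats <- list()
    for (sg in names(groups)) {
      msa <- msas[[paste0(side, ":", sg)]]
      m <- as.matrix(msa)
      members <- groups[[sg]]
      missing <- setdiff(members, rownames(m))
      if (length(missing)) {
        stop("member sequence(s) absent from subfamily alignment ",
             sg, ": ", paste(missing, collapse = ", "))
      }
      mats[[sg]] <- m[members, , drop = FALSE]
    }
    out[[side]] <- do.call(rbind, mats)
  }
  out
}

energy_filter_stage <- function(inputs, noncognate_pairs, params) {
  records <- inputs$records
  P <- max(inputs$position_map$family_position)
  out <- list()
  for (k in seq_len(nrow(noncognate_pairs))) {
    dip <- noncognate_pairs$dip_subgroup[k]
    dpr <- noncognate_pairs$dpr_subgroup[k]
    for (side in c("DIP", "Dpr")) {
      cmp <- compared_subgroups(inputs$registry, dip, dpr, side)
      tm <- inputs$templates[
        inputs$templates[[if (side == "Dpr") "dpr_subgroup"
                          else "dip_subgroup"]] == cmp["template"], ,
        drop = FALSE]
      if (nrow(tm) == 0L) {
        stop("no template complexes for subgroup ", cmp["template"])
      }
      protomer <- tm[[if (side == "Dpr") "dpr_member" else "dip_member"]]
      src_members <- if (side == "Dpr") {
        inputs$registry$dpr_subgroups[[cmp["source"]]]
      } else {
        inputs$registry$dip_subgroups[[cmp["source"]]]
      }
      mem_res <- inputs$member_residues[[side]]
      sub <- records$side == side &
        records$template_subgroup == cmp["template"] &
        records$source_subgroup == cmp["source"]
      rec_pos <- records$family_position[sub]
      rec_ddg <- records$ddg[sub]
      rec_tmpl <- records$template_id[sub]
      rec_memb <- records$source_member[sub]
      outside <- setdiff(unique(rec_tmpl), tm$template_id)
      if (length(outside)) {
        stop("ddG records reference unexpected template(s): ",
             paste(outside, collapse = ", "))
      }
      by_pos <- split(seq_along(rec_pos),
                      factor(rec_pos, levels = seq_len(P)))
      wtM <- mem_res[protomer, , drop = FALSE]    # templates x positions
      mutM <- mem_res[src_members, , drop = FALSE]  # members x positions
      n_records <- integer(P)
      min_ddg <- rep(NA_real_, P)
      coverage <- rep(NA, P)
      passed <- logical(P)
      status <- character(P)
      for (p in seq_len(P)) {
        ridx <- by_pos[[p]]
        n_records[p] <- length(ridx)
        if (length(ridx)) min_ddg[p] <- min(rec_ddg[ridx])
        differ <- outer(wtM[, p], mutM[, p], "!=")
        if (!any(differ)) {          # all members share wild-type identity
          status[p] <- "not_applicable"
          next
        }
        status[p] <- "ok"
        req <- paste(tm$template_id[row(differ)[differ]],
                     src_members[col(differ)[differ]])
        have <- paste(rec_tmpl[ridx], rec_memb[ridx])
        coverage[p] <- all(req %in% have)
        passed[p] <- coverage[p] && n_records[p] >= 1L &&
          min_ddg[p] >= params$ddg_threshold
      }
      out[[length(out) + 1L]] <- data.frame(
        dip_subgroup = dip, dpr_subgroup = dpr, side = side,
        family_position = seq_len(P), n_records = n_records,
        min_ddg = min_ddg, coverage_complete = coverage, passed = passed,
        status = status, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

evo_filter_stage <- function(inputs, noncognate_pairs, params) {
  # Per-subgroup column summaries computed once; per-pair work is then a
  # pair of small matrix products. Numerically identical to calling
  # evaluate_evo_filter() per position (asserted in the test suite).
  prep <- lapply(inputs$msas, function(msa) {
    F21 <- vapply(seq_len(ncol_msa(msa)), function(p) {
      as_profile_vector(column_frequency_profile(msa, p))
    }, numeric(length(aa_alphabet)))
    rownames(F21) <- aa_alphabet
    L <- F21 * log(F21, base = 21)
    L[F21 == 0] <- 0
    F20 <- F21[aa_residues, , drop = FALSE]
    if (params$renormalize) {
      cs <- colSums(F20)
      F20 <- sweep(F20, 2L, ifelse(cs > 0, cs, 1), "/")
    }
    modal <- lapply(seq_len(ncol(F20)), function(p) {
      f <- F21[aa_residues, p]
      top <- max(f)
      if (top <= 0) character(0) else names(f)[f >= top - 1e-12]
    })
    list(entropy = -colSums(L), F20 = F20, modal = modal)
  })
  prop <- aa_property_map()
  rank <- aa_size_rank()
  m_prop <- outer(prop, prop, "!=") * 1
  m_larger <- outer(rank, rank, ">") * 1
  m_smaller <- outer(rank, rank, "<") * 1
  P <- ncol_msa(inputs$msas[[1L]])
  out <- list()
  for (k in seq_len(nrow(noncognate_pairs))) {
    dip <- noncognate_pairs$dip_subgroup[k]
    dpr <- noncognate_pairs$dpr_subgroup[k]
    for (side in c("DIP", "Dpr")) {
      cmp <- compared_subgroups(inputs$registry, dip, dpr, side)
      pi <- prep[[paste0(side, ":", cmp["template"])]]
      pj <- prep[[paste0(side, ":", cmp["source"])]]
      prop_pct <- 100 * colSums(pi$F20 * (m_prop %*% pj$F20))
      larger <- 100 * colSums(pi$F20 * (m_larger %*% pj$F20))
      smaller <- 100 * colSums(pi$F20 * (m_smaller %*% pj$F20))
      size_pct <- pmax(larger, smaller)
      conserved <- pi$entropy < params$entropy_cutoff &
        pj$entropy < params$entropy_cutoff
      ident <- vapply(seq_len(P), function(p) {
        conserved[p] &&
          length(intersect(pi$modal[[p]], pj$modal[[p]])) == 0L
      }, logical(1))
      out[[length(out) + 1L]] <- data.frame(
        dip_subgroup = dip, dpr_subgroup = dpr, side = side,
        family_position = seq_len(P),
        subgroup_i = unname(cmp["template"]),
        subgroup_j = unname(cmp["source"]),
        entropy_i = pi$entropy, entropy_j = pj$entropy,
        identity_condition = ident,
        property_percent = prop_pct, size_percent = size_pct,
        accepted = ident | prop_pct > params$property_cutoff |
          size_pct > params$size_cutoff,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Precision and recall of constraint calls against a truth manifest
#'
#' @param calls Constraint-call data frame from
#'   [call_negative_constraints()].
#' @param truth Data frame of planted (pair, side, position) constraints.
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`, `n_called`,
#'   `n_truth`. An empty call set has precision 1 by convention (no false
#'   claims); an empty truth set has recall 1.
#' @export
evaluate_recovery <- function(calls, truth) {
  key <- function(d) paste(d$dip_subgroup, d$dpr_subgroup, d$side,
                           d$family_position, sep = "|")
  called <- unique(key(calls[calls$accepted, , drop = FALSE]))
  planted <- unique(key(truth))
  tp <- length(intersect(called, planted))
  fp <- length(setdiff(called, planted))
  fn <- length(setdiff(planted, called))
  list(precision = if (length(called)) tp / length(called) else 1,
       recall = if (length(planted)) tp / length(planted) else 1,
       tp = tp, fp = fp, fn = fn,
       n_called = length(called), n_truth = length(planted))
}
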