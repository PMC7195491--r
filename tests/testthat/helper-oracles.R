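# Independent brute-force oracles and small random-instance generators used
# across the suite. The oracles deliberately use naive double loops over
# explicit amino-acid pairs / requirement lists so they share no code with
# the implementation they check.

oracle_property_difference <- function(fi, fj, renormalize = FALSE) {
  prop <- aa_property_map()
  fi <- unclass(fi)[aa_residues]
  fj <- unclass(fj)[aa_residues]
  if (renormalize) {
    if (sum(fi) > 0) fi <- fi / sum(fi)
    if (sum(fj) > 0) fj <- fj / sum(fj)
  }
  total <- 0
  for (k in aa_residues) {
    for (l in aa_residues) {
      if (prop[[k]] != prop[[l]]) total <- total + fi[[k]] * fj[[l]]
    }
  }
  total * 100
}

oracle_size_difference <- function(fi, fj, renormalize = FALSE) {
  rank <- aa_size_rank()
  fi <- unclass(fi)[aa_residues]
  fj <- unclass(fj)[aa_residues]
  if (renormalize) {
    if (sum(fi) > 0) fi <- fi / sum(fi)
    if (sum(fj) > 0) fj <- fj / sum(fj)
  }
  larger <- 0
  smaller <- 0
  for (k in aa_residues) {
    for (l in aa_residues) {
      if (rank[[k]] > rank[[l]]) larger <- larger + fi[[k]] * fj[[l]]
      if (rank[[k]] < rank[[l]]) smaller <- smaller + fi[[k]] * fj[[l]]
    }
  }
  max(larger, smaller) * 100
}

# Explicitly enumerate every (template, member) requirement and check each.
oracle_energy_filter <- function(records, expected_templates,
                                 expected_members, exempt, threshold) {
  required <- list()
  for (t in expected_templates) {
    for (m in expected_members) {
      is_exempt <- FALSE
      if (!is.null(exempt) && nrow(exempt)) {
        for (e in seq_len(nrow(exempt))) {
          if (exempt$template_id[e] == t && exempt$source_member[e] == m) {
            is_exempt <- TRUE
          }
        }
      }
      if (!is_exempt) required[[length(required) + 1L]] <- c(t, m)
    }
  }
  if (length(required) == 0L) {
    return(list(status = "not_applicable", passed = FALSE))
  }
  covered <- TRUE
  for (r in required) {
    hit <- FALSE
    for (i in seq_len(nrow(records))) {
      if (records$template_id[i] == r[1L] &&
          records$source_member[i] == r[2L]) hit <- TRUE
    }
    if (!hit) covered <- FALSE
  }
  all_destab <- nrow(records) > 0 && all(records$ddg >= threshold)
  list(status = "ok", passed = covered && all_destab,
       coverage_complete = covered)
}

# Random 21-symbol frequency profile (normalized exponential draws).
random_profile <- function(include_gap = TRUE, concentrated = FALSE) {
  syms <- if (include_gap) aa_alphabet else aa_residues
  x <- stats::rexp(length(syms))
  if (concentrated) x <- x^4
  frequency_profile(stats::setNames(x / sum(x), syms))
}

# Random gap-containing alignment.
random_msa <- function(n_rows, n_cols, side = "Dpr", gap_prob = 0.05) {
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(aa_residues, n_cols, replace = TRUE)
    gaps <- stats::runif(n_cols) < gap_prob
    chars[gaps] <- aa_gap
    paste(chars, collapse = "")
  }, character(1))
  aligned_subfamily(rows, sequence_ids = paste0("s", seq_len(n_rows)),
                    family_side = side, subgroup_id = "rnd")
}

# A tiny ddG record data frame for filter tests.
make_records <- function(template_id, source_member, ddg,
                         side = "Dpr", family_position = 1L,
                         wt = "L", mut = "G",
                         template_subgroup = "Dpr_1",
                         source_subgroup = "Dpr_2") {
  n <- length(template_id)
  data.frame(template_id = template_id,
             template_subgroup = rep_len(template_subgroup, n),
             side = rep_len(side, n),
             family_position = rep_len(as.integer(family_position), n),
             wt_residue = rep_len(wt, n), mut_residue = rep_len(mut, n),
             source_subgroup = rep_len(source_subgroup, n),
             source_member = source_member, ddg = ddg,
             stringsAsFactors = FALSE)
}

# Small fast scenario for pipeline unit tests (not the acceptance-scale one).
small_scenario <- function(seed, ...) {
  scenario_config(n_subgroups_per_side = 3L, members_per_subgroup = 2L,
                  orthologs_per_member = 2L, n_positions = 10L,
                  templates_per_cognate_pair = 2L, seed = seed, ...)
}
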