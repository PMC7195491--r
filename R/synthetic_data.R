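#' Synthetic scenario configuration
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure the two filters assume: subfamily alignments with controlled
#' within-subgroup conservation and between-subgroup divergence, and a
#' mutational ddG table with Gaussian run noise and planted destabilizing
#' effects at known positions. The defaults are the package's reference
#' study conditions: seven subgroups per side (49 subgroup combinations, 42
#' non-cognate), 33 interfacial positions, three members per subgroup,
#' three template complexes per cognate pair, ten runs per mutation with
#' run noise sd 0.05 kcal/mol (the self-mutation spread of the reference
#' scan), planted effect mean 1.0 kcal/mol, and a 2% per-residue
#' substitution noise in the alignments.
#'
#' @param n_subgroups_per_side Subgroups on each side (max 9).
#' @param members_per_subgroup Paralog members per subgroup.
#' @param orthologs_per_member Rows per member in the subfamily alignment
#'   (the member's own sequence plus ortholog sequences generated from it).
#' @param n_positions Number of family-wide interfacial positions.
#' @param templates_per_cognate_pair Template complexes per cognate pair.
#' @param position_plan Character vector of length `n_positions` assigning
#'   each family position a class among `conserved_core`,
#'   `identity_divergent`, `property_divergent`, `size_divergent`,
#'   `neutral`; or a vector named by family positions (unnamed positions
#'   default to `neutral`). Defaults to [default_position_plan()].
#' @param substitution_noise Per-residue probability of mutating a sequence
#'   residue to a uniformly random amino acid (applied when deriving member
#'   sequences from the subgroup consensus and again for each ortholog).
#' @param ddg_effect_mean Mean planted ddG (kcal/mol) at ground-truth
#'   constraint positions.
#' @param ddg_run_sd Per-run Gaussian noise sd (kcal/mol).
#' @param n_runs Runs averaged per mutation.
#' @param stabilizing_fraction Probability that a non-planted
#'   (pair, side, position) draws a negative (stabilizing) mean instead of
#'   zero, emulating the stabilizing mutations seen in real scans.
#' @param stabilizing_mean Mean ddG (kcal/mol) of such stabilizing
#'   positions.
#' @param plant_energy If `FALSE`, no energetic effects are planted (all
#'   non-exempt records draw from the null/stabilizing means) and the truth
#'   manifest is empty; this decouples the filters for null controls.
#' @param seed Integer seed; all stochastic draws derive from it.
#' @return A list of class `ScenarioConfig`.
#' @export
scenario_config <- function(n_subgroups_per_side = 7L,
                            members_per_subgroup = 3L,
                            orthologs_per_member = 4L,
                            n_positions = 33L,
                            templates_per_cognate_pair = 3L,
                            position_plan = NULL,
                            substitution_noise = 0.02,
                            ddg_effect_mean = 1.0,
                            ddg_run_sd = 0.05,
                            n_runs = 10L,
                            stabilizing_fraction = 0.1,
                            stabilizing_mean = -0.5,
                            plant_energy = TRUE,
                            seed = 1L) {
  n_positions <- as.integer(n_positions)
  stopifnot(n_subgroups_per_side >= 1L, n_subgroups_per_side <= 9L,
            members_per_subgroup >= 1L, orthologs_per_member >= 1L,
            n_positions >= 1L, templates_per_cognate_pair >= 1L,
            substitution_noise >= 0, substitution_noise <= 1,
            ddg_run_sd >= 0, n_runs >= 1L,
            stabilizing_fraction >= 0, stabilizing_fraction <= 1,
            is.logical(plant_energy))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  plan <- normalize_position_plan(position_plan, n_positions)
  structure(list(
    n_subgroups_per_side = as.integer(n_subgroups_per_side),
    members_per_subgroup = as.integer(members_per_subgroup),
    orthologs_per_member = as.integer(orthologs_per_member),
    n_positions = n_positions,
    templates_per_cognate_pair = as.integer(templates_per_cognate_pair),
    position_plan = plan,
    substitution_noise = substitution_noise,
    ddg_effect_mean = ddg_effect_mean,
    ddg_run_sd = ddg_run_sd,
    n_runs = as.integer(n_runs),
    stabilizing_fraction = stabilizing_fraction,
    stabilizing_mean = stabilizing_mean,
    plant_energy = plant_energy,
    seed = seed), class = "ScenarioConfig")
}

position_classes <- c("conserved_core", "identity_divergent",
                      "property_divergent", "size_divergent", "neutral")
divergent_classes <- c("identity_divergent", "property_divergent",
                       "size_divergent")

normalize_position_plan <- function(plan, n_positions) {
  if (is.null(plan)) return(default_position_plan(n_positions))
  nm <- names(plan)
  plan <- vapply(plan, as.character, character(1), USE.NAMES = FALSE)
  names(plan) <- nm
  if (!all(plan %in% position_classes)) {
    stop("unknown position class: ",
         paste(setdiff(plan, position_classes), collapse = ", "))
  }
  if (!is.null(names(plan)) && any(nzchar(names(plan)))) {
    pos <- as.integer(names(plan))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > n_positions)) {
      stop("position_plan keys must be family positions in 1..", n_positions)
    }
    if (anyDuplicated(pos)) stop("duplicate position_plan key")
    full <- rep("neutral", n_positions)
    full[pos] <- unname(plan)
    return(full)
  }
  if (length(plan) != n_positions) {
    stop("unnamed position_plan must have length n_positions")
  }
  unname(plan)
}

#' Default position plan
#'
#' Assigns the five position classes cyclically along the family positions
#' (conserved core, identity-divergent, property-divergent, size-divergent,
#' neutral, then repeating), so a 33-position interface carries 7/7/7/6/6
#' positions of the respective classes.
#'
#' @param n_positions Number of family positions.
#' @return Character vector of classes, length `n_positions`.
#' @export
default_position_plan <- function(n_positions = 33L) {
  rep_len(position_classes, n_positions)
}

# Residue preference cycles per class. Distinctness of consecutive entries
# guarantees distinct subgroup consensus residues for up to 9 subgroups.
class_residue_cycle <- list(
  conserved_core = c("L", "V", "I", "F", "A", "Q", "N", "W"),
  # large-size-group residues first, so few-subgroup scenarios stay within
  # one size class (identity difference only)
  identity_divergent = c("M", "I", "L", "K", "R", "E", "V", "Q", "H"),
  # alternating property classes: hydrophobic, polar, positive, negative, ...
  property_divergent = c("L", "S", "K", "E", "F", "T", "R", "D", "I"),
  # alternating size ranks 1/3/5 -> consecutive subgroups differ by >= 2
  size_divergent = c("G", "V", "F", "S", "Q", "W", "A", "H", "Y"))

# Consensus residue of subgroup s (1-based) at position p for a class.
base_residue <- function(class, s, p) {
  cyc <- class_residue_cycle[[class]]
  cyc[((s - 1L + p - 1L) %% length(cyc)) + 1L]
}

build_base_residues <- function(config) {
  S <- config$n_subgroups_per_side
  P <- config$n_positions
  one_side <- function(side) {
    m <- matrix(NA_character_, nrow = S, ncol = P,
                dimnames = list(subgroup_labels(side, S), NULL))
    for (p in seq_len(P)) {
      cls <- config$position_plan[p]
      if (cls == "neutral") next
      if (cls == "conserved_core") {
        m[, p] <- base_residue(cls, 1L, p)
      } else {
        for (s in seq_len(S)) m[s, p] <- base_residue(cls, s, p)
      }
    }
    m
  }
  list(DIP = one_side("DIP"), Dpr = one_side("Dpr"))
}

subgroup_labels <- function(side, n) paste0(side, "_", seq_len(n))
member_labels <- function(subgroup, n) paste0(subgroup, "_m", seq_len(n))

mutate_sequence <- function(chars, eps) {
  if (eps <= 0) return(chars)
  hit <- stats::runif(length(chars)) < eps
  if (any(hit)) chars[hit] <- sample(aa_residues, sum(hit), replace = TRUE)
  chars
}

#' Generate subfamily alignments with planted divergence
#'
#' Builds, for each side and subgroup, a subfamily alignment of member and
#' ortholog sequences realizing the configured position plan:
#' `conserved_core` positions carry one residue shared by all subgroups;
#' `identity_divergent` positions give each subgroup a distinct conserved
#' residue (drawn from one size/property class as far as the subgroup count
#' allows); `property_divergent` positions alternate subgroups across
#' biophysical property classes; `size_divergent` positions place subgroups
#' at least two size ranks apart; `neutral` positions draw residues
#' uniformly per sequence. Every non-neutral residue is then mutated to a
#' uniformly random amino acid with probability `substitution_noise`, once
#' when deriving the member from the subgroup consensus and once more per
#' ortholog row. Deterministic given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `msas` (list of [aligned_subfamily()]
#'   objects named `<side>:<subgroup>`), `registry`
#'   (a [subgroup_registry()]), `position_map` (data frame), and `manifest`
#'   (a `TruthManifest`: planted constraints, realized position classes,
#'   subgroup consensus residues, member residue matrices, template table,
#'   and the generator parameters).
#' @export
generate_subfamily_msas <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  set.seed(config$seed)
  S <- config$n_subgroups_per_side
  P <- config$n_positions
  M <- config$members_per_subgroup
  O <- config$orthologs_per_member
  eps <- config$substitution_noise
  base <- build_base_residues(config)
  neutral <- config$position_plan == "neutral"

  msas <- list()
  member_residues <- list()
  for (side in c("DIP", "Dpr")) {
    subs <- subgroup_labels(side, S)
    mem_mat <- matrix(NA_character_, nrow = 0, ncol = P)
    for (s in seq_len(S)) {
      members <- member_labels(subs[s], M)
      rows <- character(0)
      ids <- character(0)
      for (m in seq_len(M)) {
        mem <- base[[side]][s, ]
        if (any(neutral)) {
          mem[neutral] <- sample(aa_residues, sum(neutral), replace = TRUE)
        }
        mem[!neutral] <- mutate_sequence(mem[!neutral], eps)
        mem_mat <- rbind(mem_mat, mem)
        rownames(mem_mat)[nrow(mem_mat)] <- members[m]
        rows <- c(rows, paste(mem, collapse = ""))
        ids <- c(ids, members[m])
        if (O > 1L) {
          for (o in seq_len(O - 1L)) {
            orth <- mem
            if (any(neutral)) {
              orth[neutral] <- sample(aa_residues, sum(neutral),
                                      replace = TRUE)
            }
            orth[!neutral] <- mutate_sequence(orth[!neutral], eps)
            rows <- c(rows, paste(orth, collapse = ""))
            ids <- c(ids, paste0(members[m], "|orth", o))
          }
        }
      }
      msas[[paste0(side, ":", subs[s])]] <- aligned_subfamily(
        rows, sequence_ids = ids, family_side = side, subgroup_id = subs[s],
        reference_id = members[1L])
    }
    member_residues[[side]] <- mem_mat
  }

  dip_subs <- subgroup_labels("DIP", S)
  dpr_subs <- subgroup_labels("Dpr", S)
  registry <- subgroup_registry(
    dip_subgroups = stats::setNames(
      lapply(dip_subs, member_labels, n = M), dip_subs),
    dpr_subgroups = stats::setNames(
      lapply(dpr_subs, member_labels, n = M), dpr_subs),
    cognate_map = data.frame(dip_subgroup = dip_subs,
                             dpr_subgroup = dpr_subs,
                             stringsAsFactors = FALSE))

  all_members <- c(rownames(member_residues$DIP),
                   rownames(member_residues$Dpr))
  position_map <- data.frame(
    family_position = rep(seq_len(P), times = length(all_members)),
    protein_id = rep(all_members, each = P),
    residue_number = rep(seq_len(P), times = length(all_members)),
    alignment_column = rep(seq_len(P), times = length(all_members)),
    stringsAsFactors = FALSE)

  templates <- build_templates(config, registry)
  planted <- plant_constraints(config, registry, base)
  manifest <- structure(list(
    planted = planted,
    position_plan = config$position_plan,
    base_residues = base,
    member_residues = member_residues,
    templates = templates,
    config = config), class = "TruthManifest")
  list(msas = msas, registry = registry, position_map = position_map,
       manifest = manifest)
}

build_templates <- function(config, registry) {
  cm <- registry$cognate_map
  rows <- lapply(seq_len(nrow(cm)), function(k) {
    dipm <- registry$dip_subgroups[[cm$dip_subgroup[k]]]
    dprm <- registry$dpr_subgroups[[cm$dpr_subgroup[k]]]
    t_idx <- seq_len(config$templates_per_cognate_pair)
    data.frame(
      template_id = paste0("T_", cm$dip_subgroup[k], "_", t_idx),
      dip_subgroup = cm$dip_subgroup[k],
      dpr_subgroup = cm$dpr_subgroup[k],
      dip_member = dipm[((t_idx - 1L) %% length(dipm)) + 1L],
      dpr_member = dprm[((t_idx - 1L) %% length(dprm)) + 1L],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

plant_constraints <- function(config, registry, base) {
  empty <- data.frame(dip_subgroup = character(0),
                      dpr_subgroup = character(0), side = character(0),
                      family_position = integer(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (!config$plant_energy) return(empty)
  pairs <- enumerate_subgroup_pairs(registry)$noncognate_pairs
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    dip <- pairs$dip_subgroup[k]
    dpr <- pairs$dpr_subgroup[k]
    for (side in c("DIP", "Dpr")) {
      cmp <- compared_subgroups(registry, dip, dpr, side)
      b_i <- base[[side]][cmp["template"], ]
      b_j <- base[[side]][cmp["source"], ]
      pos <- which(config$position_plan %in% divergent_classes &
                     !is.na(b_i) & !is.na(b_j) & b_i != b_j)
      if (length(pos)) {
        rows[[length(rows) + 1L]] <- data.frame(
          dip_subgroup = dip, dpr_subgroup = dpr, side = side,
          family_position = pos, class = config$position_plan[pos],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

# For non-cognate pair (DIP-i', Dpr-j') and a side, the subgroup whose
# cognate templates are mutated ("template") and the subgroup contributing
# the mutant residues ("source"). Dpr side: mutate the Dpr cognate of the
# DIP subgroup into the pair's Dpr subgroup; DIP side: mutate the DIP
# cognate of the Dpr subgroup into the pair's DIP subgroup.
compared_subgroups <- function(registry, dip_subgroup, dpr_subgroup, side) {
  if (side == "Dpr") {
    c(template = cognate_partner(registry, dip_subgroup, "DIP"),
      source = dpr_subgroup)
  } else {
    c(template = cognate_partner(registry, dpr_subgroup, "Dpr"),
      source = dip_subgroup)
  }
}

#' Generate a synthetic mutational ddG table
#'
#' Emulates the record layout of a template-complex mutational scan: for
#' every non-cognate pair, side, family position, template complex of the
#' cognate subfamily, and source-subgroup member whose residue differs from
#' the template's wild type, `n_runs` per-run values are drawn i.i.d.
#' Normal(mu, `ddg_run_sd`) and averaged into the record's ddG. The mean mu
#' is `ddg_effect_mean` at planted constraint positions and otherwise 0, or
#' `stabilizing_mean` with probability `stabilizing_fraction` per
#' (pair, side, position). Deterministic given `config$seed` (an
#' independent substream from the alignment generator).
#'
#' @param config A [scenario_config()].
#' @param registry The [subgroup_registry()] from
#'   [generate_subfamily_msas()].
#' @param manifest The matching `TruthManifest`.
#' @return A validated ddG record data frame (see [read_ddg_table()]).
#' @export
generate_ddg_records <- function(config, registry, manifest) {
  stopifnot(inherits(config, "ScenarioConfig"),
            inherits(registry, "SubgroupRegistry"),
            inherits(manifest, "TruthManifest"))
  if (config$templates_per_cognate_pair < 1L) {
    stop("templates_per_cognate_pair must be >= 1")
  }
  set.seed(config$seed %% 2147480000L + 7919L)
  P <- config$n_positions
  templates <- manifest$templates
  planted_key <- paste(manifest$planted$dip_subgroup,
                       manifest$planted$dpr_subgroup,
                       manifest$planted$side,
                       manifest$planted$family_position, sep = "|")
  pairs <- enumerate_subgroup_pairs(registry)$noncognate_pairs
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    dip <- pairs$dip_subgroup[k]
    dpr <- pairs$dpr_subgroup[k]
    for (side in c("DIP", "Dpr")) {
      cmp <- compared_subgroups(registry, dip, dpr, side)
      mem_res <- manifest$member_residues[[side]]
      tm <- templates[templates[[if (side == "Dpr") "dpr_subgroup"
                                 else "dip_subgroup"]] == cmp["template"], ,
                      drop = FALSE]
      protomer <- tm[[if (side == "Dpr") "dpr_member" else "dip_member"]]
      src_members <- if (side == "Dpr") {
        registry$dpr_subgroups[[cmp["source"]]]
      } else {
        registry$dip_subgroups[[cmp["source"]]]
      }
      # per-position null/stabilizing/planted means
      mu <- numeric(P)
      stab <- stats::runif(P) < config$stabilizing_fraction
      mu[stab] <- config$stabilizing_mean
      key <- paste(dip, dpr, side, seq_len(P), sep = "|")
      mu[key %in% planted_key] <- config$ddg_effect_mean

      grid <- expand.grid(t = seq_len(nrow(tm)),
                          m = seq_along(src_members),
                          p = seq_len(P), KEEP.OUT.ATTRS = FALSE)
      wt <- mem_res[cbind(match(protomer[grid$t], rownames(mem_res)),
                          grid$p)]
      mut <- mem_res[cbind(match(src_members[grid$m], rownames(mem_res)),
                           grid$p)]
      keep <- wt != mut
      if (!any(keep)) next
      grid <- grid[keep, , drop = FALSE]
      wt <- wt[keep]; mut <- mut[keep]
      n <- nrow(grid)
      runs <- matrix(stats::rnorm(n * config$n_runs,
                                  mean = rep(mu[grid$p], config$n_runs),
                                  sd = config$ddg_run_sd),
                     nrow = n)
      out[[length(out) + 1L]] <- data.frame(
        template_id = tm$template_id[grid$t],
        template_subgroup = unname(cmp["template"]),
        side = side,
        family_position = grid$p,
        wt_residue = wt,
        mut_residue = mut,
        source_subgroup = unname(cmp["source"]),
        source_member = src_members[grid$m],
        ddg = rowMeans(runs),
        run_values = I(lapply(seq_len(n), function(i) runs[i, ])),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    stop("scenario produced no ddG records (no differing residues)")
  }
  validate_ddg_records(do.call(rbind, out))
}

#' Write a complete synthetic scenario to disk
#'
#' Generates the subfamily alignments, registry, position map, template
#' table, ddG table, and truth manifest, and writes them in the formats the
#' package readers consume: one aligned FASTA per (side, subgroup), the
#' registry config, tab-separated position map / template / ddG / truth
#' tables, and a flat `key = value` echo of the generator parameters.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the generated in-memory objects and the
#'   file paths written.
#' @export
generate_scenario <- function(config, out_dir) {
  stopifnot(inherits(config, "ScenarioConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  gen <- generate_subfamily_msas(config)
  records <- generate_ddg_records(config, gen$registry, gen$manifest)

  paths <- list(
    registry = file.path(out_dir, "registry.txt"),
    position_map = file.path(out_dir, "position_map.tsv"),
    templates = file.path(out_dir, "templates.tsv"),
    ddg_table = file.path(out_dir, "ddg_table.tsv"),
    truth = file.path(out_dir, "truth_manifest.tsv"),
    config = file.path(out_dir, "scenario_config.txt"))
  write_subgroup_registry(gen$registry, paths$registry)
  write_position_map(gen$position_map, paths$position_map)
  utils::write.table(gen$manifest$templates, paths$templates, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ddg_table(records, paths$ddg_table)
  truth <- gen$manifest$planted
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(config_to_lines(config), paths$config)
  paths$msas <- character(0)
  for (nm in names(gen$msas)) {
    msa <- gen$msas[[nm]]
    fp <- file.path(out_dir, msa_file_name(msa$family_side, msa$subgroup_id))
    write_aligned_fasta(msa, fp)
    paths$msas[nm] <- fp
  }
  invisible(c(gen, list(records = records, paths = paths,
                        out_dir = out_dir)))
}

msa_file_name <- function(side, subgroup_id) {
  paste0("msa_", side, "_", gsub("[^A-Za-z0-9._-]", "-", subgroup_id),
         ".fasta")
}

config_to_lines <- function(config) {
  scalar <- config[!names(config) %in% "position_plan"]
  c(vapply(names(scalar), function(k) {
    paste0(k, " = ", format(scalar[[k]], digits = 15))
  }, character(1)),
    paste0("position_plan = ", paste(config$position_plan, collapse = ",")))
}

#' Read a scenario config file
#'
#' Parses the flat `key = value` file written by [generate_scenario()] back
#' into a [scenario_config()].
#'
#' @param path File path.
#' @return A `ScenarioConfig`.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1)))
  names(vals) <- keys
  plan <- strsplit(vals[["position_plan"]], ",", fixed = TRUE)[[1L]]
  num <- function(k) as.numeric(vals[[k]])
  scenario_config(
    n_subgroups_per_side = num("n_subgroups_per_side"),
    members_per_subgroup = num("members_per_subgroup"),
    orthologs_per_member = num("orthologs_per_member"),
    n_positions = num("n_positions"),
    templates_per_cognate_pair = num("templates_per_cognate_pair"),
    position_plan = plan,
    substitution_noise = num("substitution_noise"),
    ddg_effect_mean = num("ddg_effect_mean"),
    ddg_run_sd = num("ddg_run_sd"),
    n_runs = num("n_runs"),
    stabilizing_fraction = num("stabilizing_fraction"),
    stabilizing_mean = num("stabilizing_mean"),
    plant_energy = as.logical(vals[["plant_energy"]]),
    seed = num("seed"))
}

#' Read a truth manifest table
#'
#' @param path Path to the `truth_manifest.tsv` written by
#'   [generate_scenario()].
#' @return Data frame of planted (pair, side, position) constraints.
#' @export
read_truth_manifest <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dip_subgroup", "dpr_subgroup", "side", "family_position")
  if (!all(need %in% names(d))) {
    stop("truth manifest must have columns ", paste(need, collapse = ", "))
  }
  d$family_position <- as.integer(d$family_position)
  d
}
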