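#' Subgroup registry: specificity subfamilies and their cognate pairing
#'
#' A `SubgroupRegistry` records which proteins belong to which
#' interaction-specificity subgroup on each family side, and the one-to-one
#' cognate pairing between DIP subgroups and Dpr subgroups (the strongly
#' binding subfamily pairs). It drives enumeration of the non-cognate
#' subgroup combinations whose negative constraints are to be identified.
#'
#' @param dip_subgroups Named list: DIP subgroup id -> character vector of
#'   member protein labels.
#' @param dpr_subgroups Named list: Dpr subgroup id -> member labels.
#' @param cognate_map Data frame with columns `dip_subgroup`, `dpr_subgroup`
#'   giving the bijective cognate pairing.
#' @return An object of class `SubgroupRegistry`.
#' @seealso [enumerate_subgroup_pairs()], [read_subgroup_registry()]
#' @export
#' @examples
#' reg <- subgroup_registry(
#'   dip_subgroups = list(`DIP-alpha` = "DIP-alpha", `DIP-gamma` = "DIP-gamma"),
#'   dpr_subgroups = list(blue = c("Dpr6", "Dpr10"),
#'                        purple = c("Dpr11", "Dpr15", "Dpr16", "Dpr17")),
#'   cognate_map = data.frame(dip_subgroup = c("DIP-alpha", "DIP-gamma"),
#'                            dpr_subgroup = c("blue", "purple")))
subgroup_registry <- function(dip_subgroups, dpr_subgroups, cognate_map) {
  check_side <- function(groups, side) {
    if (!is.list(groups) || is.null(names(groups)) ||
        any(!nzchar(names(groups)))) {
      stop(side, " subgroups must be a named list")
    }
    if (anyDuplicated(names(groups))) {
      stop("duplicate ", side, " subgroup id")
    }
    members <- unlist(groups, use.names = FALSE)
    if (length(members) == 0L) stop(side, " side has no members")
    if (anyDuplicated(members)) {
      stop("protein '", members[duplicated(members)][1L],
           "' appears in more than one ", side, " subgroup")
    }
    lapply(groups, as.character)
  }
  dip_subgroups <- check_side(dip_subgroups, "DIP")
  dpr_subgroups <- check_side(dpr_subgroups, "Dpr")
  need <- c("dip_subgroup", "dpr_subgroup")
  if (!is.data.frame(cognate_map) || !all(need %in% names(cognate_map))) {
    stop("cognate_map must have columns dip_subgroup, dpr_subgroup")
  }
  cognate_map <- data.frame(
    dip_subgroup = as.character(cognate_map$dip_subgroup),
    dpr_subgroup = as.character(cognate_map$dpr_subgroup),
    stringsAsFactors = FALSE)
  unknown_dip <- setdiff(cognate_map$dip_subgroup, names(dip_subgroups))
  unknown_dpr <- setdiff(cognate_map$dpr_subgroup, names(dpr_subgroups))
  if (length(unknown_dip) || length(unknown_dpr)) {
    stop("cognate pair references unknown subgroup: ",
         paste(c(unknown_dip, unknown_dpr), collapse = ", "))
  }
  if (anyDuplicated(cognate_map$dip_subgroup) ||
      anyDuplicated(cognate_map$dpr_subgroup)) {
    stop("cognate_map must be a bijection (each subgroup appears once)")
  }
  structure(list(dip_subgroups = dip_subgroups,
                 dpr_subgroups = dpr_subgroups,
                 cognate_map = cognate_map),
            class = "SubgroupRegistry")
}

#' @export
print.SubgroupRegistry <- function(x, ...) {
  cat(sprintf("SubgroupRegistry: %d DIP subgroups (%d proteins), %d Dpr subgroups (%d proteins), %d cognate pairs\n",
              length(x$dip_subgroups),
              length(unlist(x$dip_subgroups)),
              length(x$dpr_subgroups),
              length(unlist(x$dpr_subgroups)),
              nrow(x$cognate_map)))
  invisible(x)
}

#' Cognate partner lookup
#'
#' @param registry A `SubgroupRegistry`.
#' @param subgroup_id A subgroup id.
#' @param side Side of `subgroup_id` (`"DIP"` or `"Dpr"`).
#' @return The cognate subgroup id on the opposite side, or `NA` if the
#'   subgroup has no cognate partner listed.
#' @export
cognate_partner <- function(registry, subgroup_id, side = c("DIP", "Dpr")) {
  side <- match.arg(side)
  cm <- registry$cognate_map
  hit <- if (side == "DIP") {
    cm$dpr_subgroup[match(subgroup_id, cm$dip_subgroup)]
  } else {
    cm$dip_subgroup[match(subgroup_id, cm$dpr_subgroup)]
  }
  hit
}

#' Read / write a subgroup registry file
#'
#' Plain-text format with three sections. Lines under `[dip_subgroups]` and
#' `[dpr_subgroups]` read `subgroup_id = member1,member2,...`; lines under
#' `[cognate]` read `dip_subgroup<TAB>dpr_subgroup`. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @return `read_subgroup_registry()` returns a `SubgroupRegistry`;
#'   `write_subgroup_registry()` returns `path` invisibly.
#' @export
read_subgroup_registry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  dip <- list(); dpr <- list()
  cog <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (is.na(section)) stop("registry line outside any section: ", ln)
    if (section %in% c("dip_subgroups", "dpr_subgroups")) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed subgroup line: ", ln)
      id <- trimws(kv[1L])
      members <- trimws(strsplit(kv[2L], ",", fixed = TRUE)[[1L]])
      members <- members[nzchar(members)]
      if (section == "dip_subgroups") dip[[id]] <- members else dpr[[id]] <- members
    } else if (section == "cognate") {
      pair <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1L]])
      if (length(pair) != 2L) stop("malformed cognate line (need TAB): ", ln)
      cog[[length(cog) + 1L]] <- pair
    } else {
      stop("unknown registry section: [", section, "]")
    }
  }
  if (length(cog) == 0L) stop("registry has no [cognate] section entries")
  cm <- do.call(rbind, lapply(cog, function(p) {
    data.frame(dip_subgroup = p[1L], dpr_subgroup = p[2L],
               stringsAsFactors = FALSE)
  }))
  subgroup_registry(dip, dpr, cm)
}

#' @rdname read_subgroup_registry
#' @param registry A `SubgroupRegistry` to write.
#' @export
write_subgroup_registry <- function(registry, path) {
  stopifnot(inherits(registry, "SubgroupRegistry"))
  out <- c("[dip_subgroups]",
           vapply(names(registry$dip_subgroups), function(id) {
             paste0(id, " = ", paste(registry$dip_subgroups[[id]],
                                     collapse = ","))
           }, character(1)),
           "", "[dpr_subgroups]",
           vapply(names(registry$dpr_subgroups), function(id) {
             paste0(id, " = ", paste(registry$dpr_subgroups[[id]],
                                     collapse = ","))
           }, character(1)),
           "", "[cognate]",
           paste(registry$cognate_map$dip_subgroup,
                 registry$cognate_map$dpr_subgroup, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}
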