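# End-to-end photosystem II pipeline: locate the Mn4CaO5 cluster in each
# monomer, predict the four Mn oxidation states, assign the Kok-cycle
# S-state from the total Mn charge, and tabulate reported-vs-predicted
# comparisons.

#' Assign a Kok-cycle S-state from four Mn oxidation labels
#'
#' The S index follows the total Mn charge: S0-S3 correspond to total
#' charges 13-16, extended linearly to negative indices for over-reduced
#' clusters, i.e. `s_index = total_charge - 13`.
#'
#' @param oxidations Character vector of exactly 4 labels in
#'   `{II, III, IV}` (order Mn1..Mn4; the index depends only on the sum).
#' @param monomer_id Optional identifier carried through.
#' @return Object of class `s_state`: list with `monomer_id`, `oxidations`,
#'   `total_charge`, `s_index`.
#' @export
assign_s_state <- function(oxidations, monomer_id = NA) {
  if (length(oxidations) != 4L) {
    stop("exactly 4 oxidation labels required, got ", length(oxidations))
  }
  chg <- sum(oxidation_charge(oxidations))
  structure(
    list(monomer_id = monomer_id,
         oxidations = stats::setNames(as.character(oxidations),
                                      paste0("Mn", 1:4)),
         total_charge = chg, s_index = chg - 13L),
    class = "s_state"
  )
}

#' @export
print.s_state <- function(x, ...) {
  cat("<s_state> ", format_s(x$s_index), "  Mn(",
      paste(x$oxidations, collapse = ","), ")  total charge ",
      x$total_charge, "\n", sep = "")
  invisible(x)
}

format_s <- function(s) ifelse(is.na(s), "S?", paste0("S", s))

# Single-linkage grouping of Mn atoms: edges between Mn pairs closer than
# `link_cutoff`, connected components via union-find.
cluster_mn_atoms <- function(coords, link_cutoff = 6) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1L, 0L))) for (j in (i + 1L):n) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < link_cutoff) {
      parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Extract the OEC Mn sites of each monomer
#'
#' Groups the structure's Mn atoms into monomers by proximity (single
#' linkage, Mn-Mn edges below `link_cutoff`; chain identifiers vary across
#' depositions so distance is the primary signal) and orders each group's
#' four Mn as Mn1..Mn4. When the cluster residue carries canonical atom
#' names MN1..MN4 the ordering follows them; otherwise the dangler
#' heuristic applies: Mn4 is the Mn with the greatest mean distance to the
#' other three (the dangling Mn attached by a single mu-oxo bridge), and
#' Mn1..Mn3 follow atom serial order. Groups with fewer than 4 Mn are
#' skipped with a warning; groups with more keep the 4 mutually closest.
#'
#' @param s An `mn_structure`.
#' @param cutoff Ligand search cutoff (Angstrom) passed to
#'   [find_mn_sites()].
#' @param link_cutoff Mn-Mn grouping distance (Angstrom).
#' @param allowed_elements Ligand elements.
#' @return List of monomers, each a list with `monomer_id`, `chain`,
#'   `mn_serials` (ordered Mn1..Mn4), `sites` (list of 4 `mn_site` objects,
#'   `NULL` where the Mn lacks 6 ligands within the cutoff) and `has_ca`
#'   (TRUE when a calcium sits within 4 A of the Mn centroid).
#' @export
extract_oec <- function(s, cutoff = 2.9, link_cutoff = 6,
                        allowed_elements = c("O", "N")) {
  stopifnot(inherits(s, "mn_structure"))
  atoms <- s$atoms
  mn_idx <- which(atoms$element == "MN")
  if (length(mn_idx) < 4L) {
    warning("structure has ", length(mn_idx), " Mn atom(s); no OEC candidate")
    return(list())
  }
  coords <- as.matrix(atoms[mn_idx, c("x", "y", "z")])
  comp <- cluster_mn_atoms(coords, link_cutoff)
  sites_all <- suppressWarnings(
    find_mn_sites(s, cutoff = cutoff, allowed_elements = allowed_elements,
                  required_coordination = 6L)
  )
  site_by_serial <- stats::setNames(
    sites_all, vapply(sites_all, `[[`, integer(1), "mn_serial")
  )
  monomers <- list()
  for (grp in unique(comp)) {
    members <- which(comp == grp)
    if (length(members) < 4L) {
      warning("Mn group with ", length(members), " member(s) skipped")
      next
    }
    if (length(members) > 4L) {
      combos <- utils::combn(members, 4L)
      spread <- apply(combos, 2, function(sel) {
        sum(stats::dist(coords[sel, , drop = FALSE]))
      })
      members <- combos[, which.min(spread)]
    }
    names4 <- atoms$name[mn_idx[members]]
    if (setequal(names4, paste0("MN", 1:4))) {
      members <- members[match(paste0("MN", 1:4), names4)]
    } else {
      mean_d <- vapply(seq_along(members), function(i) {
        mean(sqrt(rowSums(sweep(coords[members[-i], , drop = FALSE], 2,
                                coords[members[i], ])^2)))
      }, numeric(1))
      dangler <- which.max(mean_d)
      core <- members[-dangler][order(atoms$serial[mn_idx[members[-dangler]]])]
      members <- c(core, members[dangler])
    }
    serials <- atoms$serial[mn_idx[members]]
    ca_idx <- which(atoms$element == "CA")
    has_ca <- length(ca_idx) > 0L && any(vapply(ca_idx, function(ci) {
      min(sqrt(rowSums(sweep(coords[members, , drop = FALSE], 2,
                             unlist(atoms[ci, c("x", "y", "z")]))^2))) < 4.5
    }, logical(1)))
    sites <- lapply(as.character(serials), function(sn) {
      if (sn %in% names(site_by_serial)) site_by_serial[[sn]] else NULL
    })
    chain <- names(sort(table(atoms$chain[mn_idx[members]]),
                        decreasing = TRUE))[1]
    monomers[[length(monomers) + 1L]] <- list(
      monomer_id = length(monomers) + 1L, chain = chain,
      mn_serials = serials, sites = sites, has_ca = has_ca
    )
  }
  monomers
}

#' Predict per-Mn oxidation states and the S-state of each OEC monomer
#'
#' Runs the full pipeline for a photosystem II structure: OEC extraction,
#' per-site feature computation, classifier prediction, and S-state
#' assignment, independently per monomer. A Mn lacking six O/N ligands
#' within the cutoff yields a per-site failure record and an `NA` label
#' (the monomer is marked partially predicted; no label is fabricated).
#'
#' @param s An `mn_structure`.
#' @param model A fitted `oxidation_model`.
#' @param cutoff Ligand cutoff (Angstrom).
#' @param axial_rule Axial-pair rule for [compute_features()].
#' @param link_cutoff Mn-Mn monomer-grouping distance.
#' @return List of per-monomer results: each an `s_state` (with `s_index`
#'   `NA` when partial) plus elements `features` (per-site data frame with
#'   `site`, `E`, `A`, `label`, `mn_serial`), `failures` (character) and
#'   `complete` (logical).
#' @export
predict_oec <- function(s, model, cutoff = 2.9,
                        axial_rule = "longest_pair", link_cutoff = 6) {
  stopifnot(inherits(model, "oxidation_model"))
  monomers <- extract_oec(s, cutoff = cutoff, link_cutoff = link_cutoff)
  lapply(monomers, function(mono) {
    labels <- rep(NA_character_, 4L)
    feats <- data.frame(site = paste0("Mn", 1:4), E = NA_real_, A = NA_real_,
                        label = NA_character_, mn_serial = mono$mn_serials,
                        stringsAsFactors = FALSE)
    failures <- character()
    for (i in 1:4) {
      site <- mono$sites[[i]]
      if (is.null(site)) {
        failures <- c(failures, paste0(
          "Mn", i, " (serial ", mono$mn_serials[i],
          "): fewer than 6 O/N ligands within ", cutoff, " A"
        ))
        next
      }
      f <- compute_features(site, axial_rule = axial_rule)
      feats$E[i] <- f$E
      feats$A[i] <- f$A
      labels[i] <- predict(model, f)
    }
    feats$label <- labels
    complete <- !anyNA(labels)
    st <- if (complete) {
      assign_s_state(labels, monomer_id = mono$monomer_id)
    } else {
      structure(
        list(monomer_id = mono$monomer_id,
             oxidations = stats::setNames(labels, paste0("Mn", 1:4)),
             total_charge = NA_integer_, s_index = NA_integer_),
        class = "s_state"
      )
    }
    st$features <- feats
    st$failures <- failures
    st$complete <- complete
    st$chain <- mono$chain
    st
  })
}

#' Tabulate reported vs. predicted S-states across structures
#'
#' Builds the comparison report: one row per (structure, monomer) with the
#' predicted S index (from the four oxidation labels), the user-supplied
#' reported S-state (from experimental flash protocols, not the coordinate
#' file), and a match flag, plus summary histograms.
#'
#' @param rows Data frame with columns `pdb_id`, `monomer`, `oxidations`
#'   (comma-separated 4 labels, e.g. `"III,IV,IV,III"`) and optionally
#'   `reported_s` (integer S index; `NA` rows get a blank comparison).
#' @return Object of class `prediction_report`: list with `rows` (input plus
#'   `predicted_s`, `total_charge`, `match`), `s_histogram` (per-monomer
#'   table of predicted S indices), `ox_distribution` (per-Mn-position
#'   counts of each oxidation label) and `match_counts` (matches per
#'   monomer).
#' @export
build_report <- function(rows) {
  need <- c("pdb_id", "monomer", "oxidations")
  missing <- setdiff(need, names(rows))
  if (length(missing) > 0L) {
    stop("report rows lack column(s): ", paste(missing, collapse = ", "))
  }
  if (!"reported_s" %in% names(rows)) rows$reported_s <- NA_integer_
  out <- rows
  ox_split <- strsplit(as.character(rows$oxidations), ",[ ]*")
  bad <- vapply(ox_split, length, integer(1)) != 4L
  if (any(bad)) {
    stop("oxidations must list 4 labels: row(s) ",
         paste(which(bad), collapse = ", "))
  }
  states <- lapply(ox_split, assign_s_state)
  out$total_charge <- vapply(states, `[[`, integer(1), "total_charge")
  out$predicted_s <- vapply(states, `[[`, integer(1), "s_index")
  out$match <- ifelse(is.na(out$reported_s), NA,
                      out$reported_s == out$predicted_s)
  ox_mat <- do.call(rbind, ox_split)
  ox_distribution <- vapply(1:4, function(pos) {
    vapply(OXIDATION_LEVELS, function(cl) sum(ox_mat[, pos] == cl),
           integer(1))
  }, integer(3))
  colnames(ox_distribution) <- paste0("Mn", 1:4)
  s_histogram <- table(monomer = out$monomer, predicted_s = out$predicted_s)
  match_counts <- tapply(out$match, out$monomer, function(m) sum(m, na.rm = TRUE))
  structure(
    list(rows = out, s_histogram = s_histogram,
         ox_distribution = ox_distribution,
         match_counts = match_counts),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  r <- x$rows
  cat("<prediction_report> ", nrow(r), " rows, ",
      length(unique(r$pdb_id)), " structures\n", sep = "")
  disp <- data.frame(
    pdb_id = r$pdb_id, monomer = r$monomer,
    reported = format_s(r$reported_s), predicted = format_s(r$predicted_s),
    oxidations = paste0("Mn(", r$oxidations, ")"),
    match = ifelse(is.na(r$match), "", ifelse(r$match, "*", "")),
    stringsAsFactors = FALSE
  )
  print(disp, row.names = FALSE)
  cat("matches per monomer:",
      paste(names(x$match_counts), x$match_counts, sep = ":",
            collapse = "  "), "\n")
  invisible(x)
}
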