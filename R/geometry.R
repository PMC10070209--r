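# Octahedral geometry: antipodal ligand pairing and the two bond-length
# features (mean equatorial E, mean axial A) used by the classifiers.

#' Resolve the three antipodal ligand pairs of an octahedral site
#'
#' Exhaustively searches all 15 perfect matchings of the six ligands into
#' three pairs and returns the matching minimizing the total deviation from
#' linearity, `sum(|180 - angle(L_i, Mn, L_j)|)` in degrees. The objective
#' uses angles only, so Jahn-Teller-elongated bonds cannot distort pair
#' identification.
#'
#' @param site An `mn_site` with exactly 6 ligands.
#' @return A 3x2 integer matrix of ligand indices (rows are pairs), with
#'   attributes `"objective"` (the achieved total angular deviation in
#'   degrees) and `"pair_angles"` (the three Mn-centred angles).
#' @export
pair_opposite_ligands <- function(site) {
  stopifnot(inherits(site, "mn_site"))
  n <- nrow(site$ligands)
  if (n != 6L) {
    stop("pair_opposite_ligands requires exactly 6 ligands, got ", n)
  }
  vecs <- sweep(as.matrix(site$ligands[, c("x", "y", "z")]), 2,
                site$mn_coord)
  angles <- pairwise_angles(vecs)
  matchings <- perfect_matchings_6()
  objectives <- vapply(matchings, function(m) {
    sum(abs(180 - angles[m]))
  }, numeric(1))
  best <- which.min(objectives)   # ties: first matching in canonical order
  pairs <- matrix(matchings[[best]], ncol = 2)
  attr(pairs, "objective") <- objectives[best]
  attr(pairs, "pair_angles") <- angles[pairs]
  pairs
}

# Angle at the origin between row vectors i and j, degrees.
pairwise_angles <- function(vecs) {
  norms <- sqrt(rowSums(vecs^2))
  cosm <- (vecs %*% t(vecs)) / outer(norms, norms)
  # keep matrix dims: scalar-first pmin/pmax would drop them
  cosm <- pmin(pmax(cosm, -1), 1)
  acos(cosm) * 180 / pi
}

# The 15 perfect matchings of {1..6}, each as a 3x2 index matrix (flattened
# column-major). Built once per call; cheap enough not to memoize.
perfect_matchings_6 <- function() {
  rec <- function(idx) {
    if (length(idx) == 0L) return(list(integer(0)))
    first <- idx[1]
    rest <- idx[-1]
    out <- list()
    for (j in seq_along(rest)) {
      for (m in rec(rest[-j])) {
        out[[length(out) + 1L]] <- c(first, rest[j], m)
      }
    }
    out
  }
  lapply(rec(1:6), function(flat) {
    m <- matrix(flat, ncol = 2, byrow = TRUE)
    cbind(m[, 1], m[, 2])
  })
}

#' Compute the equatorial/axial bond-length features of an octahedral site
#'
#' Pairs the six ligands into antipodal pairs, designates one pair as axial,
#' and returns `E` (mean of the four equatorial Mn-ligand distances) and `A`
#' (mean of the two axial distances), both in Angstrom. The default
#' `longest_pair` rule takes the pair with the greatest mean distance as
#' axial, reflecting the Jahn-Teller axial elongation of Mn(III); an
#' explicit pair index can be forced with `axial_rule = "named_axis"`.
#'
#' @param site An `mn_site` with exactly 6 ligands.
#' @param axial_rule `"longest_pair"` (default) or `"named_axis"`.
#' @param axial_pair Pair index (1-3, row of the pairing matrix) when
#'   `axial_rule = "named_axis"`.
#' @return An object of class `octa_features`: list with `E`, `A`,
#'   `pairing` (3x2 index matrix), `axial_pair_index`, and `tie` (TRUE when
#'   two pair means tied to < 1e-9 A and the tie was broken by ligand index
#'   order).
#' @export
compute_features <- function(site, axial_rule = c("longest_pair", "named_axis"),
                             axial_pair = NULL) {
  axial_rule <- match.arg(axial_rule)
  pairing <- pair_opposite_ligands(site)
  d <- site$ligands$distance
  pair_means <- rowMeans(matrix(d[pairing], ncol = 2))
  tie <- FALSE
  if (axial_rule == "longest_pair") {
    axial_idx <- which.max(pair_means)
    near_ties <- which(abs(pair_means - pair_means[axial_idx]) < 1e-9)
    if (length(near_ties) > 1L) {
      # deterministic tie-break: pair containing the lowest ligand index
      axial_idx <- near_ties[which.min(apply(pairing[near_ties, , drop = FALSE],
                                             1, min))]
      tie <- TRUE
      message("compute_features: axial pair tie broken by ligand index order")
    }
  } else {
    if (is.null(axial_pair) || !axial_pair %in% 1:3) {
      stop("axial_rule = 'named_axis' requires axial_pair in 1:3")
    }
    axial_idx <- as.integer(axial_pair)
  }
  ax <- pairing[axial_idx, ]
  eq <- setdiff(seq_len(6), ax)
  out <- structure(
    list(E = mean(d[eq]), A = mean(d[ax]), pairing = pairing,
         axial_pair_index = axial_idx, tie = tie),
    class = "octa_features"
  )
  stopifnot(out$E > 0, out$A > 0)
  out
}

#' @export
print.octa_features <- function(x, ...) {
  cat(sprintf("<octa_features> E = %.3f A (equatorial), A = %.3f A (axial)\n",
              x$E, x$A))
  invisible(x)
}

#' Feature table for every octahedral Mn site of a structure
#'
#' Convenience wrapper chaining [find_mn_sites()] and [compute_features()].
#'
#' @inheritParams find_mn_sites
#' @inheritParams compute_features
#' @return Data frame with one row per 6-coordinate Mn site: `id`
#'   (serial-based), `chain`, `site_label`, `E`, `A`.
#' @export
structure_features <- function(s, cutoff = 2.9,
                               allowed_elements = c("O", "N"),
                               axial_rule = "longest_pair") {
  sites <- find_mn_sites(s, cutoff = cutoff,
                         allowed_elements = allowed_elements,
                         required_coordination = 6L)
  rows <- lapply(sites, function(site) {
    f <- compute_features(site, axial_rule = axial_rule)
    data.frame(
      id = paste0("Mn", site$mn_serial), chain = site$chain_id,
      site_label = site$site_label, E = f$E, A = f$A,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(id = character(), chain = character(),
                      site_label = character(), E = double(), A = double(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
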