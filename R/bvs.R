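# Bond-valence sums: v = sum_i exp((R0 - R_i) / B) over metal-ligand bonds,
# candidate-matching oxidation assignment, and 1-D recalibration of R0
# against reference sites of known oxidation state.

#' Bond-valence parameters for Mn-O/N bonds
#'
#' Returns the R0/B parameter table, keyed by (assumed oxidation state,
#' ligand element). `path = NULL` loads the packaged defaults
#' (`inst/extdata/bvs_params.tsv`): published bond-valence parameters from
#' the Brese & O'Keeffe / Brown compilations (external reference data, not
#' derived in this package), with the universal constant B = 0.37 A.
#'
#' @param path Optional path to a user parameter table (TSV with columns
#'   `state`, `element`, `R0`, `B`, `source`; `#` comments allowed).
#' @return Data frame of class `bvs_params`.
#' @export
bvs_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bvs_params.tsv", package = "mnoxstate",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("state", "element", "R0", "B")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("parameter table lacks column(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(all(tab$B > 0), all(tab$R0 >= 1.2), all(tab$R0 <= 2.5))
  tab$element <- toupper(tab$element)
  class(tab) <- c("bvs_params", "data.frame")
  tab
}

lookup_bvs <- function(params, state, elements) {
  idx <- match(paste(state, toupper(elements)),
               paste(params$state, params$element))
  if (anyNA(idx)) {
    bad <- unique(toupper(elements)[is.na(idx)])
    stop("no bond-valence parameters for state ", state, " with element(s) ",
         paste(bad, collapse = ", "))
  }
  params[idx, , drop = FALSE]
}

#' Bond-valence sum for a set of metal-ligand distances
#'
#' Computes `v = sum_i exp((R0_i - R_i) / B_i)` with `R0` looked up per
#' (assumed state, ligand element).
#'
#' @param distances Numeric vector of bond lengths (Angstrom), or a data
#'   frame with columns `distance` and `element`.
#' @param params A `bvs_params` table.
#' @param assumed_state Oxidation state the parameters are drawn for
#'   (`"II"`, `"III"`, `"IV"` or 2/3/4).
#' @param elements Ligand elements (recycled) when `distances` is numeric.
#' @return Object of class `bvs_result`: list with `v`, `contributions`,
#'   `assumed_state`.
#' @export
bond_valence_sum <- function(distances, params = bvs_params(),
                             assumed_state = "II", elements = "O") {
  if (is.data.frame(distances)) {
    elements <- distances$element
    distances <- distances$distance
  }
  if (length(distances) == 0L) stop("no distances supplied")
  stopifnot(all(distances > 0))
  state <- normalize_state(assumed_state)
  elements <- rep_len(toupper(elements), length(distances))
  rows <- lookup_bvs(params, state, elements)
  contrib <- exp((rows$R0 - distances) / rows$B)
  structure(
    list(v = sum(contrib), contributions = contrib, assumed_state = state),
    class = "bvs_result"
  )
}

normalize_state <- function(state) {
  if (is.numeric(state)) {
    return(OXIDATION_LEVELS[match(state, 2:4)])
  }
  match.arg(as.character(state), OXIDATION_LEVELS)
}

state_value <- function(state) c(II = 2, III = 3, IV = 4)[[state]]

#' Assign an oxidation state to a Mn site by self-consistent bond valence
#'
#' Evaluates the bond-valence sum under each candidate state's parameter
#' set and assigns the candidate minimizing `|v - candidate|`; exact ties go
#' to the lower state.
#'
#' @param site An `mn_site` (its ligand distances and elements are used), or
#'   a data frame with `distance` and `element` columns.
#' @param params A `bvs_params` table.
#' @param candidates Candidate states (default II/III/IV).
#' @return Object of class `bvs_assignment`: list with `assigned`,
#'   `candidate_table` (data frame of state, v, deviation) and the winning
#'   `bvs_result`.
#' @export
assign_bvs_oxidation <- function(site, params = bvs_params(),
                                 candidates = c("II", "III", "IV")) {
  bonds <- if (inherits(site, "mn_site")) {
    data.frame(distance = site$ligands$distance,
               element = site$ligands$element, stringsAsFactors = FALSE)
  } else {
    site
  }
  candidates <- unname(vapply(candidates, normalize_state, character(1)))
  candidates <- candidates[order(vapply(candidates, state_value, numeric(1)))]
  results <- lapply(candidates, function(st) {
    bond_valence_sum(bonds, params, assumed_state = st)
  })
  v <- vapply(results, `[[`, numeric(1), "v")
  target <- vapply(candidates, state_value, numeric(1))
  dev <- abs(v - target)
  # ties broken toward the lower state: candidates are in ascending order
  win <- which(dev <= min(dev) + 1e-12)[1]
  structure(
    list(
      assigned = candidates[win],
      candidate_table = data.frame(state = unname(candidates), v = v,
                                   deviation = dev, row.names = NULL),
      result = results[[win]]
    ),
    class = "bvs_assignment"
  )
}

#' @export
print.bvs_assignment <- function(x, ...) {
  cat("<bvs_assignment> assigned Mn(", x$assigned, ")\n", sep = "")
  print(transform(x$candidate_table, v = round(v, 4),
                  deviation = round(deviation, 4)))
  invisible(x)
}

#' Recalibrate R0 against reference sites of known oxidation state
#'
#' For each (state, element) pair being calibrated, solves for the R0 that
#' zeroes the mean residual `mean_sites(v(R0)) - state` over the reference
#' sites, by 1-D root bracketing on [1.5, 2.2] Angstrom with B held fixed.
#' Only the target element's R0 is varied; contributions from other ligand
#' elements use the existing parameters.
#'
#' @param reference_sites List of `list(site = <mn_site or bond data
#'   frame>, state = <known oxidation>)`.
#' @param params Starting `bvs_params` table.
#' @param element Ligand element whose R0 is calibrated (default `"O"`).
#' @param interval Bracketing interval for R0 (Angstrom).
#' @param tol Root residual tolerance.
#' @return Updated `bvs_params` table with attribute `"calibration"` (data
#'   frame of state, element, R0, residual, n_sites).
#' @export
calibrate_r0 <- function(reference_sites, params = bvs_params(),
                         element = "O", interval = c(1.5, 2.2),
                         tol = 1e-10) {
  stopifnot(length(reference_sites) >= 1L)
  element <- toupper(element)
  refs <- lapply(reference_sites, function(rs) {
    bonds <- if (inherits(rs$site, "mn_site")) {
      data.frame(distance = rs$site$ligands$distance,
                 element = rs$site$ligands$element, stringsAsFactors = FALSE)
    } else {
      rs$site
    }
    list(bonds = bonds, state = normalize_state(rs$state))
  })
  states <- unique(vapply(refs, `[[`, character(1), "state"))
  out <- params
  log <- data.frame(state = character(), element = character(),
                    R0 = double(), residual = double(), n_sites = integer(),
                    stringsAsFactors = FALSE)
  for (st in states) {
    sel <- refs[vapply(refs, function(r) r$state == st, logical(1))]
    b_row <- lookup_bvs(params, st, element)
    B <- b_row$B[1]
    residual <- function(r0) {
      trial <- out
      trial$R0[trial$state == st & trial$element == element] <- r0
      mean(vapply(sel, function(r) {
        bond_valence_sum(r$bonds, trial, assumed_state = st)$v
      }, numeric(1))) - state_value(st)
    }
    flo <- residual(interval[1])
    fhi <- residual(interval[2])
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
      stop("calibration failure: no R0 bracket in [",
           interval[1], ", ", interval[2], "] A for Mn(", st, ")-", element)
    }
    root <- stats::uniroot(residual, interval, tol = 1e-12)
    res <- residual(root$root)
    if (abs(res) > 1e-8) {
      stop("calibration residual ", format(res), " exceeds 1e-8 for Mn(",
           st, ")-", element)
    }
    out$R0[out$state == st & out$element == element] <- root$root
    log <- rbind(log, data.frame(
      state = st, element = element, R0 = root$root, residual = res,
      n_sites = length(sel), stringsAsFactors = FALSE
    ))
  }
  attr(out, "calibration") <- log
  out
}
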