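# Synthetic ground-truth generators: 2-D Gaussian feature mixtures emulating
# the curated small-molecule dataset, single-octahedron PDB fixtures, and
# mu-oxo-bridged Mn4(Ca) cluster fixtures for the end-to-end pipeline.
# All generators are deterministic given a seed; coordinates are written at
# PDB precision (0.001 A) and every stored ground-truth quantity is
# recomputed from the rounded coordinates so file round-trips are exact.

#' K-means cluster centers of the three Mn oxidation-state classes
#'
#' Feature-space centers (E = mean equatorial, A = mean axial bond length,
#' Angstrom) of the Mn(II), Mn(III) and Mn(IV) clusters in the curated
#' small-molecule dataset. Used as the default generating centers for
#' synthetic mixtures and as reference points in tests.
#'
#' @return 3x2 numeric matrix, rows named `II`, `III`, `IV`, columns `E`, `A`.
#' @export
default_cluster_centers <- function() {
  matrix(c(2.18, 2.28,
           1.95, 2.26,
           1.91, 2.05),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("II", "III", "IV"), c("E", "A")))
}

#' Class counts of the curated small-molecule dataset
#'
#' Number of Mn(II), Mn(III) and Mn(IV) structures in the curated octahedral
#' O/N-ligated reference dataset; the default class sizes for synthetic
#' feature tables.
#' @return Named integer vector.
#' @export
default_class_counts <- function() {
  c(II = 1734L, III = 835L, IV = 107L)
}

OXIDATION_LEVELS <- c("II", "III", "IV")

oxidation_charge <- function(labels) {
  chg <- c(II = 2L, III = 3L, IV = 4L)
  bad <- !labels %in% names(chg)
  if (any(bad)) stop("unknown oxidation label(s): ",
                     paste(unique(labels[bad]), collapse = ", "))
  unname(chg[labels])
}

#' Generate a labeled (E, A) feature table from a 3-class Gaussian mixture
#'
#' Samples per-class bivariate Gaussians around the oxidation-state cluster
#' centers and optionally corrupts a fraction of the visible labels
#' (swapping uniformly to one of the other two classes) to emulate the
#' mislabeled entries seen in the real dataset. The uncorrupted label is
#' kept in the `truth` column.
#'
#' @param counts Named integer vector of class sizes (`II`, `III`, `IV`);
#'   default: the real dataset's counts 1734/835/107.
#' @param centers 3x2 matrix of class centers (rows `II`/`III`/`IV`,
#'   columns `E`/`A`).
#' @param sigma Within-class standard deviation in Angstrom. Either a single
#'   number (isotropic) or a list of three 2x2 covariance matrices. The
#'   0.03 A isotropic default reproduces the visual spread of the real
#'   clusters.
#' @param mislabel_rate Probability that a row's visible label is swapped.
#' @param seed Integer seed; the table is bit-reproducible given the seed.
#' @return Data frame with columns `id`, `E`, `A`, `label` (visible,
#'   possibly corrupted) and `truth` (generating class).
#' @export
gen_feature_table <- function(counts = default_class_counts(),
                              centers = default_cluster_centers(),
                              sigma = 0.03, mislabel_rate = 0,
                              seed = NULL) {
  stopifnot(all(counts >= 0), sum(counts) >= 3,
            mislabel_rate >= 0, mislabel_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- rownames(centers)
  if (is.null(classes)) classes <- OXIDATION_LEVELS
  covs <- if (is.list(sigma)) {
    stopifnot(length(sigma) == length(classes))
    sigma
  } else {
    rep(list(diag(sigma^2, 2)), length(classes))
  }
  blocks <- lapply(seq_along(classes), function(k) {
    n <- counts[[classes[k]]]
    if (n == 0L) return(NULL)
    L <- chol(covs[[k]])
    z <- matrix(stats::rnorm(2L * n), ncol = 2) %*% L
    data.frame(
      E = centers[k, "E"] + z[, 1],
      A = centers[k, "A"] + z[, 2],
      truth = classes[k],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, blocks)
  n <- nrow(tab)
  tab$label <- tab$truth
  if (mislabel_rate > 0) {
    flip <- stats::runif(n) < mislabel_rate
    if (any(flip)) {
      tab$label[flip] <- vapply(tab$truth[flip], function(cl) {
        sample(setdiff(classes, cl), 1L)
      }, character(1))
    }
  }
  data.frame(
    id = sprintf("syn%05d", seq_len(n)),
    E = tab$E, A = tab$A, label = tab$label, truth = tab$truth,
    stringsAsFactors = FALSE
  )
}

# Uniformly distributed random rotation matrix (QR of a Gaussian matrix,
# det fixed to +1).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

unit <- function(v) v / sqrt(sum(v^2))

# Any unit vector orthogonal to u.
any_perp <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(pracma_cross(u, ref))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

pdb_atom_line <- function(record, serial, name, resname, chain, resseq,
                          xyz, occ = 1.0, b = 0.0, element = "") {
  nm <- if (nchar(name) < 4 && !toupper(substr(name, 1, 2)) %in%
              TWO_LETTER_ELEMENTS) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, resname, chain, resseq,
          xyz[1], xyz[2], xyz[3], occ, b, toupper(element))
}

#' Write a single-octahedron PDB fixture with known geometry
#'
#' Places one Mn with six ligands on (optionally jittered) octahedral
#' directions: four equatorial bonds of length `eq` and one antipodal axial
#' pair of length `ax`, under an optional random rotation. Coordinates are
#' rounded to PDB precision (0.001 A) before the ground truth is computed,
#' so stored distances and features agree exactly with what a reader
#' recovers from the file.
#'
#' @param path Output PDB path.
#' @param eq,ax Equatorial / axial bond lengths (Angstrom).
#' @param angular_jitter Angular noise (degrees, sd) on ligand directions.
#' @param distance_jitter Bond-length noise (Angstrom, sd).
#' @param elements Character vector of 6 ligand elements.
#' @param label Optional ground-truth oxidation label stored in the record.
#' @param seed Integer seed.
#' @param rotate Apply a random rigid rotation (default TRUE). Disable to
#'   keep axis-aligned coordinates exactly representable at file precision.
#' @param origin Mn position.
#' @return (invisibly) list with `path`, `mn_coord`, `coords` (6x3 ligand
#'   matrix, rounded), `distances`, `E`, `A`, `pairing` (ground-truth
#'   antipodal pairs), `axial_pair` (ligand indices 5:6), `label`,
#'   `elements`.
#' @export
gen_octahedron_file <- function(path, eq = 1.95, ax = 2.26,
                                angular_jitter = 0, distance_jitter = 0,
                                elements = rep("O", 6), label = NULL,
                                seed = NULL, rotate = TRUE,
                                origin = c(10, 10, 10)) {
  stopifnot(eq > 0, ax > 0, angular_jitter >= 0, distance_jitter >= 0,
            length(elements) == 6)
  if (!is.null(seed)) set.seed(seed)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  if (angular_jitter > 0) {
    sdn <- sin(angular_jitter * pi / 180)
    dirs <- t(apply(dirs, 1, function(u) unit(u + stats::rnorm(3, sd = sdn))))
  }
  d <- c(rep(eq, 4), rep(ax, 2))
  if (distance_jitter > 0) {
    d <- pmax(0.5, d + stats::rnorm(6, sd = distance_jitter))
  }
  if (rotate) {
    dirs <- dirs %*% t(random_rotation())
  }
  coords <- sweep(dirs * d, 2, origin, `+`)
  coords <- round(coords, 3)
  mn <- round(origin, 3)
  dist_true <- sqrt(rowSums(sweep(coords, 2, mn)^2))
  lines <- c(
    pdb_atom_line("HETATM", 1L, "MN", "MNO", "A", 1L, mn, element = "MN"),
    vapply(1:6, function(i) {
      pdb_atom_line("HETATM", i + 1L, paste0(elements[i], i), "MNO", "A", 1L,
                    coords[i, ], element = elements[i])
    }, character(1)),
    "END"
  )
  writeLines(lines, path)
  invisible(list(
    path = path, mn_coord = mn, coords = coords, distances = dist_true,
    E = mean(dist_true[1:4]), A = mean(dist_true[5:6]),
    pairing = matrix(1:6, ncol = 2, byrow = TRUE),
    axial_pair = 5:6, label = label, elements = elements
  ))
}

# --- OEC-like cluster construction ------------------------------------------

# Idealized Mn template (A): a bent Mn1-Mn2-Mn3 chain core at 2.8-3.0 A
# adjacent separations with the dangling Mn4 ~3.5 A from Mn3. Adjacent Mn
# pairs (closer than `bridge_max`) share a mu-oxo bridging oxygen, as in
# the real cluster; the open chain keeps every Mn at <= 2 bridges so each
# site's six intended ligands remain its six nearest atoms.
oec_mn_template <- function(dangler_shift = 0) {
  p <- rbind(
    Mn1 = c(0.00, 0.00, 0.00),
    Mn2 = c(2.80, 0.00, 0.00),
    Mn3 = c(5.00, 2.00, 0.30),
    Mn4 = c(8.30, 3.20, 0.00)
  )
  if (dangler_shift != 0) {
    p["Mn4", ] <- p["Mn4", ] + dangler_shift * unit(p["Mn4", ] - p["Mn3", ])
  }
  p
}

# Build one monomer's atoms. Returns list(atoms = data.frame, sites = list of
# per-Mn ligand row indices + ground-truth E/A) or NULL if the geometry
# attempt produced a clash (caller retries with new random phases).
build_oec_monomer <- function(labels, centers, bridge_max = 3.6,
                              dangler_shift = 0, distance_jitter = 0,
                              n_ligand_element = TRUE) {
  P <- oec_mn_template(dangler_shift)
  EA <- centers[labels, , drop = FALSE]
  Evec <- EA[, "E"]
  Avec <- EA[, "A"]
  if (distance_jitter > 0) {
    Evec <- Evec + stats::rnorm(4, sd = distance_jitter)
    Avec <- Avec + stats::rnorm(4, sd = distance_jitter)
  }
  dmat <- as.matrix(stats::dist(P))
  bridges <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    if (dmat[i, j] < bridge_max) bridges[[length(bridges) + 1L]] <- c(i, j)
  }
  n_bridges_of <- function(i) sum(vapply(bridges, function(b) i %in% b, logical(1)))
  k_count <- vapply(1:4, n_bridges_of, integer(1))
  # bridge radius on side i: equatorial unless Mn i already has 3 bridges,
  # in which case the bridge to its farthest partner doubles as its axial bond
  axial_bridge_of <- rep(NA_integer_, 4)
  for (i in 1:4) {
    if (k_count[i] == 3L) {
      partners <- vapply(bridges, function(b) {
        if (i %in% b) setdiff(b, i) else NA_integer_
      }, integer(1))
      axial_bridge_of[i] <- partners[which.max(ifelse(is.na(partners), -Inf,
                                                      dmat[i, partners]))]
    }
  }
  bridge_radius <- function(i, j) {
    if (!is.na(axial_bridge_of[i]) && axial_bridge_of[i] == j) Avec[i] else Evec[i]
  }
  # place bridging oxygens on the circle satisfying both bond lengths,
  # offset away from the centroid of the remaining Mn, with a random phase
  atoms <- data.frame(name = character(), element = character(),
                      x = double(), y = double(), z = double(),
                      stringsAsFactors = FALSE)
  add_atom <- function(name, element, xyz) {
    atoms[nrow(atoms) + 1L, ] <<- list(name, element, xyz[1], xyz[2], xyz[3])
    nrow(atoms)
  }
  mn_rows <- integer(4)
  for (i in 1:4) {
    mn_rows[i] <- add_atom(paste0("MN", i), "MN", P[i, ])
  }
  site_lig <- vector("list", 4)   # per Mn: list of (atom row, role)
  for (i in 1:4) site_lig[[i]] <- list(rows = integer(), role = character())
  ob_count <- 0L
  for (b in bridges) {
    i <- b[1]; j <- b[2]
    ri <- bridge_radius(i, j); rj <- bridge_radius(j, i)
    d <- dmat[i, j]
    if (ri + rj <= d + 1e-9) return(NULL)
    u <- unit(P[j, ] - P[i, ])
    a <- (d^2 + ri^2 - rj^2) / (2 * d)
    h <- sqrt(max(ri^2 - a^2, 0))
    others <- setdiff(1:4, b)
    away <- colMeans(P[b, , drop = FALSE]) - colMeans(P[others, , drop = FALSE])
    away_perp <- away - sum(away * u) * u
    n0 <- if (sqrt(sum(away_perp^2)) > 1e-6) unit(away_perp) else any_perp(u)
    phi <- stats::runif(1, -40, 40) * pi / 180
    n2 <- unit(pracma_cross(u, n0))
    nvec <- cos(phi) * n0 + sin(phi) * n2
    B <- P[i, ] + a * u + h * nvec
    ob_count <- ob_count + 1L
    row <- add_atom(paste0("OB", ob_count), "O", B)
    role_i <- if (!is.na(axial_bridge_of[i]) && axial_bridge_of[i] == j) "ax" else "eq"
    role_j <- if (!is.na(axial_bridge_of[j]) && axial_bridge_of[j] == i) "ax" else "eq"
    site_lig[[i]]$rows <- c(site_lig[[i]]$rows, row)
    site_lig[[i]]$role <- c(site_lig[[i]]$role, role_i)
    site_lig[[j]]$rows <- c(site_lig[[j]]$rows, row)
    site_lig[[j]]$role <- c(site_lig[[j]]$role, role_j)
  }
  # terminal ligands: antipode of each bridge (same role/length), then
  # orthogonal filler pairs; exactly one axial pair per site overall
  # placement margin for a prospective ligand atom of site i: it must clear
  # every OTHER Mn by more than that site's own longest bond (nearest-6
  # recovery) and keep a nonbonded gap from already-placed atoms
  thr_mn <- pmax(Evec, Avec) + 0.06
  ot_count <- 0L
  for (i in 1:4) {
    margin_of <- function(pos) {
      others <- setdiff(1:4, i)
      d_j <- sqrt(rowSums(sweep(P[others, , drop = FALSE], 2, pos)^2))
      existing <- as.matrix(atoms[, c("x", "y", "z")])
      d_at <- min(sqrt(rowSums(sweep(existing, 2, pos)^2)))
      min(min(d_j - thr_mn[others]), d_at - 1.2)
    }
    tilt_about <- function(base, theta, axis) {
      axis <- unit(axis - sum(axis * base) * base)
      unit(cos(theta) * base + sin(theta) * axis)
    }
    fixed_dirs <- list()
    for (bidx in seq_along(site_lig[[i]]$rows)) {
      row <- site_lig[[i]]$rows[bidx]
      role <- site_lig[[i]]$role[bidx]
      u_b <- unit(as.numeric(atoms[row, c("x", "y", "z")]) - P[i, ])
      fixed_dirs[[length(fixed_dirs) + 1L]] <- u_b
      r <- if (role == "ax") Avec[i] else Evec[i]
      # terminal roughly opposite the bridge; tilted within a 50-degree
      # cone when the exact antipode clashes (the antipodal matching must
      # survive the tilt -- verified at the end of construction)
      base <- -u_b
      best <- base
      best_margin <- margin_of(P[i, ] + r * base)
      for (cand_try in 1:120) {
        if (best_margin >= 0.15) break
        w <- tilt_about(base, stats::runif(1, 0, 50 * pi / 180),
                        stats::rnorm(3))
        m <- margin_of(P[i, ] + r * w)
        if (m > best_margin) {
          best_margin <- m
          best <- w
        }
      }
      if (best_margin < 0) return(NULL)
      ot_count <- ot_count + 1L
      trow <- add_atom(paste0("OT", i, letters[ot_count %% 26 + 1], ot_count),
                       "O", P[i, ] + r * best)
      site_lig[[i]]$rows <- c(site_lig[[i]]$rows, trow)
      site_lig[[i]]$role <- c(site_lig[[i]]$role, role)
    }
    k <- length(fixed_dirs)
    # Filler pairs fill the site to 3 antipodal pairs. Exact orthogonality
    # to the bridge directions is not required (the pairing objective uses
    # within-pair angles only), so directions are chosen by a seeded search
    # that keeps new atoms clear of existing atoms and of the other Mn.
    own_dirs <- fixed_dirs
    pick_filler <- function(r) {
      best <- NULL
      best_margin <- -Inf
      for (cand_try in 1:150) {
        w <- unit(stats::rnorm(3))
        if (length(own_dirs) > 0L) {
          dots <- vapply(own_dirs, function(u) abs(sum(u * w)), numeric(1))
          if (max(dots) > cos(40 * pi / 180)) next
        }
        m <- min(margin_of(P[i, ] + r * w), margin_of(P[i, ] - r * w))
        if (m > best_margin) {
          best_margin <- m
          best <- w
        }
        if (best_margin >= 0.15) break
      }
      if (is.null(best) || best_margin < 0) return(NULL)
      best
    }
    have_axial <- any(site_lig[[i]]$role == "ax")
    n_fillers <- 3L - k
    filler_dirs <- list()
    for (fi in seq_len(n_fillers)) {
      is_ax <- !have_axial && fi == n_fillers
      w <- pick_filler(if (is_ax) Avec[i] else Evec[i])
      if (is.null(w)) return(NULL)
      filler_dirs[[fi]] <- w
      own_dirs[[length(own_dirs) + 1L]] <- w
    }
    for (fidx in seq_along(filler_dirs)) {
      is_ax <- !have_axial && fidx == length(filler_dirs)
      r <- if (is_ax) Avec[i] else Evec[i]
      el <- if (n_ligand_element && i == 1L && !is_ax && fidx == 1L) "N" else "O"
      for (sgn in c(1, -1)) {
        ot_count <- ot_count + 1L
        trow <- add_atom(paste0(substr(el, 1, 1), "F", ot_count), el,
                         P[i, ] + sgn * r * filler_dirs[[fidx]])
        site_lig[[i]]$rows <- c(site_lig[[i]]$rows, trow)
        site_lig[[i]]$role <- c(site_lig[[i]]$role, if (is_ax) "ax" else "eq")
      }
    }
    if (length(site_lig[[i]]$rows) != 6L) return(NULL)
  }
  # calcium capping the Mn1-Mn2-Mn3 face: search candidate offsets along
  # (rotations of) the face normal and keep the least-clashing position
  face_n <- unit(pracma_cross(P[2, ] - P[1, ], P[3, ] - P[1, ]))
  min_d <- function(pos) min(sqrt(rowSums(sweep(as.matrix(atoms[, c("x", "y", "z")]),
                                                2, pos)^2)))
  centroid <- colMeans(P[1:3, ])
  cand <- list()
  for (sgn in c(1, -1)) for (r in c(2.4, 2.8, 3.2, 3.6)) {
    cand[[length(cand) + 1L]] <- centroid + sgn * r * face_n
    for (k in 1:6) {
      tilt <- unit(sgn * face_n + 0.45 * unit(stats::rnorm(3)))
      cand[[length(cand) + 1L]] <- centroid + r * tilt
    }
  }
  scores <- vapply(cand, min_d, numeric(1))
  if (max(scores) < 1.6) return(NULL)
  add_atom("CA", "CA", cand[[which.max(scores)]])
  # --- validation -----------------------------------------------------------
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  all_d <- as.matrix(stats::dist(xyz))
  diag(all_d) <- Inf
  if (min(all_d) < 0.5) return(NULL)
  on_rows <- which(atoms$element %in% c("O", "N"))
  for (i in 1:4) {
    d_on <- all_d[mn_rows[i], on_rows]
    own <- match(site_lig[[i]]$rows, on_rows)
    foreign_min <- if (length(d_on) > length(own)) min(d_on[-own]) else Inf
    if (max(d_on[own]) + 0.02 >= foreign_min) return(NULL)
  }
  # the construction allows tilted antipodes, so confirm that the actual
  # pairing algorithm still recovers the intended axial pair and features
  for (i in 1:4) {
    rows <- site_lig[[i]]$rows
    role <- site_lig[[i]]$role
    lig <- data.frame(
      element = atoms$element[rows],
      x = atoms$x[rows], y = atoms$y[rows], z = atoms$z[rows],
      distance = all_d[mn_rows[i], rows], stringsAsFactors = FALSE
    )
    site <- new_mn_site(mn_coord = P[i, ], ligands = lig)
    f <- compute_features(site)
    rec_ax <- sort(rows[f$pairing[f$axial_pair_index, ]])
    if (!identical(rec_ax, sort(rows[role == "ax"]))) return(NULL)
  }
  sites <- lapply(1:4, function(i) {
    rows <- site_lig[[i]]$rows
    role <- site_lig[[i]]$role
    dists <- all_d[mn_rows[i], rows]
    list(mn_row = mn_rows[i], ligand_rows = rows, role = role,
         E = mean(dists[role == "eq"]), A = mean(dists[role == "ax"]))
  })
  list(atoms = atoms, mn_rows = mn_rows, sites = sites)
}

#' Write a synthetic oxygen-evolving-complex PDB fixture
#'
#' Builds one or two Mn4Ca cluster monomers with mu-oxo-bridged octahedral
#' Mn sites whose per-site mean equatorial/axial bond lengths equal the
#' cluster centers of the requested oxidation labels. Each Mn's six intended
#' ligands are guaranteed to be its six nearest O/N atoms (bridging oxygens
#' are shared between adjacent Mn, as in the real cluster); clashing
#' geometries are regenerated with new orientations up to `max_tries` times.
#'
#' @param path Output PDB path.
#' @param labels Character vector of 4 oxidation labels (Mn1..Mn4), or a
#'   list of such vectors (one per monomer).
#' @param monomers Number of monomers (1 or 2); the second is translated
#'   50 A away on chain B.
#' @param use_names Emit canonical atom names MN1..MN4 (TRUE) or strip them
#'   to bare "MN" (forcing the dangler ordering heuristic downstream).
#' @param distance_jitter Per-site bond-length noise (Angstrom, sd).
#' @param centers Oxidation-class feature centers used as bond lengths.
#' @param dangler_shift Extra outward displacement of Mn4 (Angstrom); beyond
#'   ~0.1 A the Mn3-Mn4 mu-oxo bridge is dropped (the pair separates past
#'   the bridging limit).
#' @param with_ca Include the calcium ion.
#' @param seed Integer seed.
#' @param max_tries Orientation regeneration attempts per monomer.
#' @return (invisibly) ground truth: list with `path` and `monomers`, each
#'   holding `labels`, `s_index`, `total_charge` and a per-site data frame
#'   (`site`, `label`, `E`, `A`, `mn_serial`) recomputed from the rounded
#'   coordinates actually written.
#' @export
gen_oec_file <- function(path, labels = c("III", "IV", "IV", "III"),
                         monomers = 1L, use_names = TRUE,
                         distance_jitter = 0,
                         centers = default_cluster_centers(),
                         dangler_shift = 0, with_ca = TRUE, seed = NULL,
                         max_tries = 60L) {
  if (!is.list(labels)) labels <- rep(list(labels), monomers)
  stopifnot(length(labels) == monomers,
            all(vapply(labels, length, integer(1)) == 4L))
  if (!is.null(seed)) set.seed(seed)
  lines <- character()
  serial <- 0L
  truth <- list()
  for (m in seq_len(monomers)) {
    mono <- NULL
    for (try in seq_len(max_tries)) {
      mono <- build_oec_monomer(labels[[m]], centers,
                                dangler_shift = dangler_shift,
                                distance_jitter = distance_jitter)
      if (!is.null(mono)) break
    }
    if (is.null(mono)) {
      stop("could not generate a clash-free OEC monomer after ",
           max_tries, " attempts")
    }
    atoms <- mono$atoms
    if (!with_ca) atoms <- atoms[atoms$element != "CA", , drop = FALSE]
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    xyz <- xyz %*% t(random_rotation())
    xyz <- sweep(xyz, 2, c(15 + 50 * (m - 1L), 15, 15), `+`)
    xyz <- round(xyz, 3)
    chain <- LETTERS[m]
    serials <- serial + seq_len(nrow(atoms))
    for (r in seq_len(nrow(atoms))) {
      nm <- atoms$name[r]
      if (!use_names && atoms$element[r] == "MN") nm <- "MN"
      lines <- c(lines, pdb_atom_line(
        "HETATM", serials[r], substr(nm, 1, 4), "OEX", chain, 1L,
        xyz[r, ], element = atoms$element[r]
      ))
    }
    site_df <- do.call(rbind, lapply(1:4, function(i) {
      s <- mono$sites[[i]]
      dd <- sqrt(rowSums(sweep(xyz[s$ligand_rows, , drop = FALSE], 2,
                               xyz[s$mn_row, ])^2))
      data.frame(
        site = paste0("Mn", i), label = labels[[m]][i],
        E = mean(dd[s$role == "eq"]), A = mean(dd[s$role == "ax"]),
        mn_serial = serials[s$mn_row], stringsAsFactors = FALSE
      )
    }))
    chg <- sum(oxidation_charge(labels[[m]]))
    truth[[m]] <- list(labels = labels[[m]], total_charge = chg,
                       s_index = chg - 13L, sites = site_df,
                       chain = chain)
    serial <- serial + nrow(atoms)
  }
  writeLines(c(lines, "END"), path)
  invisible(list(path = path, monomers = truth))
}
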