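# Structure reading and Mn-site extraction.

test_that("a minimal single-ATOM PDB parses to one atom", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "END"
  ), p)
  s <- load_structure(p)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$element, "C")
  expect_equal(s$atoms$chain, "A")
  expect_false(s$atoms$het)
})

test_that("parse errors name the offending line; empty structures error", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 MN   MNO A   1      10.000  10.000  10.000  1.00  0.00          MN",
    "HETATM    2  O1  MNO A   1      12.000  10.0xx  10.000  1.00  0.00           O"
  ), p)
  expect_error(load_structure(p), "line 2")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", p2)
  expect_error(load_structure(p2), "no atoms")
  expect_error(load_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("generator files round-trip: distances match stored ground truth", {
  for (seed in 1:5) {
    p <- withr::local_tempfile(fileext = ".pdb")
    gt <- gen_octahedron_file(p, eq = 1.95, ax = 2.26, angular_jitter = 3,
                              distance_jitter = 0.02, seed = seed)
    s <- load_structure(p)
    sites <- find_mn_sites(s, cutoff = 2.9)
    expect_length(sites, 1L)
    expect_equal(sort(sites[[1]]$ligands$distance), sort(gt$distances),
                 tolerance = 1e-9)
  }
})

test_that("find_mn_sites equals a brute-force all-pairs neighbor scan", {
  set.seed(99)
  for (rep in 1:6) {
    n_extra <- 40L
    coords <- matrix(runif(3 * n_extra, 0, 12), ncol = 3)
    elements <- sample(c("O", "N", "C"), n_extra, replace = TRUE)
    mn_pos <- matrix(runif(6, 3, 9), ncol = 3)
    atoms <- data.frame(
      serial = seq_len(n_extra + 2L),
      name = c(paste0("X", seq_len(n_extra)), "MN", "MN"),
      altloc = "", resname = "SYN", chain = "A",
      resseq = 1L,
      element = c(elements, "MN", "MN"),
      x = c(coords[, 1], mn_pos[, 1]),
      y = c(coords[, 2], mn_pos[, 2]),
      z = c(coords[, 3], mn_pos[, 3]),
      occupancy = 1, model = 1L, het = TRUE, stringsAsFactors = FALSE
    )
    s <- structure(list(atoms = atoms, source = "memory", format = "pdb"),
                   class = "mn_structure")
    cutoff <- 4.0
    req <- 4L
    sites <- suppressWarnings(
      find_mn_sites(s, cutoff = cutoff, required_coordination = req)
    )
    # brute force oracle
    for (mi in 1:2) {
      mn <- mn_pos[mi, ]
      d <- sqrt(rowSums(sweep(coords, 2, mn)^2))
      cand <- which(elements %in% c("O", "N") & d <= cutoff)
      expected <- if (length(cand) >= req) {
        sort(atoms$serial[cand[order(d[cand])[seq_len(req)]]])
      } else {
        NULL
      }
      got <- NULL
      for (site in sites) {
        if (site$mn_serial == n_extra + mi) got <- sort(site$ligands$serial)
      }
      expect_equal(got, expected)
    }
    rej <- attr(sites, "rejected")
    expect_true(is.data.frame(rej))
  }
})

test_that("site extraction is rigid-motion invariant", {
  p <- withr::local_tempfile(fileext = ".pdb")
  gen_octahedron_file(p, eq = 1.95, ax = 2.26, angular_jitter = 4, seed = 3)
  s <- load_structure(p)
  R <- random_rotation_matrix()
  shift <- c(5, -3, 8)
  atoms2 <- s$atoms
  xyz <- as.matrix(atoms2[, c("x", "y", "z")]) %*% t(R)
  atoms2$x <- xyz[, 1] + shift[1]
  atoms2$y <- xyz[, 2] + shift[2]
  atoms2$z <- xyz[, 3] + shift[3]
  s2 <- structure(list(atoms = atoms2, source = "memory", format = "pdb"),
                  class = "mn_structure")
  d1 <- sort(find_mn_sites(s)[[1]]$ligands$distance)
  d2 <- sort(find_mn_sites(s2)[[1]]$ligands$distance)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("cutoff excludes distant atoms; undercoordinated Mn are reported", {
  p <- withr::local_tempfile(fileext = ".pdb")
  gt <- gen_octahedron_file(p, eq = 2.0, ax = 2.0, seed = 1, rotate = FALSE)
  # append a 7th O at 3.5 A from Mn
  lines <- readLines(p)
  extra <- mnoxstate:::pdb_atom_line("HETATM", 8L, "O7", "MNO", "A", 1L,
                                     gt$mn_coord + c(3.5, 0, 0),
                                     element = "O")
  writeLines(c(lines[lines != "END"], extra, "END"), p)
  s <- load_structure(p)
  sites <- find_mn_sites(s, cutoff = 2.6)
  expect_length(sites, 1L)
  expect_equal(nrow(sites[[1]]$ligands), 6L)
  expect_false(8L %in% sites[[1]]$ligands$serial)
  # tighter cutoff: too few neighbors -> rejected, with count
  expect_warning(sites2 <- find_mn_sites(s, cutoff = 1.5), "below required")
  expect_length(sites2, 0L)
  rej <- attr(sites2, "rejected")
  expect_equal(rej$n_neighbors, 0L)
  # no Mn at all
  atoms <- s$atoms[s$atoms$element != "MN", ]
  s3 <- structure(list(atoms = atoms, source = "memory", format = "pdb"),
                  class = "mn_structure")
  expect_warning(find_mn_sites(s3), "no Mn")
})

test_that("alternate locations resolve to highest occupancy, ties by altloc", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 MN  AMNO A   1      10.000  10.000  10.000  0.40  0.00          MN",
    "HETATM    2 MN  BMNO A   1      20.000  20.000  20.000  0.60  0.00          MN",
    "HETATM    3  O1 AMNO A   2       1.000   0.000   0.000  0.50  0.00           O",
    "HETATM    4  O1 BMNO A   2       2.000   0.000   0.000  0.50  0.00           O",
    "END"
  ), p)
  s <- load_structure(p)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$element == "MN"], 20.0)   # occ 0.6 wins
  expect_equal(s$atoms$x[s$atoms$element == "O"], 1.0)     # tie: altloc A
})

test_that("element symbols derive from atom names per PDB convention", {
  # metals are left-justified in the name field; " CA " is an alpha carbon
  expect_equal(mnoxstate:::element_from_name(c("MN  ", " CA ", " O1 ",
                                               "FE2 ", " NE2")),
               c("MN", "C", "O", "FE", "N"))
})

test_that("mmCIF atom_site loops parse and agree with the PDB reader", {
  p <- withr::local_tempfile(fileext = ".pdb")
  gt <- gen_octahedron_file(p, eq = 1.95, ax = 2.26, seed = 11)
  s_pdb <- load_structure(p)
  cif <- withr::local_tempfile(fileext = ".cif")
  a <- s_pdb$atoms
  writeLines(c(
    "data_synthetic",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.auth_atom_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    sprintf("HETATM %d %s %s %s %s %d %.3f %.3f %.3f 1.00",
            a$serial, a$element, a$name, a$resname, a$chain, a$resseq,
            a$x, a$y, a$z),
    "#"
  ), cif)
  s_cif <- load_structure(cif)
  expect_equal(s_cif$atoms$x, s_pdb$atoms$x)
  f_pdb <- compute_features(find_mn_sites(s_pdb)[[1]])
  f_cif <- compute_features(find_mn_sites(s_cif)[[1]])
  expect_equal(c(f_cif$E, f_cif$A), c(f_pdb$E, f_pdb$A), tolerance = 1e-12)
})
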