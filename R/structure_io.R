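# Coordinate-file input: minimal PDB / mmCIF atom readers and Mn-site
# extraction. Only the atom records are parsed; no symmetry expansion,
# assemblies or hydrogens.

TWO_LETTER_ELEMENTS <- c(
  "MN", "FE", "CA", "MG", "ZN", "NA", "CL", "BR", "NI", "CU", "CO",
  "CD", "MO", "SE", "HG", "PB", "SR", "CS", "RB", "BA", "LI", "AL"
)

#' Load an atomic structure from a PDB or mmCIF file
#'
#' Reads all `ATOM`/`HETATM` records (all models, all chains, heteroatoms
#' included) into a flat atom table. Alternate locations are resolved to the
#' highest-occupancy conformer; ties are broken by altloc identifier order.
#' Element symbols are normalized to uppercase; when the element column is
#' absent they are derived from the atom name following PDB naming
#' conventions (metals left-justified in the name field).
#'
#' @param path Path to a coordinate file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. With `"auto"` the
#'   format is taken from the file extension, falling back to content
#'   sniffing (`_atom_site.` loop implies mmCIF).
#' @return An object of class `mn_structure`: a list with elements `atoms`
#'   (data frame with columns `serial`, `name`, `altloc`, `resname`,
#'   `chain`, `resseq`, `element`, `x`, `y`, `z`, `occupancy`, `model`,
#'   `het`), `source` and `format`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' gen_octahedron_file(pdb, eq = 1.95, ax = 2.26, seed = 1)
#' s <- load_structure(pdb)
#' nrow(s$atoms)
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    lowered <- tolower(path)
    format <- if (grepl("\\.(cif|mmcif)$", lowered)) {
      "mmcif"
    } else if (grepl("\\.(pdb|ent)$", lowered)) {
      "pdb"
    } else {
      head_lines <- readLines(path, n = 200L, warn = FALSE)
      if (any(grepl("^_atom_site\\.", head_lines))) "mmcif" else "pdb"
    }
  }
  atoms <- switch(format,
    pdb = parse_pdb_atoms(path),
    mmcif = parse_mmcif_atoms(path)
  )
  if (nrow(atoms) == 0L) {
    stop("no atoms found in ", path, " (parsed as ", format, ")")
  }
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    stop("non-finite coordinates at atom serial(s) ",
         paste(atoms$serial[bad], collapse = ", "), " in ", path)
  }
  atoms <- resolve_altloc(atoms)
  structure(
    list(atoms = atoms, source = path, format = format),
    class = "mn_structure"
  )
}

#' @export
print.mn_structure <- function(x, ...) {
  cat("<mn_structure> ", nrow(x$atoms), " atoms from ", x$source,
      " [", x$format, "]\n", sep = "")
  cat("  chains: ", paste(unique(x$atoms$chain), collapse = " "),
      "; Mn atoms: ", sum(x$atoms$element == "MN"), "\n", sep = "")
  invisible(x)
}

parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(keep)
  model_no <- cumsum(grepl("^MODEL ", lines))
  model_no[model_no == 0L] <- 1L
  recs <- lines[idx]
  if (length(recs) == 0L) {
    return(empty_atom_table())
  }
  field <- function(from, to) substr(recs, from, to)
  num_field <- function(from, to, what) {
    raw <- field(from, to)
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & nzchar(trimws(raw))
    if (any(bad)) {
      stop("PDB parse error at line ", idx[which(bad)[1]],
           ": bad ", what, " field '", raw[which(bad)[1]], "'")
    }
    val
  }
  name <- field(13, 16)
  element <- toupper(trimws(field(77, 78)))
  missing_el <- !nzchar(element)
  if (any(missing_el)) {
    element[missing_el] <- element_from_name(name[missing_el])
  }
  occ <- num_field(55, 60, "occupancy")
  occ[is.na(occ)] <- 1.0
  data.frame(
    serial = as.integer(num_field(7, 11, "serial")),
    name = trimws(name),
    altloc = trimws(field(17, 17)),
    resname = trimws(field(18, 20)),
    chain = trimws(field(22, 22)),
    resseq = suppressWarnings(as.integer(trimws(field(23, 26)))),
    element = element,
    x = num_field(31, 38, "x coordinate"),
    y = num_field(39, 46, "y coordinate"),
    z = num_field(47, 54, "z coordinate"),
    occupancy = occ,
    model = as.integer(model_no[idx]),
    het = field(1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
}

empty_atom_table <- function() {
  data.frame(
    serial = integer(), name = character(), altloc = character(),
    resname = character(), chain = character(), resseq = integer(),
    element = character(), x = double(), y = double(), z = double(),
    occupancy = double(), model = integer(), het = logical(),
    stringsAsFactors = FALSE
  )
}

# Derive the element symbol from a raw 4-character PDB atom-name field.
# Metals occupy columns 13-14 (e.g. "MN  "); organic atoms are indented
# (" CA " is an alpha carbon, not calcium).
element_from_name <- function(raw_name) {
  vapply(raw_name, function(nm) {
    padded <- formatC(nm, width = 4, flag = "-")
    two <- toupper(gsub("[^A-Za-z]", "", substr(padded, 1, 2)))
    if (substr(padded, 1, 1) != " " && two %in% TWO_LETTER_ELEMENTS) {
      return(two)
    }
    first <- regmatches(nm, regexpr("[A-Za-z]", nm))
    if (length(first) == 0L) "X" else toupper(first)
  }, character(1), USE.NAMES = FALSE)
}

# Tokenize one mmCIF data line, honouring single/double quotes.
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0L) {
    stop("mmCIF parse error: no _atom_site loop in ", path)
  }
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1L
  rows <- list()
  i <- body_start
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "" || grepl("^(#|loop_|_|data_)", line)) break
    toks <- cif_tokens(line)
    if (length(toks) != length(tags)) {
      stop("mmCIF parse error at line ", i, ": expected ", length(tags),
           " fields, got ", length(toks))
    }
    rows[[length(rows) + 1L]] <- toks
    i <- i + 1L
  }
  if (length(rows) == 0L) {
    return(empty_atom_table())
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- tags
  col <- function(primary, fallback = NULL, default = NA_character_) {
    if (primary %in% tags) return(mat[, primary])
    if (!is.null(fallback) && fallback %in% tags) return(mat[, fallback])
    rep(default, nrow(mat))
  }
  need <- c("Cartn_x", "Cartn_y", "Cartn_z")
  missing_need <- setdiff(need, tags)
  if (length(missing_need) > 0L) {
    stop("mmCIF parse error: _atom_site loop lacks ",
         paste(missing_need, collapse = ", "))
  }
  dot_na <- function(v) ifelse(v %in% c(".", "?"), NA_character_, v)
  element <- toupper(trimws(dot_na(col("type_symbol"))))
  name <- dot_na(col("auth_atom_id", "label_atom_id"))
  missing_el <- is.na(element) | !nzchar(element)
  if (any(missing_el)) {
    element[missing_el] <- element_from_name(name[missing_el])
  }
  occ <- suppressWarnings(as.numeric(dot_na(col("occupancy"))))
  occ[is.na(occ)] <- 1.0
  altloc <- dot_na(col("label_alt_id"))
  altloc[is.na(altloc)] <- ""
  serial <- suppressWarnings(as.integer(dot_na(col("id"))))
  if (anyNA(serial)) serial <- seq_len(nrow(mat))
  data.frame(
    serial = serial,
    name = name,
    altloc = altloc,
    resname = dot_na(col("auth_comp_id", "label_comp_id")),
    chain = dot_na(col("auth_asym_id", "label_asym_id")),
    resseq = suppressWarnings(as.integer(dot_na(col("auth_seq_id", "label_seq_id")))),
    element = element,
    x = as.numeric(mat[, "Cartn_x"]),
    y = as.numeric(mat[, "Cartn_y"]),
    z = as.numeric(mat[, "Cartn_z"]),
    occupancy = occ,
    model = {
      mdl <- suppressWarnings(as.integer(dot_na(col("pdbx_PDB_model_num"))))
      mdl[is.na(mdl)] <- 1L
      mdl
    },
    het = col("group_PDB", default = "ATOM") == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Keep the highest-occupancy alternate location per atom; ties broken by
# altloc identifier order ("A" before "B").
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$model, atoms$chain, atoms$resseq, atoms$resname,
               atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep <- !duplicated(key[ord])
  out <- atoms[ord[keep], , drop = FALSE]
  out[order(out$model, out$serial), , drop = FALSE]
}

#' Locate Mn centers and their coordinating ligands
#'
#' Scans a structure for manganese atoms and collects, for each one, its
#' neighbouring O/N atoms within a distance cutoff. Sites with at least
#' `required_coordination` candidate ligands keep the nearest
#' `required_coordination`; Mn atoms failing the requirement are reported in
#' the `"rejected"` attribute (with their actual neighbour counts) rather
#' than silently dropped.
#'
#' @param s An `mn_structure`.
#' @param cutoff Ligand distance cutoff in Angstrom. The 2.9 A default
#'   admits long Mn(II)-O and Jahn-Teller-elongated axial bonds while
#'   excluding second-shell atoms.
#' @param allowed_elements Element symbols accepted as ligands.
#' @param required_coordination Number of ligands a site must have
#'   (6 = octahedral, the classifier requirement).
#' @return A list of `mn_site` objects, each with `mn_coord`, a `ligands`
#'   data frame (`element`, `x`, `y`, `z`, `distance`, `name`, `resname`,
#'   `resseq`, `chain`, `serial`), `chain_id`, `monomer_id`, `site_label`
#'   and `mn_serial`. Attribute `"rejected"` holds a data frame of
#'   under-coordinated Mn.
#' @export
find_mn_sites <- function(s, cutoff = 2.9, allowed_elements = c("O", "N"),
                          required_coordination = 6L) {
  stopifnot(inherits(s, "mn_structure"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (required_coordination < 4L) stop("required_coordination must be >= 4")
  atoms <- s$atoms
  mn_idx <- which(atoms$element == "MN")
  rejected <- data.frame(
    mn_serial = integer(), chain = character(), resseq = integer(),
    n_neighbors = integer(), stringsAsFactors = FALSE
  )
  if (length(mn_idx) == 0L) {
    warning("no Mn atoms found in ", s$source)
    out <- list()
    attr(out, "rejected") <- rejected
    return(out)
  }
  lig_pool <- which(atoms$element %in% toupper(allowed_elements))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  sites <- list()
  for (i in mn_idx) {
    pool <- lig_pool[atoms$model[lig_pool] == atoms$model[i]]
    d <- sqrt(colSums((t(coords[pool, , drop = FALSE]) - coords[i, ])^2))
    within <- d > 0 & d <= cutoff
    if (sum(within) < required_coordination) {
      rejected <- rbind(rejected, data.frame(
        mn_serial = atoms$serial[i], chain = atoms$chain[i],
        resseq = atoms$resseq[i], n_neighbors = sum(within),
        stringsAsFactors = FALSE
      ))
      next
    }
    sel <- pool[within][order(d[within])[seq_len(required_coordination)]]
    lig <- data.frame(
      element = atoms$element[sel],
      x = atoms$x[sel], y = atoms$y[sel], z = atoms$z[sel],
      distance = sort(d[within])[seq_len(required_coordination)],
      name = atoms$name[sel], resname = atoms$resname[sel],
      resseq = atoms$resseq[sel], chain = atoms$chain[sel],
      serial = atoms$serial[sel],
      stringsAsFactors = FALSE
    )
    label <- if (grepl("^MN[0-9]$", atoms$name[i])) atoms$name[i] else NA_character_
    sites[[length(sites) + 1L]] <- new_mn_site(
      mn_coord = coords[i, ],
      ligands = lig,
      chain_id = atoms$chain[i],
      monomer_id = NA_integer_,
      site_label = label,
      mn_serial = atoms$serial[i]
    )
  }
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " Mn site(s) below required coordination (",
            paste0(rejected$mn_serial, ":", rejected$n_neighbors,
                   collapse = ", "), ")")
  }
  attr(sites, "rejected") <- rejected
  sites
}

new_mn_site <- function(mn_coord, ligands, chain_id = NA_character_,
                        monomer_id = NA_integer_, site_label = NA_character_,
                        mn_serial = NA_integer_) {
  stopifnot(length(mn_coord) == 3, all(is.finite(mn_coord)))
  dd <- sqrt((ligands$x - mn_coord[1])^2 + (ligands$y - mn_coord[2])^2 +
             (ligands$z - mn_coord[3])^2)
  if (any(abs(dd - ligands$distance) > 1e-9)) {
    stop("ligand distances inconsistent with coordinates")
  }
  structure(
    list(mn_coord = as.numeric(mn_coord), ligands = ligands,
         chain_id = chain_id, monomer_id = monomer_id,
         site_label = site_label, mn_serial = mn_serial),
    class = "mn_site"
  )
}

#' @export
print.mn_site <- function(x, ...) {
  cat("<mn_site> Mn", if (!is.na(x$site_label)) paste0(" [", x$site_label, "]"),
      " chain ", x$chain_id, ", ", nrow(x$ligands), " ligands (",
      paste(x$ligands$element, collapse = ""), "), d = ",
      paste(sprintf("%.2f", x$ligands$distance), collapse = "/"), " A\n",
      sep = "")
  invisible(x)
}
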