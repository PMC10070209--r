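# Shared fixture builders. Sites are constructed in code (no stored binary
# fixtures); helpers intentionally use simple, independent arithmetic so
# they can serve as oracles for the package's own geometry.

# An mn_site with ligands on the canonical octahedral axes (+x,-x,+y,-y,
# +z,-z) at the given 6 distances, optionally rotated by matrix R.
make_site <- function(distances, R = diag(3), mn = c(0, 0, 0),
                      elements = rep("O", 6)) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  coords <- sweep((dirs * distances) %*% t(R), 2, mn, `+`)
  lig <- data.frame(
    element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    distance = distances,
    name = paste0(elements, 1:6), resname = "LIG", resseq = 1L,
    chain = "A", serial = 2:7, stringsAsFactors = FALSE
  )
  mnoxstate:::new_mn_site(mn_coord = mn, ligands = lig, chain_id = "A",
                          mn_serial = 1L)
}

# A site from arbitrary ligand direction matrix (rows normalized) and
# distances.
make_site_dirs <- function(dirs, distances, mn = c(0, 0, 0)) {
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coords <- sweep(dirs * distances, 2, mn, `+`)
  lig <- data.frame(
    element = rep("O", nrow(dirs)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    distance = distances,
    name = paste0("O", seq_len(nrow(dirs))), resname = "LIG", resseq = 1L,
    chain = "A", serial = seq_len(nrow(dirs)) + 1L, stringsAsFactors = FALSE
  )
  mnoxstate:::new_mn_site(mn_coord = mn, ligands = lig, chain_id = "A",
                          mn_serial = 1L)
}

random_rotation_matrix <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Independent enumeration of the 15 perfect matchings of 6 items, written
# differently from the package's recursion (pattern table via combn).
all_matchings_6 <- function() {
  out <- list()
  for (p1 in 2:6) {
    rest1 <- setdiff(2:6, p1)
    for (p2 in rest1[-1]) {
      pair2 <- c(rest1[1], p2)
      pair3 <- setdiff(rest1, pair2)
      out[[length(out) + 1L]] <- rbind(c(1, p1), pair2, pair3)
    }
  }
  out
}

angle_deg <- function(a, b) {
  acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# A quick well-separated training table + decision-tree model for pipeline
# tests (cached per session).
fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- gen_feature_table(counts = c(II = 300, III = 250, IV = 90),
                               mislabel_rate = 0.08, seed = 424L)
      rl <- kmeans_relabel(tab, seed = 424L)
      cache <<- list(model = fit_dt(rl$table), clusters = rl$model,
                     table = rl$table)
    }
    cache
  }
})
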