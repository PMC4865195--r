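# Shared fixture builders and independent oracles. PDBQT text here is
# hand-formatted, independent of the package's writer, so parser tests do
# not go through the code they check.

hand_atom <- function(serial, x, y, z, type, charge = 0, name = "X") {
  sprintf("ATOM  %5d %-4s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          serial, name, "LIG", "A", 1L, x, y, z, 1, 0, charge, type)
}

one_atom_ligand <- function(x, y, z, type = "A") {
  c("ROOT", hand_atom(1, x, y, z, type), "ENDROOT", "TORSDOF 0")
}

one_atom_receptor <- function(x = 0, y = 0, z = 0, type = "A") {
  parse_pdbqt(hand_atom(1, x, y, z, type), role = "receptor")
}

# atom records sufficient for pair_energy
atom_rec <- function(radius_class, class) {
  data.frame(radius_class = radius_class, class = class, is_heavy = TRUE,
             stringsAsFactors = FALSE)
}

# random multi-atom receptor/ligand pair for brute-force energy oracles
random_complex <- function(seed, n_rec = 8, n_lig = 3, spread = 6) {
  set.seed(seed)
  types <- c("C", "A", "N", "NA", "OA", "S")
  rec_lines <- vapply(seq_len(n_rec), function(i) {
    p <- stats::runif(3, -spread, spread)
    hand_atom(i, p[1], p[2], p[3], sample(types, 1))
  }, "")
  lig_lines <- c("ROOT", vapply(seq_len(n_lig), function(i) {
    p <- stats::runif(3, -2, 2)
    hand_atom(i, p[1], p[2], p[3], sample(types, 1))
  }, ""), "ENDROOT", "TORSDOF 0")
  list(receptor = parse_pdbqt(rec_lines, role = "receptor"),
       ligand = parse_pdbqt(lig_lines, role = "ligand"))
}

# brute-force intermolecular sum via pair_energy (independent of the
# spatial index and of raw_term_values vectorization over pairs)
brute_force_inter <- function(ligand, receptor, params) {
  total <- 0
  for (i in which(ligand$atoms$is_heavy)) {
    for (j in which(receptor$atoms$is_heavy)) {
      r <- sqrt(sum((ligand$xyz[i, ] - receptor$xyz[j, ])^2))
      d <- r - params$radii[[ligand$atoms$radius_class[i]]] -
        params$radii[[receptor$atoms$radius_class[j]]]
      if (d < params$cutoff) {
        total <- total + pair_energy(ligand$atoms[i, ], receptor$atoms[j, ],
                                     r, params)
      }
    }
  }
  total
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exhaustive symmetry-corrected RMSD: minimum over the Cartesian product of
# within-type-block permutations (blocks keyed like the implementation)
brute_force_rmsd <- function(ref_xyz, probe_xyz, keys) {
  blocks <- split(seq_along(keys), keys)
  block_perms <- lapply(blocks, function(ix) all_permutations(length(ix)))
  best <- Inf
  combo <- function(bi, ss) {
    if (bi > length(blocks)) {
      best <<- min(best, ss)
      return(invisible())
    }
    ix <- blocks[[bi]]
    for (p in block_perms[[bi]]) {
      add <- sum((ref_xyz[ix, , drop = FALSE] -
                    probe_xyz[ix[p], , drop = FALSE])^2)
      combo(bi + 1L, ss + add)
    }
  }
  combo(1L, 0)
  sqrt(best / length(keys))
}

# breadth-first bond-graph distances, independent of the package internals
bfs_bond_dist <- function(n, bonds, src) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds[k, 1]]] <- c(adj[[bonds[k, 1]]], bonds[k, 2])
    adj[[bonds[k, 2]]] <- c(adj[[bonds[k, 2]]], bonds[k, 1])
  }
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# single-pair training complexes: one receptor atom at the origin, one
# ligand atom at exact contact along +x (aromatic carbon: r = 3.8 under
# both presets)
contact_complex <- function(type = "A", params = scoring_params("vinardo")) {
  el <- dockscore:::ad_type_element(type)
  rad <- params$radii[[dockscore:::radius_class(type, el)]]
  list(receptor = one_atom_receptor(0, 0, 0, type),
       ligand = parse_pdbqt(one_atom_ligand(2 * rad, 0, 0, type),
                            role = "ligand"),
       contact = 2 * rad)
}
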