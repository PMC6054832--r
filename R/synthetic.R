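# Synthetic fixtures: toy PDB complexes with prescribed ligand-anchor
# distances and pharmacophore roles, and alignments with planted
# pharmacological neighbors. Both return machine-checkable ground truth
# so downstream modules can be tested end-to-end without downloads.

#' Specification of a toy protein-ligand complex
#'
#' Residues are placed on a 25 Angstrom grid along x (far outside the
#' contact cutoff of each other); each ligand atom is placed at a
#' prescribed distance from one named anchor atom, isolated from every
#' other protein atom, so expected contact weights follow analytically
#' from the prescribed distances.
#'
#' @param residues list of lists `list(name =, atoms = data.frame(name,
#'   element, dx, dy, dz))`; `dx/dy/dz` are offsets from the residue
#'   base position. Defaults give single-oxygen "GLY" probes.
#' @param ligand data.frame with columns `name`, `element`,
#'   `anchor_res` (residue index), `anchor_atom`, `distance` (Angstrom),
#'   `role` (one of `"donor"`, `"acceptor"`, `"cation"`, `"anion"`,
#'   `"none"`; informational, used for expected fingerprint bits).
#' @param chain chain identifier.
#' @param n_waters number of decoy water molecules to add.
#' @param seed RNG seed for atom placement.
#' @return list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(residues, ligand, chain = "A", n_waters = 0,
                             seed = 1) {
  stopifnot(all(ligand$distance >= 1.0))
  if (any(abs(ligand$distance - round(ligand$distance, 3)) > 1e-9)) {
    stop("prescribed distances must be given to at most 3 decimals (PDB precision)")
  }
  stopifnot(all(ligand$anchor_res >= 1), all(ligand$anchor_res <= length(residues)))
  structure(list(residues = residues, ligand = ligand, chain = chain,
                 n_waters = n_waters, seed = seed),
            class = "toy_complex_spec")
}

pdb_atom_line <- function(record, serial, name, resname, chain, resnum,
                          x, y, z, element, occ = 1.00) {
  sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, substr(name, 1, 4), resname, chain, resnum,
          x, y, z, occ, 0, element)
}

# random axis-aligned unit vector: keeps PDB coordinates (3 decimals)
# exactly representable, so prescribed distances survive the round-trip
# and analytic expectations hold to numerical precision
runit <- function() {
  v <- c(0, 0, 0)
  v[sample(3, 1)] <- sample(c(-1, 1), 1)
  v
}

#' Build a toy complex PDB with analytically known expected outputs
#'
#' Writes a parseable PDB (optionally with decoy waters) and returns the
#' expected per-residue contact weights implied by the prescribed
#' anchor distances and the contact ramp, plus the expected interaction
#' bits implied by the prescribed roles and the default geometric
#' criteria. Ligand atoms are rejection-sampled until every non-anchor
#' protein atom lies beyond the contact cutoff, so the analytic
#' expectations are exact.
#'
#' @param spec a [toy_complex_spec()].
#' @param path output PDB path (default: temp file).
#' @return list with `path`, `pdb` (text lines), `expected_contacts`
#'   (numeric, per residue index: sum of ramp values of its anchored
#'   ligand atoms), `expected_bits` (data.frame `residue`, `type`),
#'   `chain`.
#' @export
make_toy_complex <- function(spec, path = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  set.seed(spec$seed)
  res_base <- cbind(25 * (seq_along(spec$residues) - 1), 0, 0)
  prot <- do.call(rbind, lapply(seq_along(spec$residues), function(i) {
    at <- spec$residues[[i]]$atoms
    data.frame(res = i, resname = spec$residues[[i]]$name,
               name = at$name, element = at$element,
               x = res_base[i, 1] + at$dx, y = res_base[i, 2] + at$dy,
               z = res_base[i, 3] + at$dz, stringsAsFactors = FALSE)
  }))
  lig <- spec$ligand
  lig_xyz <- matrix(NA_real_, nrow(lig), 3)
  margin <- 0.15
  for (k in seq_len(nrow(lig))) {
    anchor <- prot[prot$res == lig$anchor_res[k] & prot$name == lig$anchor_atom[k], ]
    if (nrow(anchor) != 1) stop("anchor atom not found for ligand atom ", lig$name[k])
    a <- c(anchor$x, anchor$y, anchor$z)
    placed <- FALSE
    for (try in 1:2000) {
      p <- a + lig$distance[k] * runit()
      other <- prot[!(prot$res == lig$anchor_res[k] & prot$name == lig$anchor_atom[k]), ]
      ok <- TRUE
      if (nrow(other)) {
        dd <- sqrt((other$x - p[1])^2 + (other$y - p[2])^2 + (other$z - p[3])^2)
        ok <- all(dd > CONTACT_CUTOFF + margin)
      }
      # keep ligand atoms apart so each is untyped by connectivity unless intended
      if (ok && k > 1) {
        prev <- lig_xyz[seq_len(k - 1), , drop = FALSE]
        ok <- all(sqrt(rowSums(t(t(prev) - p)^2)) > 2.2)
      }
      if (ok) { lig_xyz[k, ] <- p; placed <- TRUE; break }
    }
    if (!placed) stop("unrealizable geometry for ligand atom ", lig$name[k])
  }

  lines <- character(0); serial <- 0
  for (r in seq_len(nrow(prot))) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line("ATOM", serial, prot$name[r], prot$resname[r],
                                    spec$chain, prot$res[r],
                                    prot$x[r], prot$y[r], prot$z[r], prot$element[r]))
  }
  lines <- c(lines, "TER")
  lig_resnum <- length(spec$residues) + 100
  for (k in seq_len(nrow(lig))) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line("HETATM", serial, lig$name[k], "LIG",
                                    spec$chain, lig_resnum,
                                    lig_xyz[k, 1], lig_xyz[k, 2], lig_xyz[k, 3],
                                    lig$element[k]))
  }
  if (spec$n_waters > 0) {
    for (w in seq_len(spec$n_waters)) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line("HETATM", serial, "O", "HOH", spec$chain,
                                      lig_resnum + w, 60 + 10 * w, 50, 50, "O"))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)

  expected_contacts <- vapply(seq_along(spec$residues), function(i) {
    sum(contact_strength(lig$distance[lig$anchor_res == i]))
  }, 0)
  cfg <- plif_config()
  bits <- list()
  for (k in seq_len(nrow(lig))) {
    r <- lig$anchor_res[k]; dd <- lig$distance[k]
    role <- lig$role[k]
    anchor_tpl <- protein_atom_roles(
      spec$residues[[r]]$name,
      spec$residues[[r]]$atoms$name[spec$residues[[r]]$atoms$name == lig$anchor_atom[k]][1]
    )
    if (role == "donor" && anchor_tpl["acceptor"] && dd <= cfg$hb_dist) {
      bits[[length(bits) + 1]] <- data.frame(residue = r, type = "HBD")
    } else if (role == "acceptor" && anchor_tpl["donor"] && dd <= cfg$hb_dist) {
      bits[[length(bits) + 1]] <- data.frame(residue = r, type = "HBA")
    } else if (role == "cation" && anchor_tpl["anion"] && dd <= cfg$ionic_dist) {
      bits[[length(bits) + 1]] <- data.frame(residue = r, type = "IONIC")
    } else if (role == "anion" && anchor_tpl["cation"] && dd <= cfg$ionic_dist) {
      bits[[length(bits) + 1]] <- data.frame(residue = r, type = "IONIC")
    } else if (dd <= cfg$surface_dist) {
      bits[[length(bits) + 1]] <- data.frame(residue = r, type = "SURFACE")
    }
  }
  expected_bits <- if (length(bits)) {
    unique(do.call(rbind, bits))
  } else {
    data.frame(residue = integer(0), type = character(0))
  }
  list(path = path, pdb = lines, expected_contacts = expected_contacts,
       expected_bits = expected_bits, chain = spec$chain)
}

# donor/acceptor/cation/anion flags of one protein atom per the template
# + backbone rules (mirrors annotate_pharmacophores for a single atom)
protein_atom_roles <- function(resname, atom) {
  out <- c(donor = FALSE, acceptor = FALSE, cation = FALSE, anion = FALSE)
  if (is.na(atom)) return(out)
  if (atom == "N" && resname != "PRO") out["donor"] <- TRUE
  if (atom %in% c("O", "OXT")) out["acceptor"] <- TRUE
  if (atom == "OXT") out["anion"] <- TRUE
  tpl <- residue_templates()
  hit <- tpl[tpl$resname == resname & tpl$atom == atom, ]
  if (nrow(hit)) {
    out["donor"] <- out["donor"] || hit$donor[1] == 1
    out["acceptor"] <- out["acceptor"] || hit$acceptor[1] == 1
    out["cation"] <- hit$cation[1] == 1
    out["anion"] <- out["anion"] || hit$anion[1] == 1
  }
  out
}

#' Generate an alignment with planted pharmacological neighbors
#'
#' Each planted pair shares identical residues at the designated site
#' columns; away from the site columns, the second member of a pair is a
#' copy of the first mutated per column with probability `background_rate`
#' (uniform replacement). Sequences not in any pair are uniform random
#' throughout. With conservation concentrated at contact columns this
#' emulates the statistical structure that profile-weighted comparison
#' exploits.
#'
#' @param n_sequences total sequences (named `S1..Sn`).
#' @param length alignment length (no gaps are generated).
#' @param neighbor_pairs list of integer pairs (1-based sequence
#'   indices), disjoint.
#' @param site_columns integer columns carrying profile weight.
#' @param background_rate per-column substitution probability in `[0,1]`
#'   off the site columns.
#' @param seed RNG seed.
#' @return list with `alignment` (a `master_alignment`), `truth`
#'   (data.frame `a`, `b` of planted partner names), `site_columns`.
#' @export
make_planted_alignment <- function(n_sequences, length, neighbor_pairs,
                                   site_columns, background_rate = 0.8,
                                   seed = 1) {
  if (n_sequences < 2) stop("need at least 2 sequences")
  stopifnot(all(unlist(neighbor_pairs) <= n_sequences),
            all(site_columns >= 1), all(site_columns <= length),
            background_rate >= 0, background_rate <= 1)
  paired <- unlist(neighbor_pairs)
  if (anyDuplicated(paired)) stop("neighbor pairs must be disjoint")
  set.seed(seed)
  rows <- matrix(sample(AA_LETTERS, n_sequences * length, replace = TRUE),
                 nrow = n_sequences)
  for (pr in neighbor_pairs) {
    i <- pr[1]; j <- pr[2]
    rows[j, ] <- rows[i, ]
    off <- setdiff(seq_len(length), site_columns)
    mut <- off[stats::runif(base::length(off)) < background_rate]
    rows[j, mut] <- sample(AA_LETTERS, base::length(mut), replace = TRUE)
  }
  names <- paste0("S", seq_len(n_sequences))
  truth <- if (base::length(neighbor_pairs)) {
    data.frame(a = names[vapply(neighbor_pairs, function(p) as.integer(p[1]), 0L)],
               b = names[vapply(neighbor_pairs, function(p) as.integer(p[2]), 0L)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0))
  }
  list(alignment = new_master_alignment(names, apply(rows, 1, paste, collapse = "")),
       truth = truth, site_columns = sort(site_columns))
}

#' Write a master alignment as aligned FASTA
#' @param aln a `master_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  out <- character(2 * base::length(aln$names))
  out[c(TRUE, FALSE)] <- paste0(">", aln$names)
  out[c(FALSE, TRUE)] <- aln$rows
  writeLines(out, path)
  invisible(path)
}
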