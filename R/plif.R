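# Protein-ligand interaction fingerprints: pharmacophore typing by
# template (protein) and element/connectivity rules (ligand), geometric
# interaction detection, Tanimoto comparison and summaries.

INTERACTION_TYPES <- c("HBD", "HBA", "IONIC", "SURFACE", "ARENE")

residue_templates <- function() {
  if (is.null(.pocketmap_env$templates)) {
    .pocketmap_env$templates <-
      read.delim(pm_extdata("residue_templates.tsv"), stringsAsFactors = FALSE)
  }
  .pocketmap_env$templates
}

#' Default geometric criteria for interaction detection
#'
#' All distances in Angstrom, angles in degrees. The hydrogen-bond angle
#' is a heavy-atom proxy (acceptor--donor--donor-antecedent); donors with
#' no bonded heavy neighbour pass the angle test by convention.
#'
#' @param hb_dist donor-heavy to acceptor-heavy distance cutoff.
#' @param hb_angle minimum acceptor-donor-antecedent angle.
#' @param ionic_dist cation-anion heavy-atom distance cutoff.
#' @param arene_dist ring-centroid to ring-centroid distance cutoff.
#' @param surface_dist cutoff for unclassified heavy-atom contacts.
#' @return named list of criteria.
#' @export
plif_config <- function(hb_dist = 3.5, hb_angle = 100,
                        ionic_dist = 4.0, arene_dist = 4.5,
                        surface_dist = 4.5) {
  list(hb_dist = hb_dist, hb_angle = hb_angle, ionic_dist = ionic_dist,
       arene_dist = arene_dist, surface_dist = surface_dist)
}

# bonds among one molecule's heavy atoms: distance <= 1.9 A
# (2.0 A when sulfur or phosphorus is involved); returns adjacency list
infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  adj <- vector("list", n)
  if (n < 2) return(adj)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  big <- atoms$element %in% c("S", "P")
  cut <- matrix(1.9, n, n)
  cut[big, ] <- 2.0
  cut[, big] <- 2.0
  bonded <- d > 0.4 & d <= cut
  for (i in seq_len(n)) adj[[i]] <- which(bonded[i, ])
  adj
}

# 5-6 membered cycles in an adjacency list; returns list of atom index sets
find_rings <- function(adj, elements) {
  ok <- elements %in% c("C", "N", "O", "S")
  rings <- list()
  seen <- character(0)
  n <- length(adj)
  # DFS paths from each start atom; cycle closes when a neighbour is start
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (!ok[nb]) next
      if (nb == path[1] && length(path) >= 5) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1]] <<- sort(path)
        }
      } else if (!(nb %in% path) && length(path) < 6 && nb > path[1]) {
        walk(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) if (ok[s]) walk(s)
  rings
}

#' Annotate donor/acceptor/ionic/aromatic pharmacophores of a complex
#'
#' Protein atoms are typed from a shipped residue template table plus
#' generic backbone rules (amide N donor except proline, carbonyl O and
#' OXT acceptors, OXT also anionic). Ligand atoms are typed from element
#' and inferred heavy-atom connectivity: amine-like N are donors (and
#' acceptors when unsubstituted enough), quaternary N are cations,
#' carboxylate-, phosphate- and sulfate-like terminal oxygens are anionic
#' acceptors, other oxygens are acceptors (terminal ones also potential
#' hydroxyl donors). Five- and six-membered ligand rings are recorded for
#' arene contacts.
#'
#' @param cx a `bs_complex`.
#' @return object of class `pharmacophore_annotation`: data.frame
#'   parallel to `cx$atoms` with logical `donor`, `acceptor`, `cation`,
#'   `anion` and character `ring` (ring id or NA); ligand bond adjacency
#'   in attribute `bonds`.
#' @export
annotate_pharmacophores <- function(cx) {
  at <- cx$atoms
  n <- nrow(at)
  ann <- data.frame(donor = logical(n), acceptor = logical(n),
                    cation = logical(n), anion = logical(n),
                    ring = rep(NA_character_, n), stringsAsFactors = FALSE)

  ## protein: backbone rules + side-chain templates
  prot <- which(!at$is_ligand)
  bb_n <- prot[at$name[prot] == "N" & at$resname[prot] != "PRO"]
  ann$donor[bb_n] <- TRUE
  bb_o <- prot[at$name[prot] %in% c("O", "OXT")]
  ann$acceptor[bb_o] <- TRUE
  ann$anion[prot[at$name[prot] == "OXT"]] <- TRUE
  tpl <- residue_templates()
  key <- paste(at$resname[prot], at$name[prot])
  hit <- match(key, paste(tpl$resname, tpl$atom))
  has <- !is.na(hit)
  ann$donor[prot[has]] <- ann$donor[prot[has]] | tpl$donor[hit[has]] == 1
  ann$acceptor[prot[has]] <- ann$acceptor[prot[has]] | tpl$acceptor[hit[has]] == 1
  ann$cation[prot[has]] <- tpl$cation[hit[has]] == 1
  ann$anion[prot[has]] <- ann$anion[prot[has]] | tpl$anion[hit[has]] == 1
  ring_lab <- tpl$ring[hit[has]]
  ringy <- ring_lab != "-"
  ann$ring[prot[has][ringy]] <- paste0(at$uid[prot[has][ringy]], "/", ring_lab[ringy])

  ## ligand: element + connectivity rules
  lig <- which(at$is_ligand)
  lat <- at[lig, , drop = FALSE]
  bonds <- infer_bonds(lat)
  deg <- lengths(bonds)
  el <- lat$element
  unknown <- !(el %in% c("C", "N", "O", "S", "P", "F", "CL", "BR", "I"))
  if (any(unknown)) {
    warning("untyped ligand element(s): ", paste(unique(el[unknown]), collapse = ", "))
  }
  is_terminal_o <- el == "O" & deg <= 1
  # terminal O sharing a C/P/S parent with >= 2 terminal O siblings -> anionic
  anion_o <- logical(length(lig))
  for (i in which(is_terminal_o)) {
    parent <- bonds[[i]]
    if (length(parent) != 1) next
    sibs <- bonds[[parent]]
    n_term_o <- sum(el[sibs] == "O" & deg[sibs] <= 1)
    if (el[parent] %in% c("C", "P", "S") && n_term_o >= 2) anion_o[i] <- TRUE
  }
  for (i in seq_along(lig)) {
    j <- lig[i]
    if (el[i] == "N") {
      if (deg[i] >= 4) {
        ann$cation[j] <- TRUE
      } else {
        ann$donor[j] <- TRUE
        if (deg[i] <= 2) ann$acceptor[j] <- TRUE
      }
    } else if (el[i] == "O") {
      ann$acceptor[j] <- TRUE
      if (anion_o[i]) {
        ann$anion[j] <- TRUE
      } else if (deg[i] <= 1) {
        ann$donor[j] <- TRUE  # hydroxyl-like
      }
    } else if (el[i] == "S" && deg[i] <= 1) {
      ann$donor[j] <- TRUE
      ann$acceptor[j] <- TRUE
    }
  }
  rings <- find_rings(bonds, el)
  for (k in seq_along(rings)) {
    idx <- lig[rings[[k]]]
    ann$ring[idx] <- ifelse(is.na(ann$ring[idx]),
                            paste0("LIG/R", k), ann$ring[idx])
  }
  attr(ann, "ligand_bonds") <- bonds
  attr(ann, "ligand_rows") <- lig
  class(ann) <- c("pharmacophore_annotation", "data.frame")
  ann
}

angle_deg <- function(vertex, p1, p2) {
  v1 <- p1 - vertex; v2 <- p2 - vertex
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# donor angle proxy: passes if donor has no bonded heavy neighbour, or if
# some neighbour X gives angle(acceptor, donor, X) >= threshold
hb_angle_ok <- function(xyz_all, donor, acceptor, antecedents, threshold) {
  if (!length(antecedents)) return(TRUE)
  for (x in antecedents) {
    if (angle_deg(xyz_all[donor, ], xyz_all[acceptor, ], xyz_all[x, ]) >= threshold) {
      return(TRUE)
    }
  }
  FALSE
}

#' Detect protein-ligand interactions and encode them per alignment column
#'
#' Applies the geometric criteria in `config` to every ligand/protein
#' heavy-atom pair and emits at most one bit per (residue, interaction
#' type), regardless of how many atom pairs qualify and of whether the
#' contact is through backbone or side chain. HBD means the ligand acts
#' as hydrogen-bond donor; HBA means the ligand accepts. Residues whose
#' uid has no alignment column are dropped (count in attribute
#' `dropped_residues`).
#'
#' @param cx a `bs_complex`.
#' @param annot its [annotate_pharmacophores()] result.
#' @param map its `alignment_map`.
#' @param config criteria from [plif_config()].
#' @return object of class `interaction_fp`: list with `complex_id`,
#'   `site`, `bits` (data.frame `column`, `type`, unique rows).
#' @export
detect_interactions <- function(cx, annot, map, config = plif_config()) {
  at <- cx$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  lig <- which(at$is_ligand)
  pro <- which(!at$is_ligand)
  d <- ligand_protein_distances(cx)  # rows = lig order, cols = pro order

  lig_bonds <- attr(annot, "ligand_bonds")
  pro_at <- at[pro, , drop = FALSE]
  pro_bonds <- infer_bonds(pro_at)

  classified <- matrix(FALSE, length(lig), length(pro))
  bits <- list()
  add_bit <- function(uid, type) {
    bits[[length(bits) + 1]] <<- data.frame(uid = uid, type = type,
                                            stringsAsFactors = FALSE)
  }

  ## hydrogen bonds, ligand as donor (HBD)
  for (i in which(annot$donor[lig])) {
    ante <- lig[lig_bonds[[i]]]
    for (j in which(annot$acceptor[pro])) {
      if (d[i, j] > config$hb_dist) next
      if (hb_angle_ok(xyz, lig[i], pro[j], ante, config$hb_angle)) {
        add_bit(at$uid[pro[j]], "HBD")
        classified[i, j] <- TRUE
      }
    }
  }
  ## hydrogen bonds, ligand as acceptor (HBA): angle at the protein donor
  for (j in which(annot$donor[pro])) {
    ante <- pro[pro_bonds[[j]]]
    for (i in which(annot$acceptor[lig])) {
      if (d[i, j] > config$hb_dist) next
      if (hb_angle_ok(xyz, pro[j], lig[i], ante, config$hb_angle)) {
        add_bit(at$uid[pro[j]], "HBA")
        classified[i, j] <- TRUE
      }
    }
  }
  ## ionic
  for (i in seq_along(lig)) {
    for (j in seq_along(pro)) {
      if (d[i, j] > config$ionic_dist) next
      li <- lig[i]; pj <- pro[j]
      if ((annot$cation[li] && annot$anion[pj]) ||
          (annot$anion[li] && annot$cation[pj])) {
        add_bit(at$uid[pj], "IONIC")
        classified[i, j] <- TRUE
      }
    }
  }
  ## arene attraction: ring-centroid pairs (no orientation test)
  lig_rings <- unique(stats::na.omit(annot$ring[lig]))
  pro_rings <- unique(stats::na.omit(annot$ring[pro]))
  for (lr in lig_rings) {
    lc <- colMeans(xyz[which(annot$ring == lr & at$is_ligand), , drop = FALSE])
    for (pr in pro_rings) {
      rows <- which(annot$ring == pr & !at$is_ligand)
      pc <- colMeans(xyz[rows, , drop = FALSE])
      if (sqrt(sum((lc - pc)^2)) <= config$arene_dist) {
        add_bit(at$uid[rows[1]], "ARENE")
      }
    }
  }
  ## surface: remaining heavy-atom contacts
  close_pairs <- which(d <= config$surface_dist & !classified, arr.ind = TRUE)
  if (nrow(close_pairs)) {
    for (uid in unique(at$uid[pro[close_pairs[, 2]]])) add_bit(uid, "SURFACE")
  }

  bits <- if (length(bits)) unique(do.call(rbind, bits)) else
    data.frame(uid = character(0), type = character(0))
  cols <- map$mapping$column[match(bits$uid, map$mapping$uid)]
  dropped <- length(unique(bits$uid[is.na(cols)]))
  if (dropped > 0) {
    message(sprintf("%s: %d interacting residue(s) without alignment column, dropped",
                    cx$complex_id, dropped))
  }
  out <- data.frame(column = cols[!is.na(cols)], type = bits$type[!is.na(cols)],
                    stringsAsFactors = FALSE)
  out <- unique(out[order(out$column, out$type), , drop = FALSE])
  rownames(out) <- NULL
  structure(
    list(complex_id = cx$complex_id, site = cx$site, bits = out,
         dropped_residues = dropped),
    class = "interaction_fp"
  )
}

#' @export
print.interaction_fp <- function(x, ...) {
  cat(sprintf("<interaction_fp> %s (%s site): %d bits over %d columns\n",
              x$complex_id, x$site, nrow(x$bits), length(unique(x$bits$column))))
  invisible(x)
}

#' Tanimoto coefficient between two interaction fingerprints
#'
#' `|intersection| / |union|` over (column, type) bit sets. Two empty
#' fingerprints compare as 0 with a warning. Comparing fingerprints from
#' different sites is an error.
#'
#' @param f1,f2 `interaction_fp` objects.
#' @return similarity in `[0, 1]`.
#' @export
fingerprint_tanimoto <- function(f1, f2) {
  if (!identical(f1$site, f2$site)) {
    stop("site mismatch: ", f1$site, " vs ", f2$site)
  }
  b1 <- paste(f1$bits$column, f1$bits$type)
  b2 <- paste(f2$bits$column, f2$bits$type)
  u <- length(union(b1, b2))
  if (u == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  length(intersect(b1, b2)) / u
}

#' Pairwise Tanimoto similarity matrix over fingerprints
#' @param fps list of `interaction_fp` objects (same site).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
fingerprint_tanimoto_matrix <- function(fps) {
  ids <- vapply(fps, function(f) f$complex_id, "")
  n <- length(fps)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- fingerprint_tanimoto(fps[[i]], fps[[j]])
    }
  }
  m
}

#' Summarize interactions across complexes
#'
#' Reports, per (column, type), the percentage of complexes (or of
#' targets, when `grouping` is given) carrying that bit; per type, the
#' share of all residue-based contacts; and the list of interacting
#' columns.
#'
#' @param fps non-empty list of `interaction_fp` objects.
#' @param grouping optional named character vector complex_id -> target;
#'   when given, a bit counts once per target.
#' @return list with data.frames `per_bit` (`column`, `type`,
#'   `percent`), `per_type` (`type`, `count`, `percent`), and integer
#'   vector `interacting_columns`.
#' @export
summarize_interactions <- function(fps, grouping = NULL) {
  stopifnot(length(fps) >= 1)
  tabs <- lapply(fps, function(f) {
    if (!nrow(f$bits)) return(NULL)
    unit <- if (is.null(grouping)) f$complex_id else unname(grouping[f$complex_id])
    cbind(f$bits, unit = unit)
  })
  tabs <- do.call(rbind, tabs)
  n_units <- if (is.null(grouping)) length(fps) else
    length(unique(unname(grouping[vapply(fps, function(f) f$complex_id, "")])))
  if (is.null(tabs)) {
    return(list(per_bit = data.frame(column = integer(0), type = character(0),
                                     percent = numeric(0)),
                per_type = data.frame(type = INTERACTION_TYPES, count = 0L,
                                      percent = NA_real_),
                interacting_columns = integer(0)))
  }
  tabs <- unique(tabs)  # one count per (bit, unit)
  per_bit <- aggregate(unit ~ column + type, tabs, function(u) length(unique(u)))
  per_bit$percent <- 100 * per_bit$unit / n_units
  per_bit <- per_bit[order(per_bit$column, per_bit$type), c("column", "type", "percent")]
  rownames(per_bit) <- NULL
  counts <- table(factor(tabs$type, levels = INTERACTION_TYPES))
  per_type <- data.frame(type = INTERACTION_TYPES,
                         count = as.integer(counts),
                         percent = 100 * as.integer(counts) / sum(counts))
  list(per_bit = per_bit, per_type = per_type,
       interacting_columns = sort(unique(per_bit$column)))
}

#' Serialize fingerprints to TSV
#' @param fps list of `interaction_fp` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints_tsv <- function(fps, path) {
  tabs <- lapply(fps, function(f) {
    if (!nrow(f$bits)) return(NULL)
    cbind(complex_id = f$complex_id, site = f$site, f$bits)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab)) {
    tab <- data.frame(complex_id = character(0), site = character(0),
                      column = integer(0), type = character(0))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
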