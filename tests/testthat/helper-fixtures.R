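# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's computation paths: explicit loops over raw data only.

AA1TO3 <- setNames(names(pocketmap:::AA3TO1), pocketmap:::AA3TO1)

# standard 3-residue toy: single-atom probe residues + 2-atom ligand
toy3_spec <- function(seed = 42, n_waters = 2,
                      distances = c(2.9, 3.93), roles = c("donor", "none")) {
  toy_complex_spec(
    residues = list(
      list(name = "GLY", atoms = data.frame(name = "O", element = "O",
                                            dx = 0, dy = 0, dz = 0)),
      list(name = "LYS", atoms = data.frame(name = "NZ", element = "N",
                                            dx = 0, dy = 0, dz = 0)),
      list(name = "ALA", atoms = data.frame(name = "CB", element = "C",
                                            dx = 0, dy = 0, dz = 0))
    ),
    ligand = data.frame(name = c("N1", "C2"), element = c("N", "C"),
                        anchor_res = c(1, 3), anchor_atom = c("O", "CB"),
                        distance = distances, role = roles,
                        stringsAsFactors = FALSE),
    n_waters = n_waters, seed = seed
  )
}

# bs_complex with one probe atom per residue, sequence given as letters
make_seq_complex <- function(letters1, id = "seqcx", target = id,
                             site = "cofactor", atom = "O", element = "O") {
  n <- nchar(letters1)
  ch <- strsplit(letters1, "")[[1]]
  atoms <- data.frame(
    name = atom, element = element,
    x = 25 * (seq_len(n) - 1), y = 0, z = 0,
    chain = "A", resnum = seq_len(n), icode = "",
    resname = unname(AA1TO3[ch]),
    uid = paste0("A:", seq_len(n), ":_"),
    is_ligand = FALSE, is_backbone = atom %in% c("N", "CA", "C", "O", "OXT"),
    stringsAsFactors = FALSE
  )
  pocketmap:::new_bs_complex(id, target, site, atoms)
}

# random proper rotation + translation applied to a complex
rigid_transform_complex <- function(cx, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t0 <- rnorm(3, sd = 20)
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% t(R)
  cx$atoms$x <- xyz[, 1] + t0[1]
  cx$atoms$y <- xyz[, 2] + t0[2]
  cx$atoms$z <- xyz[, 3] + t0[3]
  cx
}

# alignment map asserting identity structure order -> given columns
manual_map <- function(cx, columns) {
  res <- pocketmap:::complex_residues(cx)
  stopifnot(nrow(res) == length(columns))
  structure(
    list(complex_id = cx$complex_id, row_name = "manual",
         mapping = data.frame(uid = res$uid, resnum = res$resnum,
                              icode = res$icode, column = columns,
                              stringsAsFactors = FALSE),
         coverage = 1, identity = 1),
    class = "alignment_map"
  )
}

# minimal interaction_fp constructor for set-arithmetic tests
manual_fp <- function(id, bits, site = "cofactor") {
  structure(list(complex_id = id, site = site,
                 bits = bits, dropped_residues = 0L),
            class = "interaction_fp")
}

# --- independent oracle: score matrix by explicit loops -----------------
brute_score_matrix <- function(aln, profiles) {
  M <- gonnet_matrix()
  n <- length(aln$names)
  chars <- lapply(aln$rows, function(r) strsplit(r, "")[[1]])
  zs <- list()
  for (p in profiles) {
    cols <- as.integer(names(p$weights))
    raw <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        s <- 0
        for (k in seq_along(cols)) {
          a <- chars[[i]][cols[k]]
          b <- chars[[j]][cols[k]]
          sim <- if (a %in% rownames(M) && b %in% rownames(M)) {
            M[a, b] / sqrt(M[a, a] * M[b, b])
          } else 0
          s <- s + unname(p$weights[k]) * sim
        }
        raw[i, j] <- s
      }
    }
    vals <- raw[upper.tri(raw)]
    z <- (raw - mean(vals)) / sd(vals)
    diag(z) <- NA_real_
    zs[[length(zs) + 1]] <- z
  }
  avg <- Reduce(`+`, zs) / length(zs)
  vals <- avg[upper.tri(avg)]
  norm <- (avg - min(vals)) / (max(vals) - min(vals))
  diag(norm) <- 1
  list(averaged = avg, normalized = norm, distance = 1 - norm)
}

# --- independent oracle: exhaustive UPGMA agglomerator ------------------
# inter-cluster distance recomputed as the mean over ORIGINAL leaf pairs
oracle_upgma <- function(m) {
  leaves <- rownames(m)
  clusters <- as.list(leaves)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; bd <- Inf; bk <- ""
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        s <- 0; cnt <- 0
        for (x in clusters[[i]]) for (y in clusters[[j]]) {
          s <- s + m[x, y]; cnt <- cnt + 1
        }
        dij <- s / cnt
        key <- paste(sort(c(paste(sort(clusters[[i]]), collapse = "|"),
                            paste(sort(clusters[[j]]), collapse = "|"))),
                     collapse = "~")
        if (dij < bd - 1e-12 || (abs(dij - bd) <= 1e-12 && key < bk)) {
          bd <- dij; best <- c(i, j); bk <- key
        }
      }
    }
    merges[[length(merges) + 1]] <- list(a = sort(clusters[[best[1]]]),
                                         b = sort(clusters[[best[2]]]),
                                         height = bd / 2)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# random targets/complexes manifest built from a planted alignment; each
# structure carries its row's full sequence as probe residues
build_synthetic_manifest <- function(aln, site_columns, dir,
                                     site = "cofactor", seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_along(aln$names)) {
    nm <- aln$names[i]
    letters1 <- aln$rows[i]  # no gaps in planted alignments
    residues <- lapply(strsplit(letters1, "")[[1]], function(ch) {
      list(name = unname(AA1TO3[ch]),
           atoms = data.frame(name = "O", element = "O", dx = 0, dy = 0, dz = 0))
    })
    anchors <- sample(site_columns, 3)
    lig <- data.frame(name = paste0("N", 1:3), element = "N",
                      anchor_res = anchors, anchor_atom = "O",
                      distance = c(2.9, 3.2, 4.0), role = "donor",
                      stringsAsFactors = FALSE)
    spec <- toy_complex_spec(residues, lig, seed = seed + i)
    path <- file.path(dir, paste0(nm, ".pdb"))
    make_toy_complex(spec, path)
    rows[[i]] <- data.frame(complex_id = paste0(nm, "_cx"), path = path,
                            chain = "A", target = nm, site = site,
                            ligand_selector = "LIG", alignment_row = nm,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
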