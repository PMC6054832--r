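# PDB reading and binding-site complex construction.
#
# Only the fixed-column ATOM/HETATM/TER subset of the PDB format is
# supported (no mmCIF). Altloc and insertion codes are honored; waters
# and hydrogens are always discarded on load.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

modres_aliases <- function() {
  if (is.null(.pocketmap_env$modres)) {
    tab <- read.delim(pm_extdata("modres_aliases.tsv"), stringsAsFactors = FALSE)
    .pocketmap_env$modres <- setNames(tab$parent, tab$modres)
  }
  .pocketmap_env$modres
}

#' Parse ATOM/HETATM records from a PDB file
#'
#' Low-level fixed-column reader. Returns one row per atom record with
#' coordinates, occupancy, altloc and insertion code. Elements missing
#' from columns 77-78 are inferred from the atom name.
#'
#' @param path path to a PDB file.
#' @return data.frame with columns `record`, `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resnum`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `element`, `line`.
#' @export
read_pdb_atoms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stop("no ATOM/HETATM records in ", path)
  ln <- lines[keep]
  # pad short lines so fixed-column extraction is safe
  ln <- formatC(ln, width = 80, flag = "-")
  num <- function(s, lo, hi, what) {
    v <- suppressWarnings(as.numeric(substr(s, lo, hi)))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("PDB format error at line %d: unreadable %s field",
                   keep[bad[1]], what))
    }
    v
  }
  element <- trimws(substr(ln, 77, 78))
  name <- trimws(substr(ln, 13, 16))
  # fall back to the first alphabetic character of the atom name
  noel <- !nzchar(element)
  element[noel] <- substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", name[noel])), 1, 1)
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    record = trimws(substr(ln, 1, 6)),
    serial = num(ln, 7, 11, "serial"),
    name = name,
    altloc = substr(ln, 17, 17),
    resname = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resnum = num(ln, 23, 26, "residue number"),
    icode = substr(ln, 27, 27),
    x = num(ln, 31, 38, "x coordinate"),
    y = num(ln, 39, 46, "y coordinate"),
    z = num(ln, 47, 54, "z coordinate"),
    occupancy = occ,
    element = toupper(element),
    line = keep,
    stringsAsFactors = FALSE
  )
}

residue_uid <- function(chain, resnum, icode) {
  paste0(chain, ":", resnum, ":", ifelse(icode == " " | icode == "", "_", icode))
}

# keep highest occupancy altloc per (residue, atom name); ties broken by
# altloc label order
resolve_altlocs <- function(at) {
  key <- paste(residue_uid(at$chain, at$resnum, at$icode), at$resname, at$name)
  ord <- order(key, -at$occupancy, at$altloc)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

#' Load a protein-ligand binding-site complex from a PDB file
#'
#' Reads one chain, removes waters and hydrogens, resolves alternate
#' locations (highest occupancy kept, ties broken by altloc label), and
#' selects ligand HETATM groups matching `ligand_selector`. Modified
#' polymer residues (MSE and friends) are treated as protein with their
#' parent residue name.
#'
#' @param path PDB file.
#' @param chain_id single chain identifier.
#' @param ligand_selector character vector of HETATM residue names
#'   (e.g. `"SAH"`) and/or residue UIDs `"RESNAME:chain:resnum"`.
#' @param site `"cofactor"` or `"substrate"`.
#' @param complex_id identifier for the complex; defaults to the file
#'   base name.
#' @param target_name protein target label; defaults to `complex_id`.
#' @return object of class `bs_complex`: list with `complex_id`,
#'   `target_name`, `site` and an `atoms` data.frame (heavy atoms only,
#'   `is_ligand`/`is_backbone` flags, `uid` residue identifiers).
#' @export
load_complex <- function(path, chain_id, ligand_selector,
                         site = c("cofactor", "substrate"),
                         complex_id = NULL, target_name = NULL) {
  site <- match.arg(site)
  at <- read_pdb_atoms(path)
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (!nrow(at)) stop("chain not found: '", chain_id, "' in ", path)
  at <- at[!(at$resname %in% WATER_RESNAMES), , drop = FALSE]
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  at <- resolve_altlocs(at)

  aliases <- modres_aliases()
  is_polymer <- at$record == "ATOM" |
    (at$record == "HETATM" & at$resname %in% names(aliases))
  at$resname[at$resname %in% names(aliases)] <- aliases[at$resname[at$resname %in% names(aliases)]]

  uid <- residue_uid(at$chain, at$resnum, at$icode)
  sel_uid <- grepl(":", ligand_selector, fixed = TRUE)
  lig_by_name <- !is_polymer & at$record == "HETATM" &
    at$resname %in% ligand_selector[!sel_uid]
  lig_by_uid <- !is_polymer & at$record == "HETATM" &
    paste0(at$resname, ":", at$chain, ":", at$resnum) %in% ligand_selector[sel_uid]
  is_ligand <- lig_by_name | lig_by_uid
  if (!any(is_ligand)) {
    stop("no ligand matched selector [", paste(ligand_selector, collapse = ", "),
         "] in chain ", chain_id, " of ", path)
  }
  keep <- is_polymer | is_ligand
  at <- at[keep, , drop = FALSE]
  is_ligand <- is_ligand[keep]
  is_polymer <- is_polymer[keep]

  atoms <- data.frame(
    name = at$name, element = at$element,
    x = at$x, y = at$y, z = at$z,
    chain = at$chain, resnum = at$resnum,
    icode = ifelse(at$icode == " ", "", at$icode),
    resname = at$resname,
    uid = residue_uid(at$chain, at$resnum, at$icode),
    is_ligand = is_ligand,
    is_backbone = is_polymer & !is_ligand & at$name %in% BACKBONE_ATOMS,
    stringsAsFactors = FALSE
  )
  if (is.null(complex_id)) complex_id <- tools::file_path_sans_ext(basename(path))
  if (is.null(target_name)) target_name <- complex_id
  new_bs_complex(complex_id, target_name, site, atoms)
}

new_bs_complex <- function(complex_id, target_name, site, atoms) {
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  stopifnot(!any(atoms$is_ligand & atoms$is_backbone))
  obj <- structure(
    list(complex_id = complex_id, target_name = target_name,
         site = site, atoms = atoms),
    class = "bs_complex"
  )
  obj
}

#' @export
print.bs_complex <- function(x, ...) {
  cat(sprintf("<bs_complex> %s (%s, %s site): %d protein atoms, %d ligand atoms, %d residues\n",
              x$complex_id, x$target_name, x$site,
              sum(!x$atoms$is_ligand), sum(x$atoms$is_ligand),
              length(unique(x$atoms$uid[!x$atoms$is_ligand]))))
  invisible(x)
}

protein_atoms <- function(cx) cx$atoms[!cx$atoms$is_ligand, , drop = FALSE]
ligand_atoms <- function(cx) cx$atoms[cx$atoms$is_ligand, , drop = FALSE]

# polymer residues in (resnum, icode) order, one row each
complex_residues <- function(cx) {
  p <- protein_atoms(cx)
  r <- p[!duplicated(p$uid), c("uid", "chain", "resnum", "icode", "resname")]
  r[order(r$resnum, r$icode), , drop = FALSE]
}

# one-letter sequence of the polymer; unknown residues become X
complex_sequence <- function(cx) {
  r <- complex_residues(cx)
  letters1 <- AA3TO1[r$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' Serialize a complex to a TSV file (one atom per row)
#'
#' @param cx a `bs_complex`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complex_tsv <- function(cx, path) {
  meta <- sprintf("# complex_id=%s\ttarget_name=%s\tsite=%s",
                  cx$complex_id, cx$target_name, cx$site)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.table(cx$atoms, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a complex serialized by [write_complex_tsv()]
#'
#' @param path TSV path.
#' @return a `bs_complex`.
#' @export
read_complex_tsv <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# complex_id=")) stop("not a serialized complex: ", path)
  kv <- strsplit(sub("^# ", "", header), "\t")[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  atoms <- read.delim(path, skip = 1, stringsAsFactors = FALSE,
                      colClasses = c(icode = "character"))
  atoms$icode[is.na(atoms$icode)] <- ""
  new_bs_complex(meta[["complex_id"]], meta[["target_name"]], meta[["site"]], atoms)
}

#' Pairwise ligand RMSD matrix over a set of complexes
#'
#' Atoms are matched by name between each pair of ligands and the RMSD is
#' computed in the given coordinate frame (no re-superposition: complexes
#' are assumed to be pre-superposed upstream). Pairs sharing fewer than 3
#' atom names are flagged `NA` rather than silently reported as zero.
#'
#' @param complexes list of `bs_complex` objects.
#' @return symmetric numeric matrix of RMSD values in Angstrom, zero
#'   diagonal, dimnames from complex ids.
#' @export
ligand_rmsd_matrix <- function(complexes) {
  stopifnot(length(complexes) >= 1)
  ids <- vapply(complexes, function(cx) cx$complex_id, "")
  if (anyDuplicated(ids)) stop("duplicate complex ids")
  ligs <- lapply(complexes, ligand_atoms)
  n <- length(ligs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- ligs[[i]]; b <- ligs[[j]]
      shared <- intersect(a$name, b$name)
      if (length(shared) < 3) {
        m[i, j] <- m[j, i] <- NA_real_
        next
      }
      pa <- as.matrix(a[match(shared, a$name), c("x", "y", "z")])
      pb <- as.matrix(b[match(shared, b$name), c("x", "y", "z")])
      m[i, j] <- m[j, i] <- sqrt(mean(rowSums((pa - pb)^2)))
    }
  }
  m
}
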