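# Master alignment handling and normalized Gonnet residue similarities.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CHARS <- c("-", ".")

new_master_alignment <- function(names, rows) {
  if (anyDuplicated(names)) stop("duplicate sequence names in alignment")
  len <- nchar(rows)
  if (length(unique(len)) > 1) {
    bad <- names[which(len != len[1])[1]]
    stop("ragged alignment: ", bad)
  }
  structure(list(names = names, rows = toupper(rows)),
            class = "master_alignment")
}

#' @export
print.master_alignment <- function(x, ...) {
  cat(sprintf("<master_alignment> %d sequences x %d columns\n",
              length(x$names), nchar(x$rows[1])))
  invisible(x)
}

#' Number of columns of a master alignment
#' @param aln a `master_alignment`.
#' @return integer column count.
#' @export
alignment_length <- function(aln) nchar(aln$rows[1])

#' Read a master multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal (`CLUSTAL` header) files. Clustal
#' conservation lines are ignored. All rows must have equal length; a
#' ragged alignment raises an error naming the offending sequence.
#'
#' @param path alignment file.
#' @return a `master_alignment` (fields `names`, `rows`).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    return(read_clustal(path))
  }
  seqs <- Biostrings::readAAStringSet(path)
  rows <- as.character(seqs)
  len <- nchar(rows)
  if (length(unique(len)) > 1) {
    bad <- names(seqs)[which(len != len[1])[1]]
    stop("ragged alignment: ", bad)
  }
  new_master_alignment(sub("\\s.*$", "", names(seqs)), unname(rows))
}

read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)[-1]
  seqs <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next  # conservation line
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2) next
    nm <- parts[1]
    chunk <- gsub("[0-9]", "", paste(parts[-1], collapse = ""))
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]], chunk)
  }
  if (!length(seqs)) stop("no sequences parsed from Clustal file: ", path)
  len <- nchar(unlist(seqs))
  if (length(unique(len)) > 1) {
    bad <- names(seqs)[which(len != len[1])[1]]
    stop("ragged alignment: ", bad)
  }
  new_master_alignment(names(seqs), unname(unlist(seqs)))
}

#' The shipped Gonnet (1992) residue comparison matrix
#'
#' @return symmetric 20x20 numeric matrix `M` over the standard amino
#'   acids, in 10*log10-odds units.
#' @export
gonnet_matrix <- function() {
  if (is.null(.pocketmap_env$gonnet)) {
    txt <- readLines(pm_extdata("gonnet1992.txt"))
    txt <- txt[!grepl("^#", txt)]
    header <- strsplit(trimws(txt[1]), "\\s+")[[1]]
    rows <- strsplit(trimws(txt[-1]), "\\s+")
    m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
    dimnames(m) <- list(vapply(rows, `[`, "", 1), header)
    stopifnot(identical(rownames(m), colnames(m)),
              isTRUE(all.equal(m, t(m))),
              all(diag(m) > 0))
    # normalized similarity must not exceed 1 anywhere on the shipped table
    S <- m / sqrt(outer(diag(m), diag(m)))
    stopifnot(max(S) <= 1 + 1e-12)
    .pocketmap_env$gonnet <- m
    .pocketmap_env$gonnet_S <- S
  }
  .pocketmap_env$gonnet
}

#' Normalized Gonnet per-residue similarity
#'
#' `S(a, b) = M(a, b) / sqrt(M(a, a) * M(b, b))` with the Gonnet matrix
#' `M`, so `S(a, a) = 1` for every residue. Gaps and (by default) `X`
#' contribute similarity 0; any other non-standard letter is an error.
#'
#' @param a,b single amino-acid letters (vectorized, recycled).
#' @param unknown named numeric vector mapping non-standard letters to a
#'   fixed similarity (default `c(X = 0)`).
#' @return numeric similarity in `(-Inf, 1]`.
#' @export
gonnet_similarity <- function(a, b, unknown = c(X = 0)) {
  gonnet_matrix()
  S <- .pocketmap_env$gonnet_S
  a <- toupper(a); b <- toupper(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- numeric(n)
  gap <- a %in% GAP_CHARS | b %in% GAP_CHARS
  std <- a %in% AA_LETTERS & b %in% AA_LETTERS
  unk <- !gap & !std
  if (any(unk)) {
    letters_unk <- setdiff(unique(c(a[unk], b[unk])), c(AA_LETTERS, GAP_CHARS))
    bad <- setdiff(letters_unk, names(unknown))
    if (length(bad)) stop("non-standard residue letter(s): ", paste(bad, collapse = ", "))
    ua <- ifelse(a[unk] %in% names(unknown), unknown[a[unk]], unknown[b[unk]])
    out[unk] <- ua
  }
  out[std] <- S[cbind(a[std], b[std])]
  out[gap] <- 0
  out
}

# substitution matrix for pairwise alignment: Gonnet + zero-scored X
alignment_submat <- function() {
  m <- gonnet_matrix()
  full <- matrix(0, 21, 21, dimnames = list(c(AA_LETTERS, "X"), c(AA_LETTERS, "X")))
  full[AA_LETTERS, AA_LETTERS] <- m
  full
}

#' Map a structure's residues to master-alignment columns
#'
#' Pairwise-aligns the structure's observed one-letter sequence against
#' the ungapped master row (global-local alignment, Gonnet scoring,
#' affine gaps: open 10 / extend 0.5), then composes the result with the
#' row's gap pattern to obtain a residue-to-column map. An alignment
#' identity below `min_identity` raises a "structure/row mismatch" error,
#' guarding against a wrong row assignment.
#'
#' @param cx a `bs_complex`.
#' @param aln a `master_alignment`.
#' @param row_name name of the alignment row this structure belongs to.
#' @param min_identity identity floor over aligned (non-gap) pairs.
#' @return object of class `alignment_map`: list with `complex_id`,
#'   `row_name`, `mapping` (data.frame `uid`, `resnum`, `icode`,
#'   `column`), and `coverage` (fraction of structure residues mapped).
#' @export
map_structure_to_columns <- function(cx, aln, row_name, min_identity = 0.60) {
  idx <- match(row_name, aln$names)
  if (is.na(idx)) stop("row name not in alignment: ", row_name)
  res <- complex_residues(cx)
  if (!nrow(res)) stop("structure has no polymer residues")
  struct_seq <- complex_sequence(cx)
  row <- aln$rows[idx]
  row_chars <- strsplit(row, "")[[1]]
  nongap <- !(row_chars %in% GAP_CHARS)
  ungapped <- paste(row_chars[nongap], collapse = "")
  if (!nchar(ungapped)) stop("alignment row is all gaps: ", row_name)

  al <- Biostrings::pairwiseAlignment(
    pattern = struct_seq, subject = ungapped,
    substitutionMatrix = alignment_submat(),
    gapOpening = 10, gapExtension = 0.5, type = "global-local"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sub_start <- al@subject@range@start

  aligned <- pa != "-" & sa != "-"
  identity <- if (any(aligned)) mean(pa[aligned] == sa[aligned]) else 0
  if (identity < min_identity) {
    stop(sprintf("structure/row mismatch: identity %.2f below floor %.2f for row %s",
                 identity, min_identity, row_name))
  }

  col_of_ungapped <- which(nongap)  # ungapped position -> alignment column
  pat_pos <- cumsum(pa != "-")
  sub_pos <- cumsum(sa != "-") + (sub_start - 1)
  pat_idx <- pat_pos[aligned]
  columns <- col_of_ungapped[sub_pos[aligned]]

  mapping <- data.frame(
    uid = res$uid[pat_idx],
    resnum = res$resnum[pat_idx],
    icode = res$icode[pat_idx],
    column = columns,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(mapping$column) || anyDuplicated(mapping$uid)) {
    stop("internal error: non-injective structure-to-column mapping")
  }
  structure(
    list(complex_id = cx$complex_id, row_name = row_name,
         mapping = mapping, coverage = nrow(mapping) / nrow(res),
         identity = identity),
    class = "alignment_map"
  )
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("<alignment_map> %s -> row '%s': %d residues mapped (coverage %.2f, identity %.2f)\n",
              x$complex_id, x$row_name, nrow(x$mapping), x$coverage, x$identity))
  invisible(x)
}

#' Serialize alignment maps to TSV
#' @param maps list of `alignment_map` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_maps_tsv <- function(maps, path) {
  tabs <- lapply(maps, function(m) {
    cbind(complex_id = m$complex_id, row_name = m$row_name, m$mapping)
  })
  write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
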