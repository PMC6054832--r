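# Profile-weighted pocket similarity: per-profile weighted Gonnet sums,
# Z-standardization, averaging across profiles, min-max normalization,
# distance conversion and neighbor ranking.

#' Profile-weighted Gonnet similarity between two aligned rows
#'
#' Sum over the profile's columns `c` of `w(c) * S(seq1[c], seq2[c])`,
#' where `S` is the normalized Gonnet similarity. A gap in either row at
#' a profile column contributes 0 (contact residues falling in gaps
#' cannot be propagated).
#'
#' @param seq1,seq2 gapped rows from the same master alignment.
#' @param profile a `contact_profile`.
#' @return numeric similarity (unbounded above by the profile's total
#'   weight, which it attains for identical gap-free rows).
#' @export
gonnet_pfp <- function(seq1, seq2, profile) {
  cols <- as.integer(names(profile$weights))
  len <- nchar(seq1)
  if (nchar(seq2) != len) stop("rows have different lengths")
  if (any(cols < 1 | cols > len)) {
    stop("profile column out of alignment range: ",
         paste(cols[cols < 1 | cols > len], collapse = ", "))
  }
  a <- strsplit(seq1, "")[[1]][cols]
  b <- strsplit(seq2, "")[[1]][cols]
  sum(profile$weights * gonnet_similarity(a, b))
}

offdiag_upper <- function(m) m[upper.tri(m)]

#' Pocket similarity matrices from contact profiles
#'
#' For each profile `L`, computes the raw matrix of [gonnet_pfp()] values
#' over all sequence pairs (self-pairs included on the diagonal), then
#' standardizes each raw matrix into Z-scores over its off-diagonal
#' upper-triangle population, averages the Z-matrices element-wise across
#' profiles with equal weight, min-max normalizes the average (again over
#' the off-diagonal population) into `[0, 1]` with the diagonal set to 1
#' by convention, and emits the distance twin `1 - normalized`.
#'
#' @param aln a `master_alignment` (>= 2 sequences).
#' @param profiles non-empty list of `contact_profile` objects.
#' @return object of class `score_matrix_set`: list with `names`,
#'   `raw` (named list of per-profile matrices), `zscored` (same, NA
#'   diagonal), `averaged`, `normalized`, `distance`.
#' @export
score_matrix <- function(aln, profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  n <- length(aln$names)
  if (n < 2) stop("need at least 2 sequences")
  if (n == 2) stop("degenerate profile population: a single off-diagonal pair has no spread")
  raw <- list(); z <- list()
  for (p in profiles) {
    m <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
    for (i in seq_len(n)) {
      for (j in i:n) {
        m[i, j] <- m[j, i] <- gonnet_pfp(aln$rows[i], aln$rows[j], p)
      }
    }
    pop <- offdiag_upper(m)
    s <- sd(pop)
    if (!is.finite(s) || s == 0) {
      stop("degenerate profile: ", p$target_name,
           " (constant raw similarity over all sequence pairs)")
    }
    zm <- (m - mean(pop)) / s
    diag(zm) <- NA_real_
    raw[[p$target_name]] <- m
    z[[p$target_name]] <- zm
  }
  avg <- Reduce(`+`, z) / length(z)
  pop <- offdiag_upper(avg)
  rng <- range(pop)
  if (rng[1] == rng[2]) stop("degenerate averaged matrix: no spread to normalize")
  norm <- (avg - rng[1]) / (rng[2] - rng[1])
  diag(norm) <- 1
  dist <- 1 - norm
  structure(
    list(names = aln$names, raw = raw, zscored = z,
         averaged = avg, normalized = norm, distance = dist,
         n_profiles = length(profiles)),
    class = "score_matrix_set"
  )
}

#' @export
print.score_matrix_set <- function(x, ...) {
  cat(sprintf("<score_matrix_set> %d sequences, %d profile(s); stages: raw, zscored, averaged, normalized, distance\n",
              length(x$names), x$n_profiles))
  invisible(x)
}

#' Rank pharmacological neighbors of a target
#'
#' Sorts all other sequences by descending normalized similarity to
#' `target`; ties are broken alphabetically by name.
#'
#' @param scores a `score_matrix_set` (its `normalized` stage is used) or
#'   a plain symmetric similarity matrix with dimnames.
#' @param target sequence name.
#' @param k number of neighbors to report (capped at n - 1).
#' @return data.frame `name`, `similarity` (full precision) and
#'   `similarity_2dp` (reporting convention, 2 decimals).
#' @export
rank_neighbors <- function(scores, target, k = 10) {
  m <- if (inherits(scores, "score_matrix_set")) scores$normalized else scores
  if (!(target %in% rownames(m))) stop("unknown target: ", target)
  sims <- m[target, setdiff(colnames(m), target)]
  ord <- order(-sims, names(sims))
  out <- data.frame(name = names(sims)[ord], similarity = unname(sims[ord]),
                    stringsAsFactors = FALSE)
  out <- utils::head(out, min(k, nrow(out)))
  out$similarity_2dp <- round(out$similarity, 2)
  rownames(out) <- NULL
  out
}

#' Write a square matrix as CSV (header row and column)
#' @param m matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Classical whole-pocket Gonnet similarity baseline
#'
#' Comparison baseline: instead of soft contact weights, every alignment
#' column hosting a residue within `cutoff` of any ligand (in any of the
#' supplied mapped complexes) gets weight 1, and the same scoring
#' cascade is applied.
#'
#' @param aln a `master_alignment`.
#' @param complexes list of `bs_complex`.
#' @param maps parallel list of `alignment_map`.
#' @param site site label for the pooled pseudo-profile.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return a `score_matrix_set` built from a single binary pocket profile.
#' @export
classic_pocket_scores <- function(aln, complexes, maps, site = "cofactor",
                                  cutoff = 4.5) {
  cols <- integer(0)
  for (k in seq_along(complexes)) {
    d <- ligand_protein_distances(complexes[[k]])
    pro <- protein_atoms(complexes[[k]])
    near <- unique(pro$uid[apply(d <= cutoff, 2, any)])
    cc <- maps[[k]]$mapping$column[match(near, maps[[k]]$mapping$uid)]
    cols <- union(cols, cc[!is.na(cc)])
  }
  if (!length(cols)) stop("no pocket columns within cutoff")
  prof <- structure(
    list(target_name = "pocket_union", site = site,
         weights = setNames(rep(1, length(cols)), sort(cols)),
         n_complexes = length(complexes), mode = "binary", rescaled = FALSE),
    class = "contact_profile"
  )
  score_matrix(aln, list(prof))
}
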