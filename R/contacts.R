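# Distance-ramp contact strengths and per-target ensemble profiles.

CONTACT_PLATEAU <- 3.23  # Angstrom: full-strength contact at or below
CONTACT_CUTOFF <- 4.63   # Angstrom: no contact at or beyond

#' Soft contact strength of an atom pair
#'
#' Piecewise-linear ramp on interatomic distance `d`: 1 for
#' `d <= 3.23` Angstrom, 0 for `d >= 4.63` Angstrom, linear in between.
#' Continuous and non-increasing.
#'
#' @param d non-negative distance(s) in Angstrom.
#' @return contact strength(s) in `[0, 1]`.
#' @export
contact_strength <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  pmin(1, pmax(0, (CONTACT_CUTOFF - d) / (CONTACT_CUTOFF - CONTACT_PLATEAU)))
}

# ligand x protein heavy-atom distance matrix
ligand_protein_distances <- function(cx) {
  lig <- as.matrix(ligand_atoms(cx)[, c("x", "y", "z")])
  pro <- as.matrix(protein_atoms(cx)[, c("x", "y", "z")])
  d2 <- outer(rowSums(lig^2), rowSums(pro^2), "+") - 2 * lig %*% t(pro)
  sqrt(pmax(d2, 0))
}

#' Per-column contact weight vector of one complex
#'
#' For every pair of non-hydrogen ligand and protein atoms the soft
#' contact strength is evaluated and summed per protein residue (total
#' contact strength: backbone and side chain both included). Residue
#' weights are then keyed by master-alignment column through `map`;
#' residues without a column are dropped and their count attached as
#' attribute `dropped_residues`.
#'
#' @param cx a `bs_complex`.
#' @param map the complex's `alignment_map`.
#' @return named numeric vector (names = alignment columns) of positive
#'   contact weights; empty if no atom pair is within the contact cutoff.
#' @export
complex_contact_vector <- function(cx, map) {
  stopifnot(inherits(map, "alignment_map"), map$complex_id == cx$complex_id)
  d <- ligand_protein_distances(cx)
  s <- matrix(contact_strength(d), nrow = nrow(d))  # pmax drops dims
  pro <- protein_atoms(cx)
  w <- tapply(colSums(s), pro$uid, sum)
  w <- w[w > 0]
  if (!length(w)) return(setNames(numeric(0), character(0)))
  cols <- map$mapping$column[match(names(w), map$mapping$uid)]
  dropped <- sum(is.na(cols))
  if (dropped > 0) {
    message(sprintf("%s: %d contact residue(s) not mapped to an alignment column, dropped",
                    cx$complex_id, dropped))
  }
  out <- setNames(as.numeric(w[!is.na(cols)]), cols[!is.na(cols)])
  out <- out[order(as.integer(names(out)))]
  attr(out, "dropped_residues") <- dropped
  out
}

#' Aggregate contact vectors of one target into an ensemble profile
#'
#' Combines per-complex contact vectors column-wise by `mode` (default
#' `"max"`, which removes redundancy between near-identical complexes;
#' `"mean"` available), then rescales so the strongest column has weight
#' 1, making profiles of targets with many vs few complexes comparable.
#'
#' @param vectors list of named numeric vectors from
#'   [complex_contact_vector()] (same target and site).
#' @param target_name,site labels stored on the profile.
#' @param mode `"max"` or `"mean"`.
#' @param rescale rescale maximum weight to 1 (default TRUE; FALSE keeps
#'   raw aggregated sums).
#' @return object of class `contact_profile`: list with `target_name`,
#'   `site`, `weights` (named by column), `n_complexes`.
#' @export
ensemble_profile <- function(vectors, target_name, site = "cofactor",
                             mode = c("max", "mean"), rescale = TRUE) {
  mode <- match.arg(mode)
  if (!length(vectors)) stop("no contact vectors supplied for ", target_name)
  vectors <- lapply(vectors, function(v) v[v > 0])
  cols <- sort(unique(as.integer(unlist(lapply(vectors, names)))))
  if (!length(cols)) stop("all contact vectors empty for ", target_name)
  stacked <- vapply(vectors, function(v) {
    out <- setNames(numeric(length(cols)), cols)
    out[names(v)] <- v
    out
  }, numeric(length(cols)))
  stacked <- matrix(stacked, nrow = length(cols))
  w <- switch(mode,
    max = apply(stacked, 1, max),
    mean = rowMeans(stacked)
  )
  names(w) <- cols
  if (rescale) w <- w / max(w)
  structure(
    list(target_name = target_name, site = site, weights = w,
         n_complexes = length(vectors), mode = mode, rescaled = rescale),
    class = "contact_profile"
  )
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("<contact_profile> %s (%s site): %d columns, %d complex(es), mode=%s\n",
              x$target_name, x$site, length(x$weights), x$n_complexes, x$mode))
  invisible(x)
}

#' Serialize contact profiles to TSV
#' @param profiles list of `contact_profile` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  tabs <- lapply(profiles, function(p) {
    data.frame(target = p$target_name, site = p$site,
               column = as.integer(names(p$weights)),
               weight = as.numeric(p$weights))
  })
  write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
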