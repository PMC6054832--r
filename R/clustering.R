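# Average-linkage (UPGMA) agglomeration and Newick export.
#
# Heights follow the standard UPGMA convention height = merge distance/2,
# so cophenetic distances on ultrametric input reproduce the input
# exactly. Tie-breaking is lexicographic on the sorted leaf-name tuples
# of the candidate pair, for cross-platform determinism.

#' Average-linkage / UPGMA tree from a distance matrix
#'
#' Agglomerates with arithmetic-mean linkage (size-weighted
#' Lance-Williams update), i.e. the inter-cluster distance is the mean of
#' all cross-cluster pairwise input distances.
#'
#' @param dist_mat symmetric numeric matrix with zero diagonal and
#'   dimnames (or a `score_matrix_set`, whose `distance` stage is used).
#' @return object of class `pm_dendrogram`: list with `leaves` and
#'   `merges` (list of `list(a, b, height)` with `a`, `b` sorted leaf
#'   name vectors, `height` = merge distance / 2, non-decreasing).
#' @export
average_linkage_tree <- function(dist_mat) {
  if (inherits(dist_mat, "score_matrix_set")) dist_mat <- dist_mat$distance
  m <- as.matrix(dist_mat)
  diag(m) <- 0
  leaves <- rownames(m)
  if (is.null(leaves)) leaves <- paste0("L", seq_len(nrow(m)))
  if (anyDuplicated(leaves)) stop("duplicate leaf names")
  if (nrow(m) < 2) stop("need at least 2 leaves")
  if (!isTRUE(all.equal(m, t(m)))) stop("distance matrix not symmetric")
  nas <- which(!is.finite(m) & upper.tri(m), arr.ind = TRUE)
  if (nrow(nas)) {
    stop("non-finite distances for pairs: ",
         paste(sprintf("(%s,%s)", leaves[nas[, 1]], leaves[nas[, 2]]), collapse = ", "))
  }
  clusters <- lapply(leaves, function(l) l)  # member leaf names, sorted
  sizes <- rep(1L, length(leaves))
  d <- m
  merges <- list()
  while (length(clusters) > 1) {
    n <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        dij <- d[i, j]
        key <- paste(sort(c(paste(clusters[[i]], collapse = "|"),
                            paste(clusters[[j]], collapse = "|"))), collapse = "~")
        if (dij < best_d || (dij == best_d && key < best_key)) {
          best_d <- dij; best <- c(i, j); best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1]] <- list(
      a = clusters[[i]], b = clusters[[j]], height = best_d / 2
    )
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    # Lance-Williams UPGMA update against all remaining clusters
    others <- setdiff(seq_len(n), c(i, j))
    newrow <- (sizes[i] * d[i, others] + sizes[j] * d[j, others]) /
      (sizes[i] + sizes[j])
    keep <- others
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], newrow),
                c(newrow, 0))
    clusters <- c(clusters[keep], list(merged))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    d <- d2
  }
  structure(list(leaves = sort(leaves), merges = merges),
            class = "pm_dendrogram")
}

#' @export
print.pm_dendrogram <- function(x, ...) {
  cat(sprintf("<pm_dendrogram> %d leaves, %d merges, root height %.4g\n",
              length(x$leaves), length(x$merges),
              x$merges[[length(x$merges)]]$height))
  invisible(x)
}

newick_label <- function(name) {
  if (grepl("[](),:;'[ \t]", name)) {
    paste0("'", gsub("'", "''", name), "'")
  } else {
    name
  }
}

#' Export a dendrogram as a rooted Newick string
#'
#' Branch lengths are parent height minus child height (leaves at height
#' 0). Leaf names containing Newick-reserved characters are quoted.
#'
#' @param tree a `pm_dendrogram`.
#' @param path optional output file; when NULL only the string is
#'   returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  if (anyDuplicated(tree$leaves)) stop("duplicate leaf names")
  # rebuild nested structure from the merge list
  nodes <- lapply(tree$leaves, function(l) list(members = l, height = 0, text = newick_label(l)))
  names(nodes) <- tree$leaves
  keyof <- function(members) paste(members, collapse = "|")
  pool <- setNames(nodes, vapply(nodes, function(nd) keyof(nd$members), ""))
  fmt <- function(x) sprintf("%.*g", digits, x)
  for (mg in tree$merges) {
    ka <- keyof(mg$a); kb <- keyof(mg$b)
    a <- pool[[ka]]; b <- pool[[kb]]
    if (is.null(a) || is.null(b)) stop("inconsistent merge list")
    if (kb < ka) { tmp <- a; a <- b; b <- tmp }  # deterministic child order
    text <- sprintf("(%s:%s,%s:%s)",
                    a$text, fmt(mg$height - a$height),
                    b$text, fmt(mg$height - b$height))
    pool[[ka]] <- NULL; pool[[kb]] <- NULL
    members <- sort(c(mg$a, mg$b))
    pool[[keyof(members)]] <- list(members = members, height = mg$height, text = text)
  }
  if (length(pool) != 1) stop("merge list does not connect all leaves")
  out <- paste0(pool[[1]]$text, ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Distance between two leaves is twice the height of their lowest
#' common cluster.
#'
#' @param tree a `pm_dendrogram`.
#' @return symmetric matrix over the leaves.
#' @export
cophenetic_matrix <- function(tree) {
  n <- length(tree$leaves)
  m <- matrix(0, n, n, dimnames = list(tree$leaves, tree$leaves))
  for (mg in tree$merges) {
    m[mg$a, mg$b] <- m[mg$b, mg$a] <- 2 * mg$height
  }
  m
}

#' Merge table of a dendrogram as a data.frame
#' @param tree a `pm_dendrogram`.
#' @return data.frame with columns `cluster_a`, `cluster_b`, `height`.
#' @export
merges_table <- function(tree) {
  data.frame(
    cluster_a = vapply(tree$merges, function(m) paste(m$a, collapse = "|"), ""),
    cluster_b = vapply(tree$merges, function(m) paste(m$b, collapse = "|"), ""),
    height = vapply(tree$merges, function(m) m$height, 0),
    stringsAsFactors = FALSE
  )
}
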