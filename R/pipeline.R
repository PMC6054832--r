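# End-to-end orchestration: manifest + alignment in, fingerprints,
# summaries, contact profiles, similarity matrices, neighbor reports and
# Newick trees out. Fully deterministic for a given config and seed.

#' Assemble a pipeline configuration
#'
#' @param manifest path to a manifest TSV (columns `complex_id`, `path`,
#'   `chain`, `target`, `site`, `ligand_selector` (comma-separated),
#'   `alignment_row`) or an equivalent data.frame.
#' @param alignment path to the master alignment (aligned FASTA or
#'   Clustal) or a `master_alignment`.
#' @param output_dir artifact directory (created if needed).
#' @param seed integer seed recorded in metadata (the pipeline itself is
#'   deterministic; the seed also feeds any synthetic pre-steps).
#' @param ensemble_mode `"max"` or `"mean"` aggregation of complex
#'   contact vectors per target.
#' @param rescale_profiles rescale each profile's maximum weight to 1.
#' @param min_identity identity floor for structure-to-row mapping.
#' @param neighbor_k neighbors reported per target.
#' @param plif geometric criteria from [plif_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, alignment, output_dir,
                            seed = 1, ensemble_mode = "max",
                            rescale_profiles = TRUE, min_identity = 0.60,
                            neighbor_k = 10, plif = plif_config()) {
  structure(list(manifest = manifest, alignment = alignment,
                 output_dir = output_dir, seed = seed,
                 ensemble_mode = ensemble_mode,
                 rescale_profiles = rescale_profiles,
                 min_identity = min_identity, neighbor_k = neighbor_k,
                 plif = plif),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("manifest", "alignment", "output_dir")
  missing <- setdiff(required, names(raw))
  if (length(missing)) stop("config missing field(s): ", paste(missing, collapse = ", "))
  plif <- if (is.null(raw$plif)) plif_config() else do.call(plif_config, as.list(raw$plif))
  pipeline_config(
    manifest = raw$manifest, alignment = raw$alignment,
    output_dir = raw$output_dir,
    seed = if (is.null(raw$seed)) 1 else raw$seed,
    ensemble_mode = if (is.null(raw$ensemble_mode)) "max" else raw$ensemble_mode,
    rescale_profiles = if (is.null(raw$rescale_profiles)) TRUE else raw$rescale_profiles,
    min_identity = if (is.null(raw$min_identity)) 0.60 else raw$min_identity,
    neighbor_k = if (is.null(raw$neighbor_k)) 10 else raw$neighbor_k,
    plif = plif
  )
}

read_manifest <- function(manifest) {
  tab <- if (is.data.frame(manifest)) manifest else {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    read.delim(manifest, stringsAsFactors = FALSE)
  }
  required <- c("complex_id", "path", "chain", "target", "site",
                "ligand_selector", "alignment_row")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  absent <- tab$path[!file.exists(tab$path)]
  if (length(absent)) stop("manifest references missing file(s): ",
                           paste(absent, collapse = ", "))
  tab
}

stage <- function(name, id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed for '%s': %s", name, id, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pharmacological-mapping pipeline
#'
#' For each site present in the manifest: loads and maps every complex,
#' writes interaction fingerprints (TSV) and their summary (CSV), the
#' fingerprint-Tanimoto tree (Newick, average linkage on 1 - Tanimoto),
#' per-target ensemble contact profiles (TSV), every similarity-matrix
#' stage (CSV), neighbor reports (TSV) and the profile-based UPGMA tree
#' (Newick), plus a run-metadata JSON echoing every setting.
#'
#' @param config a `pipeline_config` or path to a JSON config file.
#' @return invisibly, a list per site with the in-memory objects and a
#'   `paths` vector of written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_manifest(config$manifest)
  aln <- if (inherits(config$alignment, "master_alignment")) config$alignment else
    stage("alignment", config$alignment, read_alignment(config$alignment))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  results <- list()
  all_paths <- character(0)
  for (site in unique(manifest$site)) {
    rows <- manifest[manifest$site == site, , drop = FALSE]
    out <- function(f) file.path(config$output_dir, paste0(site, "_", f))

    complexes <- list(); maps <- list(); fps <- list(); vectors <- list()
    dropped <- integer(0)
    for (r in seq_len(nrow(rows))) {
      id <- rows$complex_id[r]
      cx <- stage("load", id, load_complex(
        rows$path[r], rows$chain[r],
        strsplit(rows$ligand_selector[r], ",")[[1]],
        site = site, complex_id = id, target_name = rows$target[r]
      ))
      map <- stage("map", id, map_structure_to_columns(
        cx, aln, rows$alignment_row[r], min_identity = config$min_identity
      ))
      annot <- stage("plif", id, annotate_pharmacophores(cx))
      fp <- stage("plif", id, suppressMessages(
        detect_interactions(cx, annot, map, config$plif)
      ))
      vec <- stage("profile", id, suppressMessages(complex_contact_vector(cx, map)))
      dropped[id] <- attr(vec, "dropped_residues") %||% 0L
      complexes[[id]] <- cx; maps[[id]] <- map; fps[[id]] <- fp
      vectors[[id]] <- vec
    }

    write_fingerprints_tsv(fps, out("fingerprints.tsv"))
    grouping <- setNames(rows$target, rows$complex_id)
    summ <- summarize_interactions(fps)
    write.csv(summ$per_bit, out("interaction_summary.csv"), row.names = FALSE)
    write.csv(summ$per_type, out("interaction_types.csv"), row.names = FALSE)

    tan <- fingerprint_tanimoto_matrix(fps)
    write_matrix_csv(tan, out("plif_tanimoto.csv"))
    plif_tree_path <- NULL
    if (nrow(tan) >= 2) {
      plif_tree <- stage("tree", site, average_linkage_tree(1 - tan))
      plif_tree_path <- out("plif_tree.nwk")
      write_newick(plif_tree, plif_tree_path)
    }

    profiles <- list()
    for (tg in unique(rows$target)) {
      ids <- rows$complex_id[rows$target == tg]
      vv <- vectors[ids]
      vv <- vv[vapply(vv, length, 0L) > 0]
      if (!length(vv)) next
      profiles[[tg]] <- stage("profile", tg, ensemble_profile(
        vv, target_name = tg, site = site,
        mode = config$ensemble_mode, rescale = config$rescale_profiles
      ))
    }
    write_profiles_tsv(profiles, out("contact_profiles.tsv"))

    scores <- stage("score", site, score_matrix(aln, unname(profiles)))
    for (st in c("averaged", "normalized", "distance")) {
      write_matrix_csv(scores[[st]], out(paste0("scores_", st, ".csv")))
    }
    for (pn in names(scores$raw)) {
      write_matrix_csv(scores$raw[[pn]], out(paste0("scores_raw_", pn, ".csv")))
    }

    nb <- do.call(rbind, lapply(aln$names, function(tg) {
      cbind(target = tg, rank_neighbors(scores, tg, k = config$neighbor_k))
    }))
    write.table(nb, out("neighbors.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

    upgma <- stage("tree", site, average_linkage_tree(scores))
    write_newick(upgma, out("coinpocket_tree.nwk"))

    site_paths <- c(out("fingerprints.tsv"), out("interaction_summary.csv"),
                    out("interaction_types.csv"), out("plif_tanimoto.csv"),
                    plif_tree_path, out("contact_profiles.tsv"),
                    out("scores_averaged.csv"), out("scores_normalized.csv"),
                    out("scores_distance.csv"), out("neighbors.tsv"),
                    out("coinpocket_tree.nwk"))
    all_paths <- c(all_paths, site_paths)
    results[[site]] <- list(complexes = complexes, maps = maps, fps = fps,
                            profiles = profiles, scores = scores,
                            tanimoto = tan, tree = upgma,
                            dropped_residues = dropped, paths = site_paths)
  }

  meta <- list(
    package_version = as.character(packageVersion("pocketmap")),
    r_version = R.version.string,
    seed = config$seed,
    settings = list(
      ensemble_mode = config$ensemble_mode,
      rescale_profiles = config$rescale_profiles,
      min_identity = config$min_identity,
      neighbor_k = config$neighbor_k,
      plif = config$plif,
      contact_ramp = c(plateau = CONTACT_PLATEAU, cutoff = CONTACT_CUTOFF),
      zscore_population = "offdiagonal_upper_triangle",
      minmax_population = "offdiagonal_upper_triangle",
      upgma_height = "merge_distance_over_2"
    ),
    dropped_residues = lapply(results, function(r) as.list(r$dropped_residues)),
    sites = names(results)
  )
  jsonlite::write_json(meta, file.path(config$output_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
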