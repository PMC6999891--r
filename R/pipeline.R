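# Pipeline orchestration: classify -> neighbors -> per-image significance
# -> cohort scores -> networks -> diameters.  Stage outputs are files, so
# each stage is independently re-runnable and testable; the pipeline
# itself draws no random numbers, making reruns byte-identical.

#' Run the full cohort analysis pipeline
#'
#' Takes a cohort manifest (data frame or CSV path) pointing at cell
#' tables, or an in-memory list of datasets, and runs every stage in
#' order.  Per image: small-object filter, classification (when `pc` is
#' absent), class frequencies, nearest-neighbor table, significance
#' matrix.  Per diagnosis group (plus the pooled `"all"` group): score
#' matrix, preference network, diameter histogram; when the cohort
#' contains LA images, the disease histograms are background-corrected
#' against the pooled LA histogram.
#'
#' @param manifest manifest data frame / CSV path (see [read_manifest()]),
#'   or a named list of `image_dataset` objects.
#' @param config an [analysis_config()].
#' @param out_dir output directory for all artifact CSVs, or `NULL` to
#'   skip writing.
#' @return an object of class `run_report` (list): `images` (per-image
#'   frequencies, mean NN distance, significance matrix), `groups`
#'   (per-group score matrix, network, diameter analysis), `config`.
#' @export
run_pipeline <- function(manifest, config = analysis_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  log_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(out_dir, "run_log.txt")
    cat("", file = log_path)  # truncate
    log_stage(log_path, "config",
              sprintf(paste0("cutoff=%g alpha=%g bin=%g ref=[%g,%g) ",
                             "edge_fraction=%g thresholds={min_area=%g, ",
                             "area_large=%g, ecc=%g, solidity=%g}"),
                      config$max_neighbor_distance, config$alpha,
                      config$diameter_bin_width, config$reference_bin[1],
                      config$reference_bin[2],
                      config$network_edge_fraction,
                      config$thresholds$min_area,
                      config$thresholds$area_large,
                      config$thresholds$ecc_elongated,
                      config$thresholds$solidity_frayed))
  }
  # --- load ----------------------------------------------------------
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.data.frame(manifest)) {
    datasets <- list()
    for (r in seq_len(nrow(manifest))) {
      datasets[[manifest$image_id[r]]] <- tryCatch(
        read_cell_table(manifest$path[r], manifest$image_id[r],
                        manifest$diagnosis[r]),
        error = function(e) stop("stage load, image ",
                                 manifest$image_id[r], ": ",
                                 conditionMessage(e), call. = FALSE))
    }
  } else {
    stopifnot(is.list(manifest),
              all(vapply(manifest, inherits, logical(1), "image_dataset")))
    datasets <- manifest
    if (is.null(names(datasets))) {
      names(datasets) <- vapply(datasets, `[[`, character(1), "image_id")
    }
  }
  # --- per image -----------------------------------------------------
  images <- list()
  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", what, ", image ", id, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  for (id in names(datasets)) {
    ds <- datasets[[id]]
    ds <- stage("filter", id,
                filter_small_objects(ds, config$thresholds$min_area))
    if (anyNA(ds$cells$pc)) {
      ds <- stage("classify", id, classify_cells(ds, config$thresholds))
    }
    tab <- stage("neighbors", id,
                 nearest_neighbors(ds, config$max_neighbor_distance))
    sm <- stage("significance", id,
                significance_matrix(ds, tab, config$alpha))
    freqs <- class_frequencies(ds)
    nn <- if (nrow(tab) > 0L) mean_nn_distance(tab) else c(mean = NA_real_,
                                                           sd = NA_real_)
    images[[id]] <- list(dataset = ds, table = tab, significance = sm,
                         frequencies = freqs, nn_distance = nn)
    log_stage(log_path, "image", sprintf(
      "%s: %d cells, %d with neighbor (%d isolated), mean NN %.1f um",
      id, nrow(ds$cells), nrow(tab), attr(tab, "excluded_isolated"),
      nn["mean"]))
    if (!is.null(out_dir)) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      write_cell_table(ds, file.path(img_dir,
                                     paste0("image_", id, "_cells.csv")))
      write_nbr_table(tab, file.path(img_dir,
                                     paste0("image_", id, "_nbr.csv")))
      write_significance_matrix(sm, img_dir)
    }
  }
  # --- per group -----------------------------------------------------
  diagnoses <- vapply(images, function(im) im$dataset$diagnosis,
                      character(1))
  groups <- list()
  la_hist <- NULL
  la_ids <- names(images)[diagnoses == "LA"]
  if (length(la_ids) > 0L) {
    la_d <- unlist(lapply(la_ids,
                          function(id) images[[id]]$dataset$cells$feret_um))
    la_hist <- diameter_histogram(la_d, config$diameter_bin_width)
  }
  group_ids <- c(stats::setNames(lapply(unique(diagnoses), function(dg) {
    names(images)[diagnoses == dg]
  }), unique(diagnoses)), list(all = names(images)))
  for (gname in names(group_ids)) {
    ids <- group_ids[[gname]]
    sms <- lapply(ids, function(id) images[[id]]$significance)
    scm <- score_matrix(sms, gname)
    net <- build_network(scm, config$network_edge_fraction)
    d <- unlist(lapply(ids,
                       function(id) images[[id]]$dataset$cells$feret_um))
    hist <- diameter_histogram(d, config$diameter_bin_width)
    corrected <- NULL
    if (!is.null(la_hist) && gname %in% c("NScHL", "MCcHL")) {
      corrected <- background_correction(hist, la_hist,
                                         config$reference_bin)
    }
    groups[[gname]] <- list(score = scm, network = net,
                            diameters = hist, corrected = corrected)
    log_stage(log_path, "group", sprintf(
      "%s: %d images, %d network edge(s)%s", gname, scm$n_images,
      nrow(net$edges),
      if (!is.null(corrected))
        sprintf(", HRS proportion %.3f", corrected$proportion) else ""))
    if (!is.null(out_dir)) {
      grp_dir <- file.path(out_dir, "groups")
      dir.create(grp_dir, showWarnings = FALSE)
      stem <- file.path(grp_dir, gname)
      write_matrix(scm$score, paste0(stem, "_score.csv"))
      write_matrix(scm$percent, paste0(stem, "_percent.csv"))
      export_network(net, paste0(stem, "_network.dot"), "dot")
      export_network(net, paste0(stem, "_network.graphml"), "graphml")
      write_histogram(hist, paste0(stem, "_diameters.csv"))
      if (!is.null(corrected)) {
        write_histogram(corrected, paste0(stem, "_diameters_corrected.csv"))
      }
    }
  }
  structure(list(images = images, groups = groups, config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", length(x$images), "image(s),",
      length(x$groups), "group(s)\n")
  for (gname in names(x$groups)) {
    g <- x$groups[[gname]]
    cat(sprintf("  %s: %d images, %d edge(s)%s\n", gname,
                g$score$n_images, nrow(g$network$edges),
                if (!is.null(g$corrected))
                  sprintf(", HRS proportion %.3f",
                          g$corrected$proportion) else ""))
  }
  invisible(x)
}
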