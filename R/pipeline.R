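# End-to-end screen driver: images -> per-object labels -> well metrics
# -> condition summaries -> vehicle-normalized hit table -> statistics.

#' Run the full screen pipeline
#'
#' Scores every image in the manifest with [analyze_snapshot()], pools
#' object labels per well (the well is the statistical unit; snapshots
#' and rounds pool into one count vector), applies the well exclusion
#' rule, normalizes condition means to the vehicle and calls hits, and
#' compares conditions against the control when one is designated.
#'
#' @param manifest data.frame with columns `file`, `condition`, `well`
#'   (optionally `round`, `snapshot`), as written by [generate_screen()].
#' @param plate_map data.frame with `well`, `condition`, `role`
#'   (`control` / `vehicle` / `drug`).
#' @param network A `trained_network` or checkpoint path.
#' @param params A [detection_params()].
#' @param metric `"coiled"`, `"coiled_curled"` or `"all"`.
#' @param well Optional `well_circle` for all images.
#' @param out_dir Optional directory for result CSV/JSON files.
#' @param hit_threshold Hit cutoff in percent of vehicle.
#' @return List: `objects` (all scored objects), `well_table`,
#'   `summaries`, `screen_table`, `comparisons` (or `NULL`).
#' @export
run_pipeline <- function(manifest, plate_map, network,
                         params = detection_params(), metric = "coiled",
                         well = NULL, out_dir = NULL, hit_threshold = 50) {
  if (is.character(network)) network <- load_network(network)
  missing <- manifest$file[!file.exists(manifest$file)]
  if (length(missing))
    stop("missing input images: ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  objects <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- analyze_snapshot(manifest$file[i], network, params, well)
    if (nrow(res) == 0) next
    res$condition <- manifest$condition[i]
    res$well <- manifest$well[i]
    res$round <- if ("round" %in% names(manifest)) manifest$round[i] else 1L
    res$snapshot <- if ("snapshot" %in% names(manifest))
      manifest$snapshot[i] else i
    objects[[length(objects) + 1]] <- as.data.frame(res)
  }
  objects <- if (length(objects)) do.call(rbind, objects) else
    stop("no objects detected in any image")
  well_table <- summarize_wells(objects)
  summaries <- condition_summary(well_table, metric)
  roles <- plate_map[!duplicated(plate_map$condition),
                     c("condition", "role")]
  summaries <- merge(summaries, roles, by = "condition", all.x = TRUE)
  vehicle <- summaries[summaries$role == "vehicle", ][1, ]
  screen_table <- if (!is.na(vehicle$condition)) {
    normalize_screen(summaries[summaries$role == "drug", , drop = FALSE],
                     vehicle, hit_threshold)
  } else NULL
  comparisons <- NULL
  ctrl <- summaries$condition[summaries$role == "control"][1]
  if (!is.na(ctrl) && nrow(summaries) >= 2) {
    groups <- summaries$values
    names(groups) <- summaries$condition
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) >= 2 && ctrl %in% names(groups))
      comparisons <- tryCatch(compare_conditions(groups, control = ctrl),
                              error = function(e) {
                                warning("group comparison skipped: ",
                                        conditionMessage(e))
                                NULL
                              })
  }
  out <- list(objects = objects, well_table = well_table,
              summaries = summaries, screen_table = screen_table,
              comparisons = comparisons)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(objects, file.path(out_dir, "objects.csv"), row.names = FALSE)
    write.csv(well_table, file.path(out_dir, "well_table.csv"),
              row.names = FALSE)
    if (!is.null(screen_table))
      write.csv(screen_table, file.path(out_dir, "screen_table.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(conditions = summaries[, c("condition", "mean", "sd",
                                      "n_wells", "n_worms")],
           hits = if (!is.null(screen_table))
             screen_table$condition[screen_table$hit] else character()),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
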