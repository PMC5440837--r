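# End-to-end orchestration: dock-and-score, co-localization batches, BiFC
# batches. Each run can write machine-readable artifacts plus a manifest
# (config + seed + package version) sufficient to reproduce it.

.write_manifest <- function(cfg, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(command = name, config = cfg,
                   package = "groovedock",
                   version = as.character(utils::packageVersion("groovedock")))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}

#' Run template-guided docking and interface scoring
#'
#' Executes [template_guided_dock()] and then scores the pose with
#' [buried_area()], [contact_pairs()] and [groove_lining()]. Structures may be
#' given in-memory or as PDB paths.
#'
#' @param cfg list with elements `template`, `query`, `receptor`
#'   ([structure3d()] or PDB paths), `filler` and `target_m4`
#'   ([helix_segment()]), and optionally `step` (default 1), `clash_cutoff`
#'   (default 2.5), `hard_ceiling` (default 25), `sasa` (a [sasa_params()]),
#'   `out_dir`.
#' @return list with `dock` (a `dock_result` whose `buried_area` is filled
#'   in) and `interface` (an `interface_result` with contacts and
#'   groove-lining labels).
#' @export
run_dock_and_score <- function(cfg) {
  need <- function(x) if (is.null(cfg[[x]]))
    stop_gd("config lacks '%s'", x, class = "groovedock_config_error") else cfg[[x]]
  as_struct <- function(x) if (inherits(x, "structure3d")) x else read_pdb(x)
  template <- as_struct(need("template"))
  query <- as_struct(need("query"))
  receptor <- as_struct(need("receptor"))
  dk <- template_guided_dock(template, need("filler"), query, receptor,
                             need("target_m4"),
                             step = cfg$step %||% 1,
                             p = clash_params(cfg$clash_cutoff %||% 2.5),
                             hard_ceiling = cfg$hard_ceiling %||% 25)
  sp <- cfg$sasa %||% sasa_params()
  iface <- buried_area(dk$query_docked, receptor, sp)
  iface$contacts <- contact_pairs(dk$query_docked, receptor)
  iface$groove_lining <- tryCatch(
    groove_lining(dk$query_docked,
                  select_atoms(receptor, cfg$target_m4$chain, cfg$target_m4)),
    error = function(e) NULL)
  dk$buried_area <- iface$buried_area
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pdb(dk$query_docked, file.path(out_dir, "query_docked.pdb"))
    jsonlite::write_json(
      list(best_angle = dk$best_angle, clash_count = dk$clash_count,
           rotation = as.numeric(t(dk$transform$R)),
           translation = dk$transform$t,
           buried_area = iface$buried_area,
           scan = dk$scan, contacts = iface$contacts,
           groove_lining = iface$groove_lining),
      file.path(out_dir, "dock_result.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_manifest(cfg[setdiff(names(cfg), c("template", "query", "receptor"))],
                    out_dir, "dock")
  }
  list(dock = dk, interface = iface)
}

#' Run a co-localization batch
#'
#' Computes per-cell thresholded PCCs, per-group mean +/- s.e.m., a
#' Kruskal-Wallis test with Dunn's post hoc when three or more groups are
#' present, and per-group cumulative-frequency (empirical CDF) tables for
#' plotting.
#'
#' @param cfg list with `cells` (list of [two_channel_image()] or of lists
#'   with `ch1`/`ch2` matrices), `groups` (group label per cell), and
#'   optionally `rule`, `n_steps` (see [thresholded_pcc()]), `out_dir`.
#' @return list with `per_cell` (data.frame), `summary` (see
#'   [summarize_groups()]) and `cdf` (data.frame group, pcc, cumfreq).
#' @export
run_coloc_batch <- function(cfg) {
  cells <- cfg$cells
  groups <- cfg$groups
  if (is.null(cells) || is.null(groups) || length(cells) != length(groups))
    stop_gd("config needs 'cells' and matching 'groups'",
            class = "groovedock_config_error")
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    img <- cells[[i]]
    if (!inherits(img, "two_channel_image"))
      img <- two_channel_image(img$ch1, img$ch2, img$mask)
    r <- tryCatch(thresholded_pcc(img, rule = cfg$rule %||% "both",
                                  n_steps = cfg$n_steps %||% 256),
                  error = function(e) e)
    if (inherits(r, "error")) {
      warning(sprintf("cell %d skipped: %s", i, conditionMessage(r)))
      next
    }
    rows[[i]] <- data.frame(cell = i, group = groups[i], t1 = r$t1, t2 = r$t2,
                            pcc = r$pcc, n_pixels = r$n_pixels_used,
                            stringsAsFactors = FALSE)
  }
  per_cell <- do.call(rbind, rows)
  split_pcc <- split(per_cell$pcc, per_cell$group)
  if (any(!unique(groups) %in% names(split_pcc)))
    stop_gd("group(s) with no scoreable cells: %s",
            paste(setdiff(unique(groups), names(split_pcc)), collapse = ", "),
            class = "groovedock_data_error")
  summ <- summarize_groups(split_pcc)
  cdf <- do.call(rbind, lapply(names(split_pcc), function(g) {
    v <- sort(split_pcc[[g]])
    data.frame(group = g, pcc = v, cumfreq = seq_along(v) / length(v),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(per_cell, file.path(cfg$out_dir, "pcc_per_cell.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(summ$table, file.path(cfg$out_dir, "pcc_groups.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cdf, file.path(cfg$out_dir, "pcc_cdf.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    .write_manifest(cfg[setdiff(names(cfg), "cells")], cfg$out_dir, "coloc")
  }
  list(per_cell = per_cell, summary = summ, cdf = cdf)
}

#' Run a BiFC batch
#'
#' @param cfg list with `records` (data.frame or TSV path with columns
#'   cell_id, group, background, cy3, venus), `control_group`, and optionally
#'   `factor` (default 3.5), `out_dir`.
#' @return a `bifc_result`.
#' @export
run_bifc_batch <- function(cfg) {
  rec <- cfg$records
  if (is.null(rec) || is.null(cfg$control_group))
    stop_gd("config needs 'records' and 'control_group'",
            class = "groovedock_config_error")
  if (is.character(rec))
    rec <- utils::read.table(rec, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  res <- bifc_pipeline(rec, cfg$control_group, cfg$factor %||% 3.5)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$records, file.path(cfg$out_dir, "bifc_cells.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(group_table = res$group_table, factor = res$factor,
           welch = list(F = res$test$statistic, df = res$test$df, p = res$test$p)),
      file.path(cfg$out_dir, "bifc_result.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_manifest(cfg[setdiff(names(cfg), "records")], cfg$out_dir, "bifc")
  }
  res
}
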