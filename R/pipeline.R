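#' Run manifest
#'
#' A manifest pins everything a pipeline run depends on: the detection CSV
#' inputs (processed in lexicographic path order, for determinism), the
#' design, the analysis parameters and the output directory.  Re-running the
#' same manifest reproduces byte-identical outputs; the only randomness in
#' the system lives in the simulator and flows from explicit seeds.
#'
#' @param detections character vector of detection CSV paths (or a directory,
#'   expanded to its \code{*.csv} files).
#' @param out_dir output directory for the report bundle.
#' @param design an \code{\link{epc_design}} or path to a design YAML.
#' @param fps capture fps of the input streams.
#' @param downsample_factor decimation applied on ingestion (default 2:
#'   30 fps footage analyzed at 15 fps).
#' @param k unrest proportionality factor.
#' @param empty_policy unrest empty-frame policy.
#' @param edge_mode,edge_margin duplicate-suppression policy (see
#'   \code{\link{edge_policy}}).
#' @param alpha significance level for the treatment comparisons.
#' @return a \code{run_manifest} list.
#' @export
run_manifest <- function(detections, out_dir, design = epc_design(),
                         fps = 30, downsample_factor = 2L, k = 1,
                         empty_policy = "missing", edge_mode = "off",
                         edge_margin = 20, alpha = 0.05) {
  if (length(detections) == 1 && dir.exists(detections))
    detections <- list.files(detections, pattern = "\\.csv$",
                             full.names = TRUE)
  if (is.character(design)) design <- read_design(design)
  structure(list(detections = sort(detections), out_dir = out_dir,
                 design = design, fps = fps,
                 downsample_factor = as.integer(downsample_factor),
                 k = k, empty_policy = empty_policy, edge_mode = edge_mode,
                 edge_margin = edge_margin, alpha = alpha),
            class = "run_manifest")
}

#' Read a run manifest from YAML
#'
#' @param path YAML file with the fields of \code{\link{run_manifest}}
#'   (\code{design} as a path, resolved relative to the manifest file).
#' @return a \code{run_manifest}.
#' @export
read_manifest <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  design <- if (is.null(cfg$design)) epc_design() else read_design(rel(cfg$design))
  run_manifest(detections = rel(unlist(cfg$detections)),
               out_dir = rel(cfg$out_dir),
               design = design,
               fps = cfg$fps %||% 30,
               downsample_factor = cfg$downsample_factor %||% 2L,
               k = cfg$k %||% 1,
               empty_policy = cfg$empty_policy %||% "missing",
               edge_mode = cfg$edge_mode %||% "off",
               edge_margin = cfg$edge_margin %||% 20,
               alpha = cfg$alpha %||% 0.05)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

write_stage_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole chain on a manifest: ingest every detection CSV
#' (lexicographic order), down-sample, optionally suppress doorway
#' duplicates, compute the unrest series and window-level aggregation, the
#' per-frame counts and permanence times, then compare treatments (one-way
#' ANOVA + Tukey + letters across lights within each temperature for unrest;
#' factorial ANOVA plus the same per-temperature comparisons for
#' permanence).  Writes \code{unrest.csv}, \code{permanence.csv},
#' \code{anova.csv}, \code{tukey.csv}, \code{letters.csv} and
#' \code{summary.json} into the manifest's output directory and logs
#' per-stage record counts to \code{stderr} so filtering losses stay
#' auditable.
#'
#' An empty input set is not an error: the run writes an explicit
#' \code{"no data"} summary and header-only tables, and returns normally.
#' Statistical comparisons that lack replication are skipped with a note in
#' the summary rather than fabricated.
#'
#' @param manifest a \code{\link{run_manifest}} or path to a manifest YAML.
#' @param quiet suppress the stage log.
#' @return invisibly, a list with the unrest aggregation, permanence table,
#'   comparison tables and the summary structure.
#' @export
run_pipeline <- function(manifest, quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  outputs <- c(unrest = "unrest.csv", permanence = "permanence.csv",
               anova = "anova.csv", tukey = "tukey.csv",
               letters = "letters.csv")
  out_path <- function(nm) file.path(manifest$out_dir, outputs[[nm]])

  if (length(manifest$detections) == 0) {
    log_("no input files: writing empty report")
    for (nm in names(outputs)) writeLines("no_data", out_path(nm))
    summary <- list(status = "no data", inputs = character(0))
    jsonlite::write_json(summary, file.path(manifest$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(summary = summary)))
  }

  streams <- stage("ingest", lapply(manifest$detections, function(p) {
    s <- read_detection_csv(p, fps = manifest$fps)
    log_("ingest: %s -> %d box records", basename(p), sum(!is.na(s$x_min)))
    s
  }))
  streams <- stage("downsample", lapply(streams, function(s)
    if (manifest$downsample_factor > 1)
      downsample(s, manifest$downsample_factor) else s))
  if (manifest$edge_mode == "suppress")
    streams <- stage("resolve_duplicates", lapply(streams, function(s)
      resolve_duplicates(s, edge_policy(manifest$edge_margin, "suppress"))))

  params <- unrest_params(k = manifest$k,
                          empty_frame_policy = manifest$empty_policy)
  series <- stage("unrest", do.call(rbind, lapply(streams, unrest_series,
                                                  params = params)))
  log_("unrest: %d frame pairs (%d missing)", nrow(series),
       sum(is.na(series$value)))
  unrest_agg <- stage("aggregate_unrest",
                      aggregate_unrest(series, manifest$design))

  counts <- stage("counts", do.call(rbind, lapply(streams, function(s) {
    fc <- frame_counts(s)
    attr_fps <- attr(fc, "effective_fps")
    out <- annotate_treatments(as.data.frame(fc), manifest$design)
    structure(out, effective_fps = attr_fps)
  })))
  eff_fps <- manifest$fps / manifest$downsample_factor
  flock <- attr(manifest$design, "flock_size") %||% 6
  perm <- stage("permanence",
                occupancy_fractions(permanence_time(counts, fps = eff_fps,
                                                    flock_size = flock)))
  log_("permanence: %d treatment cells", nrow(perm))

  comparisons <- stage("inference", compare_treatments(
    unrest_agg$windows, permanence_units(counts, fps = eff_fps),
    alpha = manifest$alpha))

  stage("report", {
    write_stage_csv(unrest_agg$windows, out_path("unrest"))
    write_stage_csv(as.data.frame(perm), out_path("permanence"))
    write_stage_csv(comparisons$anova, out_path("anova"))
    write_stage_csv(comparisons$tukey, out_path("tukey"))
    write_stage_csv(comparisons$letters, out_path("letters"))
  })
  summary <- list(
    status = "ok",
    inputs = basename(manifest$detections),
    parameters = list(fps = manifest$fps,
                      downsample_factor = manifest$downsample_factor,
                      effective_fps = eff_fps, k = manifest$k,
                      empty_policy = manifest$empty_policy,
                      edge_mode = manifest$edge_mode, alpha = manifest$alpha),
    version = as.character(packageVersion("chamberpref")),
    n_frame_pairs = nrow(series),
    n_cells = nrow(perm),
    skipped_comparisons = comparisons$skipped,
    outputs = as.list(outputs))
  jsonlite::write_json(summary, file.path(manifest$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(unrest = unrest_agg, permanence = perm,
                 comparisons = comparisons, summary = summary))
}

# Treatment comparisons shared by the pipeline: per-temperature one-way
# Tukey across lights for both responses, plus a factorial ANOVA for each
# response when the layout is balanced.
compare_treatments <- function(unrest_windows, permanence_units_df,
                               alpha = 0.05) {
  anova_rows <- list(); tukey_rows <- list(); letter_rows <- list()
  skipped <- character(0)
  responses <- list(
    unrest = data.frame(light = unrest_windows$light,
                        temperature = unrest_windows$temperature,
                        value = unrest_windows$mean_unrest_px),
    permanence = data.frame(light = permanence_units_df$light,
                            temperature = permanence_units_df$temperature,
                            value = permanence_units_df$T_bird_seconds))
  for (resp in names(responses)) {
    d <- responses[[resp]]
    tab <- table(d$light, d$temperature)
    if (all(tab >= 2) && length(unique(as.vector(tab))) == 1 &&
        nrow(tab) > 1 && ncol(tab) > 1) {
      an <- two_way_anova(d)
      anova_rows[[length(anova_rows) + 1]] <-
        cbind(response = resp, scope = "factorial", an)
    } else skipped <- c(skipped, paste0(resp, ": factorial (unbalanced or unreplicated)"))
    for (temp in unique(d$temperature)) {
      dd <- d[d$temperature == temp, ]
      grp <- split(dd$value, dd$light)
      if (length(grp) < 2 || any(vapply(grp, length, 0L) < 2)) {
        skipped <- c(skipped, paste0(resp, "/", temp, ": too few replicates"))
        next
      }
      ow <- one_way_anova(grp)
      anova_rows[[length(anova_rows) + 1]] <- data.frame(
        response = resp, scope = paste0("lights@", temp),
        term = "light", df = ow$df_between, sum_sq = NA_real_,
        mean_sq = NA_real_, f = ow$f, p = ow$p)
      tk <- tukey_hsd(grp, alpha = alpha)
      tukey_rows[[length(tukey_rows) + 1]] <-
        cbind(response = resp, temperature = temp, as.data.frame(tk))
      ld <- letter_display(tk)
      letter_rows[[length(letter_rows) + 1]] <- data.frame(
        response = resp, temperature = temp, group = names(ld),
        letters = as.character(ld))
    }
  }
  empty_an <- data.frame(response = character(0), scope = character(0),
                         term = character(0), df = numeric(0),
                         sum_sq = numeric(0), mean_sq = numeric(0),
                         f = numeric(0), p = numeric(0))
  list(anova = if (length(anova_rows)) do.call(rbind, anova_rows) else empty_an,
       tukey = if (length(tukey_rows)) do.call(rbind, tukey_rows) else
         data.frame(response = character(0), temperature = character(0)),
       letters = if (length(letter_rows)) do.call(rbind, letter_rows) else
         data.frame(response = character(0), temperature = character(0),
                    group = character(0), letters = character(0)),
       skipped = skipped)
}
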