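# End-to-end orchestration: truncate -> ratemaps -> MFR-change classifier ->
# speed tuning -> population vectors, with every analysis parameter surfaced
# in one configuration object and recorded alongside the outputs.

#' Pipeline configuration
#'
#' Collects every analysis parameter in one place; the defaults are the
#' pipeline's reference values (765 s window, 10 blocks, alpha 0.05, 3 cm
#' spatial bins, 7 cm smoothing kernel, 0.4 s population-vector bins,
#' 5-55 cm/s speed-analysis bins). Every override is recorded in the run
#' log written by [run_pipeline()].
#'
#' @param t_max Analysis window, seconds. Default 765.
#' @param n_blocks Blocks per session for the MFR classifier. Default 10.
#' @param alpha Significance threshold for all tests. Default 0.05.
#' @param spatial_bin_cm Ratemap bin side, cm. Default 3.
#' @param smooth_kernel_cm Ratemap smoothing kernel span, cm. Default 7.
#' @param pv_bin_s Population-vector bin width, seconds. Default 0.4.
#' @param speed_smooth_frames Boxcar width for speed estimation. Default 5.
#' @param min_speed_occupancy_s Minimum occupancy for a speed bin. Default 1.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(t_max = 765, n_blocks = 10, alpha = 0.05,
                            spatial_bin_cm = 3, smooth_kernel_cm = 7,
                            pv_bin_s = 0.4, speed_smooth_frames = 5,
                            min_speed_occupancy_s = 1) {
  structure(list(t_max = t_max, n_blocks = n_blocks, alpha = alpha,
                 spatial_bin_cm = spatial_bin_cm,
                 smooth_kernel_cm = smooth_kernel_cm,
                 pv_bin_s = pv_bin_s,
                 speed_smooth_frames = speed_smooth_frames,
                 min_speed_occupancy_s = min_speed_occupancy_s),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a triplet
#'
#' Executes, in order: truncation to the common window (done by the triplet
#' loader), per-cell MFR-change classification, per-cell speed-tuning
#' classification, population-vector correlation analysis, and optionally
#' smoothed ratemaps. Writes per-cell CSVs, a population summary JSON and a
#' plain-text report into `out_dir`; the run log records the configuration
#' used. Outputs are a pure function of (triplet, config).
#'
#' @param trip A `session_triplet`, or a path to a triplet `manifest.json`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created). `NULL` skips all file output
#'   and just returns results.
#' @param ratemaps If `TRUE`, per-cell smoothed ratemap grids are written as
#'   CSVs under `out_dir/ratemaps/`. Default `FALSE` (they are large).
#' @return List with `classifications` (data.frame), `summary` (population
#'   summary list), `speed` (data.frame: cell_id, p per session,
#'   speed_sensitive, category), `pv` (a `pv_correlation_set`), `config`.
#' @export
run_pipeline <- function(trip, config = pipeline_config(), out_dir = NULL,
                         ratemaps = FALSE) {
  if (is.character(trip)) trip <- load_triplet(trip, t_max = config$t_max)
  stopifnot(inherits(trip, "session_triplet"),
            inherits(config, "pipeline_config"))
  if (length(trip$cell_roster) == 0)
    stop("pipeline requires a nonempty cell roster")
  cls <- classify_triplet(trip, alpha = config$alpha,
                          n_blocks = config$n_blocks)
  summ <- summarize_population(cls, trip$manipulation_type)
  spd <- lapply(trip$cell_roster, function(id)
    classify_speed_cell(trip, id, alpha = config$alpha,
                        smooth_frames = config$speed_smooth_frames))
  speed_df <- data.frame(
    cell_id = vapply(spd, `[[`, character(1), "cell_id"),
    p_pre = vapply(spd, function(x) x$p[["pre"]], numeric(1)),
    p_manip = vapply(spd, function(x) x$p[["manip"]], numeric(1)),
    p_post = vapply(spd, function(x) x$p[["post"]], numeric(1)),
    speed_sensitive = vapply(spd, `[[`, logical(1), "speed_sensitive"),
    category = vapply(spd, `[[`, character(1), "category"),
    stringsAsFactors = FALSE)
  sets <- pv_correlation_sets(trip, bin_s = config$pv_bin_s)
  pv <- compare_correlation_distributions(sets)
  res <- list(classifications = cls, summary = summ, speed = speed_df,
              pv = pv, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cls, file.path(out_dir, "classifications.csv"),
                     row.names = FALSE)
    utils::write.csv(speed_df, file.path(out_dir, "speed_tuning.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summ, file.path(out_dir, "population_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(config), file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(pipeline_report(res), file.path(out_dir, "report.txt"))
    if (ratemaps) {
      rd <- file.path(out_dir, "ratemaps")
      dir.create(rd, showWarnings = FALSE)
      for (id in trip$cell_roster) {
        for (sn in c("pre", "manip", "post")) {
          s <- trip[[sn]]
          rm <- smooth_ratemap(
            compute_ratemap(s$spikes[[id]], s$trace, s$arena,
                            bin_size = config$spatial_bin_cm),
            kernel_cm = config$smooth_kernel_cm)
          utils::write.csv(rm$rate,
                           file.path(rd, paste0(id, "_", sn, ".csv")),
                           row.names = FALSE)
        }
      }
    }
  }
  res
}

# human-readable population report
pipeline_report <- function(res) {
  s <- res$summary
  spd <- res$speed
  sig <- res$classifications$label != "none"
  c(sprintf("MFR-change classification (%s manipulation, n = %d cells)",
            s$manipulation_type, s$n_total),
    sprintf("  significant change: %d (%.1f%%)", s$n_significant,
            s$pct_significant),
    sprintf("  increase: %d (%.1f%% of all; %.1f%% of significant)",
            s$n_increase, s$pct_increase,
            ifelse(is.na(s$pct_increase_of_significant), 0,
                   s$pct_increase_of_significant)),
    sprintf("  decrease: %d (%.1f%% of all; %.1f%% of significant)",
            s$n_decrease, s$pct_decrease,
            ifelse(is.na(s$pct_decrease_of_significant), 0,
                   s$pct_decrease_of_significant)),
    sprintf("  mean |delta|: increase %.2f, decrease %.2f spikes/s",
            s$mean_delta_increase, s$mean_delta_decrease),
    "",
    sprintf("Speed tuning: %d/%d (%.1f%%) speed-sensitive in >= 1 session",
            sum(spd$speed_sensitive), nrow(spd),
            100 * mean(spd$speed_sensitive)),
    sprintf("  among MFR-change cells: %d/%d speed-sensitive",
            sum(spd$speed_sensitive[sig]), sum(sig)),
    "",
    "Population vector correlations (median r):",
    sprintf("  %-13s %.3f (n = %d)", res$pv$labels, res$pv$medians,
            res$pv$n),
    sprintf("  omnibus H = %.1f, p = %.3g", res$pv$omnibus$H,
            res$pv$omnibus$p))
}
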