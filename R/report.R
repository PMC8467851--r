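# Run orchestration and report outputs: full-network assessment to CSV /
# GeoJSON, per-segment profiles, and the audit dump of model constants.

#' Run a full assessment and write report artifacts
#'
#' Assesses every segment over the 24 periods and writes `risk.csv` (one
#' row per segment-period with every risk-record field), `summary.csv`
#' (per-segment maxima/means, worst period, over-capacity flags), a JSON
#' run manifest (input hashes, constants, package version), and optionally
#' a GeoJSON with per-segment risk summaries as feature properties.
#'
#' @param network A [road_network()] or a path loadable by
#'   [load_network()].
#' @param scenario A [release_scenario()].
#' @param stability A [stability_parameters()] or a class letter for
#'   [pasquill_gifford()].
#' @param out_dir Output directory, created if missing.
#' @param config An [assessment_config()].
#' @param geojson Write `risk.geojson` with summary properties?
#' @return Invisibly, the assessment data.frame.
#' @export
run_assessment <- function(network, scenario, stability = "D",
                           out_dir = ".", config = assessment_config(),
                           geojson = FALSE) {
  net_path <- NULL
  if (is.character(network)) {
    net_path <- network
    network <- load_network(network)
  }
  if (is.character(stability)) stability <- pasquill_gifford(stability)
  records <- assess_network(network, scenario, stability, config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  num_cols <- vapply(records, is.numeric, logical(1)) &
    !names(records) %in% "period"
  rec_out <- records
  rec_out[num_cols] <- lapply(rec_out[num_cols], fmt_num)
  utils::write.csv(rec_out, file.path(out_dir, "risk.csv"),
                   row.names = FALSE, quote = TRUE)
  summ <- rank_segments(records)
  summ_out <- summ
  nc <- vapply(summ_out, is.numeric, logical(1)) &
    !grepl("period", names(summ_out))
  summ_out[nc] <- lapply(summ_out[nc], fmt_num)
  utils::write.csv(summ_out, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = TRUE)
  manifest <- list(
    package = "hazmatrisk",
    version = as.character(utils::packageVersion("hazmatrisk")),
    generated = "run manifest",
    network_file = if (!is.null(net_path))
      list(path = net_path,
           md5 = unname(tools::md5sum(net_path))) else "in-memory",
    n_segments = length(network$segments),
    n_records = nrow(records),
    scenario = unclass(scenario),
    stability = unclass(stability),
    constants = model_constants())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  if (geojson) {
    nd <- network$nodes
    feats <- lapply(names(network$segments), function(id) {
      s <- network$segments[[id]]
      srow <- summ[summ$segment_id == id, ]
      xy <- function(nid) {
        r <- nd[nd$id == nid, ]
        c(if (is.na(r$x)) 0 else r$x, if (is.na(r$y)) 0 else r$y)
      }
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = list(xy(s$from), xy(s$to))),
           properties = as.list(srow))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         file.path(out_dir, "risk.geojson"),
                         auto_unbox = TRUE, digits = I(17))
  }
  invisible(records)
}

#' 24-period profile report for one segment
#'
#' @param records Output of [assess_network()].
#' @param segment_id Canonical segment id (see [segment_id()]).
#' @param plot_file Optional PNG path: plots P(t), consequences and risk
#'   scores over the 24 periods.
#' @return 24-row data.frame for the segment, ordered by period.
#' @export
segment_profile <- function(records, segment_id, plot_file = NULL) {
  rows <- records[records$segment_id == segment_id, ]
  if (!nrow(rows)) {
    stop(sprintf("unknown segment '%s'", segment_id), call. = FALSE)
  }
  rows <- rows[order(rows$period), ]
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    graphics::plot(rows$period, rows$p_leak, type = "b", pch = 16,
                   xlab = "period (h)", ylab = "P(t)",
                   main = paste("leakage probability", segment_id))
    graphics::plot(rows$period, rows$c_pop, type = "b", pch = 16,
                   xlab = "period (h)", ylab = "C_pop(t)",
                   main = "population consequence")
    graphics::plot(rows$period, rows$c_env, type = "b", pch = 16,
                   xlab = "period (h)", ylab = "C_env(t)",
                   main = "environmental consequence")
    graphics::matplot(rows$period, cbind(rows$er_pop, rows$er_env),
                      type = "b", pch = 16, lty = 1,
                      xlab = "period (h)", ylab = "ER(t)",
                      main = "risk scores")
    graphics::legend("topright", c("ER_pop", "ER_env"), col = 1:2, pch = 16)
  }
  rows
}

#' Dump every numeric model constant
#'
#' Auditability hook: the probability tables, piecewise preference
#' breakpoints and values, geometric coefficients, the bearing-area width,
#' the friction-velocity bounds and unit-conversion factors, as one nested
#' list (serializable to JSON).
#'
#' @return Named list of constants.
#' @export
model_constants <- function() {
  list(
    accident_rate_table = truck_accident_rates(),
    leakage_conditional_table = leakage_conditionals(),
    probability_unit_factor = 1e-6,
    length_factor_default = "L/2",
    preference_breakpoints = c(0.5, 1.0, 1.5),
    preference_values = c(0.9, 0.95, 1.0, 1.05, 1.1),
    d_pop_m = D_POP_DEFAULT,
    friction_velocity_bounds = c(0.02, 0.553),
    hemisphere_coefficient = 2 / 3,
    quarter_sphere_coefficient = 1 / 3,
    lake_river_dispersion_coefficient = 0.58,
    river_bank_reflection_coefficient = 0.145,
    persons_km2_to_m2 = 1e-6,
    tons_to_mg = 1e9
  )
}
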