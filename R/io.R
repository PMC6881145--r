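#' Write sweeps to the long-CSV interchange format
#'
#' One row per sample: `cell_id`, `timepoint`, `sweep`, `t_ms`, `v_mV`,
#' `i_pA`. The step metadata is implicit in the command-current column (the
#' step is its non-zero stretch), so the file round-trips through
#' [load_sweeps()] without side channels.
#'
#' @param cells list of cells from [generate_cohort()], or a named list of
#'   blocks for a single cell.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweeps_csv <- function(cells, path) {
  chunks <- list()
  for (cell in cells) {
    for (tp in names(cell$blocks)) {
      sweeps <- cell$blocks[[tp]]$sweeps
      for (k in seq_along(sweeps)) {
        s <- sweeps[[k]]
        chunks[[length(chunks) + 1L]] <- data.frame(
          cell_id = cell$id, timepoint = tp, sweep = k,
          t_ms = sweep_times(s), v_mV = s$v, i_pA = sweep_command(s))
      }
    }
  }
  utils::write.csv(do.call(rbind, chunks), path, row.names = FALSE)
  invisible(path)
}

#' Load sweeps from the long-CSV interchange format
#'
#' @param path input file.
#' @param dialect on-disk dialect; only `"long-csv"` is supported.
#' @return nested list: `cells[[cell_id]][[timepoint]]$sweeps` is a list of
#'   [ie_sweep()] objects.
#' @export
load_sweeps <- function(path, dialect = "long-csv") {
  if (!identical(dialect, "long-csv")) {
    stop("unsupported sweep dialect: ", dialect,
         " (only \"long-csv\" is available)", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "timepoint", "sweep", "t_ms", "v_mV", "i_pA")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[c("t_ms", "v_mV", "i_pA")]))
  if (length(bad)) {
    stop("parse error: malformed rows at line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (cid in unique(df$cell_id)) {
    dc <- df[df$cell_id == cid, ]
    out[[as.character(cid)]] <- lapply(split(dc, dc$timepoint), function(dtp) {
      sweeps <- lapply(split(dtp, dtp$sweep), function(ds) {
        ds <- ds[order(ds$t_ms), ]
        dt <- stats::median(diff(ds$t_ms))
        step_idx <- which(ds$i_pA != 0)
        if (!length(step_idx)) {
          stop("parse error: sweep without a current step in cell ", cid,
               call. = FALSE)
        }
        ie_sweep(dt, ds$v_mV, ds$i_pA,
                 step_onset = step_idx[1], step_offset = step_idx[length(step_idx)],
                 step_amp = ds$i_pA[step_idx[1]])
      })
      list(sweeps = unname(sweeps))
    })
  }
  out
}

#' Write a place session to spikes/position CSV files
#'
#' @param session a `place_session`.
#' @param spikes_path,pos_path output files.
#' @param cell_id label written with every spike.
#' @return invisibly, the two paths.
#' @export
write_place_csv <- function(session, spikes_path, pos_path, cell_id = "cell_01") {
  utils::write.csv(data.frame(cell_id = cell_id, t_s = session$spikes),
                   spikes_path, row.names = FALSE)
  pos <- session$position
  lap_row <- match_interval(pos$t_s, session$laps$start, session$laps$end)
  pos$lap <- session$laps$lap[lap_row]
  pos$direction <- session$laps$direction[lap_row]
  utils::write.csv(pos, pos_path, row.names = FALSE)
  invisible(c(spikes_path, pos_path))
}

#' Load a place session from spikes/position CSV files
#'
#' Laps are re-segmented from the position trace, so the files only need
#' `t_s` plus `x_cm` (position) and `t_s` (spikes).
#'
#' @param spikes_path,pos_path input files.
#' @param track_length track length (cm); inferred from the position range
#'   when `NULL`.
#' @return a `place_session` (without generator-native counts).
#' @export
load_place_csv <- function(spikes_path, pos_path, track_length = NULL) {
  sp <- utils::read.csv(spikes_path, stringsAsFactors = FALSE)
  pos <- utils::read.csv(pos_path, stringsAsFactors = FALSE)
  if (!all(c("t_s", "x_cm") %in% names(pos)) || !"t_s" %in% names(sp)) {
    stop("parse error: expected columns t_s (spikes) and t_s, x_cm (position)",
         call. = FALSE)
  }
  track_length <- track_length %||% max(pos$x_cm)
  structure(list(spikes = sort(sp$t_s), position = pos[c("t_s", "x_cm")],
                 laps = segment_laps(pos[c("t_s", "x_cm")], track_length),
                 track_length = track_length),
            class = "place_session")
}

# declared column schemas of the published per-figure source tables
source_data_schemas <- function() {
  ephys <- c("cell_id", "condition", "timepoint")
  list(
    fig1 = list(id = ephys, values = "spike_count"),
    fig2 = list(id = ephys, values = c("rin_mohm", "latency_ms")),
    fig3 = list(id = ephys, values = c("spike_count", "rin_mohm", "latency_ms")),
    fig4 = list(id = ephys, values = c("spike_count", "rin_mohm", "latency_ms")),
    fig5 = list(id = ephys, values = "sag_ratio"),
    fig6 = list(id = ephys, values = c("spike_count", "rin_mohm", "latency_ms")),
    fig7 = list(id = ephys, values = c("spike_count", "rin_mohm", "latency_ms")),
    fig8 = list(id = c("cell_id", "lap"),
                values = c("in_rate_hz", "out_rate_hz")))
}

#' Load a published figure source-data table
#'
#' Validates a delimited table against the declared schema for the figure
#' and normalizes it to long format (`metric` / `value`), ready for the
#' group-statistics operations.
#'
#' @param path delimited file (comma or tab separated).
#' @param figure_id one of `"fig1"` ... `"fig8"`.
#' @return long-format data frame: the figure's id columns plus `metric`
#'   and `value`.
#' @export
load_source_data <- function(path, figure_id) {
  schemas <- source_data_schemas()
  if (!figure_id %in% names(schemas)) {
    stop("unknown figure id; expected one of ",
         paste(names(schemas), collapse = ", "), call. = FALSE)
  }
  sc <- schemas[[figure_id]]
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  miss <- setdiff(c(sc$id, sc$values), names(df))
  if (length(miss)) {
    stop("schema error for ", figure_id, ": expected columns ",
         paste(c(sc$id, sc$values), collapse = ", "),
         "; missing ", paste(miss, collapse = ", "), call. = FALSE)
  }
  long <- do.call(rbind, lapply(sc$values, function(vc) {
    out <- df[sc$id]
    out$metric <- vc
    out$value <- df[[vc]]
    out
  }))
  rownames(long) <- NULL
  long
}

#' Group statistics from a long-format source-data table
#'
#' Reproduces the per-metric group statistics (per-cell percent change
#' pre -> post, mean, SEM, paired and between-group p-values) from a table
#' in the layout returned by [load_source_data()] for the
#' electrophysiology figures.
#'
#' @param long long-format table with `cell_id`, `condition`, `timepoint`,
#'   `metric`, `value`.
#' @param metric metric to analyze.
#' @param conditions two condition labels to compare.
#' @param pre,post timepoint labels.
#' @return [group_stats()] output.
#' @export
source_data_group_stats <- function(long, metric, conditions = c("TBS", "control"),
                                    pre = "pre", post = "20") {
  d <- long[long$metric == metric, ]
  grab <- function(cond, tp) {
    sub <- d[d$condition == cond & d$timepoint == tp, ]
    stats::setNames(sub$value, sub$cell_id)
  }
  pair <- function(cond) {
    a <- grab(cond, pre)
    b <- grab(cond, post)
    ids <- intersect(names(a), names(b))
    list(pre = a[ids], post = b[ids])
  }
  g1 <- pair(conditions[1])
  g2 <- pair(conditions[2])
  group_stats(g1$pre, g1$post, g2$pre, g2$post, labels = conditions)
}

#' Default pipeline configuration
#'
#' Collects every protocol and analysis constant with its published default
#' in one place: step protocol, TBS timing, the dV/dt spike criterion
#' (10 V/s), the burst-defining ISI (10 ms), the Rin/sag search window
#' (150 ms), the sag steady-state and AHP windows (50 ms), the QC bounds
#' (Vm < -55 mV, Rs < 100 MOhm, spike amplitude > 40 mV), the 250-spike
#' matched-comparison filter and the 0.1 place-cell inclusion cutoffs.
#'
#' @param seed master seed.
#' @param n_cells named vector of group sizes.
#' @param out_dir output directory.
#' @param timepoints post-stimulation blocks (min).
#' @param ... overrides of any listed constant.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_cells = c(TBS = 16L, control = 11L),
                            out_dir = "ieplast-out",
                            timepoints = c(10, 20, 30), ...) {
  cfg <- list(
    seed = as.integer(seed),
    conditions = c("TBS", "control", "BAPTA", "MK801", "ZD", "DTX"),
    n_cells = n_cells,
    out_dir = out_dir,
    timepoints = timepoints,
    proto = stim_protocol(),
    dt_ms = 0.025,
    dvdt_thresh_vps = 10,
    burst_isi_ms = 10,
    rin_window_ms = 150,
    sag_steady_ms = 50,
    ahp_window_ms = 50,
    qc_vm_max_mv = -55,
    qc_rs_max_mohm = 100,
    qc_spike_amp_min_mv = 40,
    dtx_min_spikes = 250,
    inclusion_cutoff = 0.1)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm, call. = FALSE)
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config", overrides = names(over))
}

#' Run the end-to-end simulation and analysis pipeline
#'
#' Simulates the configured groups, extracts features, computes per-cell
#' changes and group statistics, and writes `features.csv`, `changes.csv`,
#' `stats.csv` and `manifest.json` into the output directory. Deterministic
#' given the configured seed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with `features`, `changes`, `stats` (data frames),
#'   `results` (the [analyze_cohorts()] output) and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  groups <- names(config$n_cells)
  bad <- setdiff(groups, config$conditions)
  if (length(bad)) {
    stop("config error: unknown condition(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(groups) < 2L) stop("config error: need two groups", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  cohorts <- list()
  for (g in groups) {
    t0 <- Sys.time()
    cohorts[[g]] <- generate_cohort(config$n_cells[[g]], g,
                                    seed = derive_seed(config$seed, match(g, groups)),
                                    proto = config$proto, dt = config$dt_ms,
                                    timepoints = config$timepoints)
    say("simulated %s (n=%d) in %.1f s", g, config$n_cells[[g]],
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  res <- analyze_cohorts(cohorts[[1]], cohorts[[2]],
                         post = as.character(config$timepoints[
                           min(2L, length(config$timepoints))]),
                         labels = groups[1:2])
  features <- rbind(cohort_features(cohorts[[1]]), cohort_features(cohorts[[2]]))
  changes <- rbind(res$changes_a, res$changes_b)

  stats_df <- do.call(rbind, lapply(c("firing", "rin", "latency"), function(met) {
    g <- res[[met]]
    do.call(rbind, lapply(groups[1:2], function(lab) {
      data.frame(metric = met, group = lab, n = g[[lab]]$n,
                 mean_change = g[[lab]]$mean_change,
                 sem_change = g[[lab]]$sem_change,
                 paired_p = g[[lab]]$paired_p, between_p = g$between_p)
    }))
  }))

  paths <- file.path(config$out_dir,
                     c("features.csv", "changes.csv", "stats.csv", "manifest.json"))
  utils::write.csv(features, paths[1], row.names = FALSE)
  utils::write.csv(changes, paths[2], row.names = FALSE)
  utils::write.csv(stats_df, paths[3], row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ieplast")),
    seed = config$seed,
    groups = as.list(config$n_cells),
    overrides = attr(config, "overrides"),
    digests = as.list(tools::md5sum(paths[1:3])))
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, pretty = TRUE)
  say("wrote %s", paste(basename(paths), collapse = ", "))

  list(features = features, changes = changes, stats = stats_df,
       results = res, paths = paths)
}
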