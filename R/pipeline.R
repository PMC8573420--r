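#' Pipeline run configuration
#'
#' One declarative object drives every stage; all randomness flows from
#' `seed` via named substreams, so rerunning any stage with the same config
#' reproduces its outputs bit-identically.
#'
#' @param out_dir root directory for stage artifacts.
#' @param seed root seed.
#' @param n_subjects,duration,fs cohort size and recording geometry for the
#'   `simulate` stage (defaults give a small demonstration cohort: 8
#'   subjects, 120 s segments).
#' @param conditions recorded conditions.
#' @param band analysis band, Hz. The demo default starts at 0.02 Hz so that
#'   a 120 s segment still spans two cycles of the lowest grid frequency.
#' @param m surrogate count.
#' @param voices voices per octave of the connectivity grid.
#' @param decimate decimation factor before wavelet analysis.
#' @param surrogate_mode `"both"` or `"one"`.
#' @param aggregation `"zero"` or `"valid-only"`.
#' @param cutoff_period DCT high-pass cutoff, seconds. The demo default
#'   (60 s) is half the demo segment; for full 600 s recordings use the
#'   conventional 128 s.
#' @param hrf apply the HRF low-pass during preprocessing.
#' @param fraction extreme-group fraction for the prior-level contrast.
#' @param cohort optional full [cohort_config()] overriding the scalar
#'   cohort arguments.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = "wpconet_run", seed = 1,
                       n_subjects = 8, duration = 120, fs = 13.33,
                       conditions = c("near", "far"),
                       band = c(0.02, 0.1), m = 30, voices = 8,
                       decimate = 8, surrogate_mode = "both",
                       aggregation = "zero", cutoff_period = 60,
                       hrf = TRUE, fraction = 0.27, cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- cohort_config(
      n_subjects = n_subjects, fs = fs, duration = max(duration, 200),
      seed = as.integer(seed)
    )
    cohort$duration <- duration # demo segments may be shorter than 200 s
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), conditions = conditions,
      band = band, m = m, voices = voices, decimate = decimate,
      surrogate_mode = surrogate_mode, aggregation = aggregation,
      cutoff_period = cutoff_period, hrf = hrf, fraction = fraction,
      cohort = cohort
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields of [run_config()] in plain YAML; unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "cohort")
  bad <- setdiff(names(y), allowed)
  if (length(bad)) {
    stop("unknown config key(s) in ", path, ": ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(run_config, y)
}

stage_dir <- function(config, stage) file.path(config$out_dir, stage)

write_manifest <- function(config, stage, extra = list()) {
  m <- c(
    list(
      stage = stage, seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
      package_version = as.character(utils::packageVersion("wpconet")),
      band = config$band, m = config$m, aggregation = config$aggregation
    ),
    extra
  )
  path <- file.path(stage_dir(config, stage), "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(m, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

require_upstream <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf(
      "stage `%s` needs missing upstream artifact: %s (run the producing stage first)",
      stage, path
    ), call. = FALSE)
  }
  path
}

#' Run one pipeline stage
#'
#' Stages communicate only through on-disk artifacts under
#' `config$out_dir/<stage>/`, each with a JSON manifest recording the seed
#' and a hash of the configuration. Stages: `simulate` (synthetic cohort),
#' `preprocess` (HRF low-pass + DCT detrend), `connectivity` (pairwise WPCO
#' with surrogate validity), `network` (ROI aggregation), `stats`
#' (contrasts and performance correlations), `all` (everything in order).
#'
#' @param stage stage name.
#' @param config a [run_config()] or path to a YAML config file.
#' @return the stage's output directory, invisibly.
#' @export
run_stage <- function(stage = c(
                        "simulate", "preprocess", "connectivity",
                        "network", "stats", "all"
                      ),
                      config = run_config()) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (stage == "all") {
    for (s in c("simulate", "preprocess", "connectivity", "network", "stats")) {
      run_stage(s, config)
    }
    return(invisible(config$out_dir))
  }
  dir.create(stage_dir(config, stage), showWarnings = FALSE, recursive = TRUE)
  switch(stage,
    simulate = stage_simulate(config),
    preprocess = stage_preprocess(config),
    connectivity = stage_connectivity(config),
    network = stage_network(config),
    stats = stage_stats(config)
  )
  invisible(stage_dir(config, stage))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config = run_config()) run_stage("all", config)

rec_files <- function(config, stage) {
  d <- stage_dir(config, stage)
  expand.grid(
    s = seq_len(config$cohort$n_subjects), cond = config$conditions,
    stringsAsFactors = FALSE
  ) |>
    (\(g) file.path(d, sprintf("S%02d_%s.csv", g$s, g$cond)))()
}

stage_simulate <- function(config) {
  cohort <- generate_cohort(config$cohort, conditions = config$conditions)
  write_cohort(cohort, stage_dir(config, "simulate"))
  write_manifest(config, "simulate", list(
    n_subjects = config$cohort$n_subjects,
    duration_s = config$cohort$duration, fs_hz = config$cohort$fs
  ))
}

stage_preprocess <- function(config) {
  for (f in rec_files(config, "simulate")) {
    rec <- read_recording(require_upstream(f, "preprocess"))
    rec <- preprocess(rec, cutoff_period = config$cutoff_period, hrf = config$hrf)
    write_recording(rec, file.path(stage_dir(config, "preprocess"), basename(f)))
  }
  write_manifest(config, "preprocess", list(
    cutoff_period_s = config$cutoff_period, hrf = config$hrf
  ))
}

stage_connectivity <- function(config) {
  for (f in rec_files(config, "preprocess")) {
    rec <- read_recording(require_upstream(f, "connectivity"))
    pairs <- pair_matrix(rec,
      m = config$m,
      seed = substream_seed(config$seed, "conn", basename(f)),
      band = config$band, voices = config$voices,
      surrogate_mode = config$surrogate_mode, decimate = config$decimate
    )
    out <- file.path(
      stage_dir(config, "connectivity"),
      sub("\\.csv$", "_pairs.csv", basename(f))
    )
    write_pairs(pairs, out)
  }
  write_manifest(config, "connectivity", list(
    voices = config$voices, decimate = config$decimate,
    surrogate_mode = config$surrogate_mode
  ))
}

read_pairs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  structure(df[, setdiff(names(df), c("subject", "condition"))],
    subject_id = df$subject[1], condition = df$condition[1]
  )
}

stage_network <- function(config) {
  map <- load_roi_map()
  for (f in rec_files(config, "preprocess")) {
    pf <- file.path(
      stage_dir(config, "connectivity"),
      sub("\\.csv$", "_pairs.csv", basename(f))
    )
    pairs <- read_pairs_csv(require_upstream(pf, "network"))
    net <- aggregate_network(pairs, map, mode = config$aggregation)
    write_network(net, file.path(
      stage_dir(config, "network"),
      sub("\\.csv$", "_network.csv", basename(f))
    ))
  }
  write_manifest(config, "network", list(mode = config$aggregation))
}

read_network_csv <- function(path, subject_id, condition) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$roi
  structure(m,
    subject_id = subject_id, condition = condition,
    class = c("roi_network", "matrix", "array")
  )
}

stage_stats <- function(config) {
  beh <- readr::read_csv(
    require_upstream(file.path(stage_dir(config, "simulate"), "behavioral.csv"), "stats"),
    show_col_types = FALSE, progress = FALSE
  )
  nets <- lapply(
    stats::setNames(config$conditions, config$conditions),
    function(cond) {
      lapply(seq_len(config$cohort$n_subjects), function(s) {
        f <- file.path(
          stage_dir(config, "network"),
          sprintf("S%02d_%s_network.csv", s, cond)
        )
        read_network_csv(require_upstream(f, "stats"), sprintf("S%02d", s), cond)
      })
    }
  )
  feats <- feature_table(nets)
  d <- stage_dir(config, "stats")
  if (all(c("near", "far") %in% config$conditions)) {
    ct <- contrast_report(feats, "condition", conditions = c("near", "far"))
    readr::write_csv(ct, file.path(d, "contrast_near_vs_far.csv"), progress = FALSE)
    prior <- stats::setNames(beh$prior_score, beh$subject_id)
    g <- ceiling(config$fraction * nrow(beh))
    if (g >= 2 && 2 * g <= nrow(beh)) {
      gs <- contrast_report(feats, "prior_split",
        conditions = "near",
        prior_scores = prior, fraction = config$fraction
      )
      readr::write_csv(gs, file.path(d, "contrast_prior_split.csv"), progress = FALSE)
    }
  }
  perf <- stats::setNames(beh$performance_near, beh$subject_id)
  cp <- correlate_performance(feats, perf, condition = config$conditions[1])
  readr::write_csv(cp, file.path(d, "performance_correlation.csv"), progress = FALSE)
  write_manifest(config, "stats", list(fraction = config$fraction))
}
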