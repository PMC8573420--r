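#' Paired t-test on matched vectors
#'
#' Two-sided paired t on `d = x - y`: `t = mean(d) / (sd(d)/sqrt(n))`,
#' `df = n - 1` (computed via [stats::t.test()]). A zero-variance difference
#' is degenerate: `t` is 0 (all-zero differences) or infinite in sign of the
#' mean, `p` is `NA` and the result is flagged.
#'
#' @param x,y numeric vectors of equal length `n >= 2`, matched by subject.
#' @return list `(t, p, df, estimate, degenerate)`; `estimate` is `mean(d)`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(
      t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
      p = NA_real_, df = length(d) - 1, estimate = mean(d), degenerate = TRUE
    ))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(
    t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
    estimate = unname(ht$estimate), degenerate = FALSE
  )
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with p from `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom (computed via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return list `(r, p, n)`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Extreme-group split by score quantile
#'
#' The top and bottom `fraction` of subjects by score (the conventional 27%
#' extreme-group design: 31 subjects give 9 per group). Group size is
#' `ceiling(fraction * n)`; ties are broken by position in the input
#' (subject-id order), so the split is deterministic.
#'
#' @param scores numeric scores, one per subject.
#' @param ids subject identifiers (default positional).
#' @param fraction quantile fraction in `(0, 0.5]` (default 0.27).
#' @return list `(high, low)` of disjoint id vectors, each of length
#'   `ceiling(fraction * n)`; `high` ordered by decreasing score, `low` by
#'   increasing score. Both groups come from the two ends of one ranking by
#'   `(score, input position)`, so they are disjoint even when all scores tie.
#' @export
quantile_split <- function(scores, ids = seq_along(scores), fraction = 0.27) {
  n <- length(scores)
  stopifnot(n >= 2, fraction > 0, fraction <= 0.5, length(ids) == n)
  g <- ceiling(fraction * n)
  if (2 * g > n) stop("groups would overlap: 2 * ceiling(fraction * n) > n", call. = FALSE)
  ord <- order(scores, seq_len(n)) # one ranking; ties by input position
  list(high = ids[rev(ord)[seq_len(g)]], low = ids[ord[seq_len(g)]])
}

#' Build the per-subject feature table
#'
#' One row per (subject, condition, feature): band wavelet amplitude per ROI
#' (mean over the region's channels) and band WPCO per ROI pair, taken from
#' per-subject ROI networks and channel amplitudes.
#'
#' @param networks named list per condition of lists of `roi_network`
#'   objects (one per subject, in subject order).
#' @param amplitudes optional named list per condition of lists of named
#'   per-channel amplitude vectors (from [band_amplitude()]).
#' @param map a [load_roi_map()] result (needed when `amplitudes` given).
#' @param behavioral optional behavioral tibble joined on `subject_id`.
#' @return tibble: `subject_id`, `condition`, `feature_type`
#'   (`"wpco"`/`"amplitude"`), `unit` (ROI or `"ROI1-ROI2"`), `value`.
#' @export
feature_table <- function(networks, amplitudes = NULL, map = NULL,
                          behavioral = NULL) {
  rows <- list()
  for (cond in names(networks)) {
    for (net in networks[[cond]]) {
      el <- to_edgelist(net, threshold = -Inf)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = attr(net, "subject_id"),
        condition = cond,
        feature_type = "wpco",
        unit = paste0(el$roi_a, "-", el$roi_b),
        value = el$weight
      )
    }
  }
  if (!is.null(amplitudes)) {
    stopifnot(!is.null(map))
    for (cond in names(amplitudes)) {
      subj_amp <- amplitudes[[cond]]
      for (s in seq_along(subj_amp)) {
        amp <- subj_amp[[s]]
        roi_amp <- vapply(map, function(chs) mean(amp[chs]), numeric(1))
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = names(subj_amp)[s] %||% sprintf("S%02d", s),
          condition = cond,
          feature_type = "amplitude",
          unit = names(map),
          value = unname(roi_amp)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(behavioral)) out <- dplyr::left_join(out, behavioral, by = "subject_id")
  out
}

#' Condition and group contrasts over connectivity features
#'
#' The inferential layer: for every feature unit (ROI or ROI pair), either a
#' paired t between two conditions (`contrast = "condition"`, e.g. near vs
#' far transfer) or the extreme-group prior-level contrast
#' (`contrast = "prior_split"`): subjects are split into top/bottom
#' `fraction` by `prior_scores`, the two groups are rank-matched and compared
#' by a paired t with `df = group size - 1` — the matched-extremes design.
#' Uncorrected p-values are reported (the convention for these edge-wise
#' screens) together with Benjamini-Hochberg q-values.
#'
#' @param features a [feature_table()] tibble.
#' @param contrast `"condition"` or `"prior_split"`.
#' @param conditions length-2: conditions compared (for `"condition"`) or
#'   the single condition whose features are group-compared (length-1, for
#'   `"prior_split"`).
#' @param prior_scores named vector (names = subject ids) of prior scores,
#'   required for `"prior_split"`.
#' @param fraction extreme-group fraction (default 0.27).
#' @param feature_type restrict to `"wpco"`, `"amplitude"` or `"both"`.
#' @return tidy tibble: `unit`, `feature_type`, `estimate`, `t`, `df`, `p`,
#'   `q`, `degenerate`.
#' @export
contrast_report <- function(features, contrast = c("condition", "prior_split"),
                            conditions = c("near", "far"),
                            prior_scores = NULL, fraction = 0.27,
                            feature_type = "both") {
  contrast <- match.arg(contrast)
  if (feature_type != "both") {
    features <- features[features$feature_type == feature_type, ]
  }
  units <- unique(features[, c("unit", "feature_type")])
  res <- lapply(seq_len(nrow(units)), function(u) {
    f <- features[features$unit == units$unit[u] &
      features$feature_type == units$feature_type[u], ]
    if (contrast == "condition") {
      a <- f[f$condition == conditions[1], ]
      b <- f[f$condition == conditions[2], ]
      common <- intersect(a$subject_id, b$subject_id)
      if (length(common) < 2) stop("missing cells for unit ", units$unit[u], call. = FALSE)
      x <- a$value[match(common, a$subject_id)]
      y <- b$value[match(common, b$subject_id)]
    } else {
      if (is.null(prior_scores)) stop("`prior_scores` required", call. = FALSE)
      f <- f[f$condition == conditions[1], ]
      grp <- quantile_split(unname(prior_scores), names(prior_scores), fraction)
      x <- f$value[match(grp$high, f$subject_id)] # rank-matched pairing
      y <- f$value[match(grp$low, f$subject_id)]
      if (anyNA(x) || anyNA(y)) stop("missing cells for unit ", units$unit[u], call. = FALSE)
    }
    pt <- paired_t(x, y)
    tibble::tibble(
      unit = units$unit[u], feature_type = units$feature_type[u],
      estimate = pt$estimate, t = pt$t, df = pt$df, p = pt$p,
      degenerate = pt$degenerate
    )
  })
  out <- dplyr::bind_rows(res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("unit", "feature_type", "estimate", "t", "df", "p", "q", "degenerate")]
}

#' Correlate connectivity features with transfer performance
#'
#' Pearson correlation, per feature unit, between the feature under one
#' condition and a per-subject performance score.
#'
#' @param features a [feature_table()] tibble.
#' @param performance named numeric vector (names = subject ids).
#' @param condition condition whose features are correlated.
#' @param feature_type `"wpco"`, `"amplitude"` or `"both"`.
#' @return tidy tibble: `unit`, `feature_type`, `r`, `p`, `q`, `n`.
#' @export
correlate_performance <- function(features, performance, condition = "near",
                                  feature_type = "both") {
  if (feature_type != "both") {
    features <- features[features$feature_type == feature_type, ]
  }
  features <- features[features$condition == condition, ]
  units <- unique(features[, c("unit", "feature_type")])
  res <- lapply(seq_len(nrow(units)), function(u) {
    f <- features[features$unit == units$unit[u] &
      features$feature_type == units$feature_type[u], ]
    y <- performance[f$subject_id]
    keep <- !is.na(y)
    if (sum(keep) < 3 || stats::sd(f$value[keep]) == 0) {
      return(tibble::tibble(
        unit = units$unit[u], feature_type = units$feature_type[u],
        r = NA_real_, p = NA_real_, n = sum(keep)
      ))
    }
    pc <- pearson_cor(f$value[keep], unname(y[keep]))
    tibble::tibble(
      unit = units$unit[u], feature_type = units$feature_type[u],
      r = pc$r, p = pc$p, n = pc$n
    )
  })
  out <- dplyr::bind_rows(res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("unit", "feature_type", "r", "p", "q", "n")]
}

#' Simulate edge features with a planted paired effect
#'
#' Feature-level simulator for power and type-I calibration of the contrast
#' machinery: every ROI-pair edge gets per-subject values under two
#' conditions whose within-subject difference is `N(0, 1)` except for the
#' planted edge, where the difference is `N(d, 1)` — a paired Cohen's d of
#' `d`. Deterministic given `seed`.
#'
#' @param n_subjects subjects (default 31).
#' @param planted_edge edge label like `"LOFA-ROFA"`, or `NULL` for a global
#'   null.
#' @param d paired standardized effect size at the planted edge.
#' @param seed integer seed.
#' @param map a [load_roi_map()] result (defines the 45 edges).
#' @return a [feature_table()]-shaped tibble (feature_type `"wpco"`,
#'   conditions `"near"` and `"far"`).
#' @export
simulate_edge_features <- function(n_subjects = 31, planted_edge = NULL,
                                   d = 1.2, seed = 1, map = load_roi_map()) {
  rois <- names(map)
  idx <- utils::combn(length(rois), 2)
  edges <- paste0(rois[idx[1, ]], "-", rois[idx[2, ]])
  if (!is.null(planted_edge) && !planted_edge %in% edges) {
    stop("unknown edge: ", planted_edge, call. = FALSE)
  }
  ids <- sprintf("S%02d", seq_len(n_subjects))
  with_seed(seed, {
    rows <- lapply(edges, function(e) {
      base <- stats::rnorm(n_subjects, 0.4, 0.1) # shared subject level
      shift <- if (!is.null(planted_edge) && e == planted_edge) d else 0
      diff <- stats::rnorm(n_subjects, shift, 1)
      tibble::tibble(
        subject_id = rep(ids, 2),
        condition = rep(c("near", "far"), each = n_subjects),
        feature_type = "wpco",
        unit = e,
        value = c(base + diff / 2, base - diff / 2)
      )
    })
    dplyr::bind_rows(rows)
  })
}
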