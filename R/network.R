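roi_labels <- c(
  "LFOA", "RFOA", "LOFA", "ROFA", "LPTBA", "RPTBA",
  "LDLPFC", "RDLPFC", "LIPFG", "RIPFG"
)

montage_labels <- function() sprintf("CH%02d", 1:22)

#' Load the channel-to-ROI mapping
#'
#' The 22-channel prefrontal montage maps onto 10 regions of interest: left
#' and right frontopolar area (FOA), orbitofrontal area (OFA), pars
#' triangularis Broca's area (PTBA), dorsolateral prefrontal cortex (DLPFC)
#' and inferior prefrontal gyrus (IPFG). Two midline channels sit on both
#' hemispheric regions (CH04 in LFOA and RFOA; CH19 in LOFA and ROFA). The
#' shipped fixture encodes this montage; a user file with the same two-column
#' schema (`roi,channel`) may be supplied instead.
#'
#' @param source path to a `roi,channel` CSV; default the shipped montage.
#' @return named list of class `roi_map`: one character vector of channel
#'   labels per ROI, in canonical ROI order.
#' @export
load_roi_map <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "roi_map.csv", package = "wpconet")
  }
  df <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  if (!all(c("roi", "channel") %in% names(df))) {
    stop("ROI map must have columns `roi` and `channel`", call. = FALSE)
  }
  bad <- setdiff(df$channel, montage_labels())
  if (length(bad)) {
    stop("channel label(s) outside the CH01-CH22 montage: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  missing_roi <- setdiff(roi_labels, df$roi)
  if (length(missing_roi)) {
    stop("ROI(s) missing from map: ", paste(missing_roi, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(df$roi, roi_labels)
  if (length(extra)) {
    stop("unknown ROI label(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  map <- lapply(stats::setNames(roi_labels, roi_labels), function(r) {
    sort(unique(df$channel[df$roi == r]))
  })
  uncovered <- setdiff(montage_labels(), unlist(map))
  if (length(uncovered)) {
    stop("channel(s) not assigned to any ROI: ",
      paste(uncovered, collapse = ", "),
      call. = FALSE
    )
  }
  structure(map, class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  cat("<roi_map> 10 regions\n")
  for (r in names(x)) cat(sprintf("  %-7s %s\n", r, paste(x[[r]], collapse = " ")))
  invisible(x)
}

#' Aggregate channel-pair coherence into the ROI brain network
#'
#' The edge between two regions is the mean band WPCO over their constituent
#' cross-region channel pairs, with each pair entering as its coherence value
#' if the surrogate test accepted it and as 0 otherwise (`mode = "zero"`,
#' the default rule: an invalid coherence *is* 0). `mode = "valid-only"`
#' instead averages only the accepted pairs (0 when none are accepted).
#'
#' Constituent pairs of edge (A, B) are the unordered channel pairs with one
#' end in A and the other in B, excluding pairs lying entirely inside either
#' region (relevant where a midline channel belongs to both hemispheric
#' regions); each unordered pair counts once.
#'
#' @param pairs a `wpco_pairs` tibble from [pair_matrix()] (or any tibble
#'   with `ch_i`, `ch_j`, `band_wpco`, `valid` covering all montage pairs).
#' @param map a [load_roi_map()] result.
#' @param mode `"zero"` or `"valid-only"`.
#' @return A 10 x 10 symmetric matrix of class `roi_network` with zero
#'   diagonal, edge weights in `[0, 1]`, and attributes `n_pairs` (matrix of
#'   constituent-pair counts; edges with no constituent pair are `NA` in the
#'   weight matrix), `mode`, `subject_id`, `condition`, `band`.
#' @export
aggregate_network <- function(pairs, map, mode = c("zero", "valid-only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "roi_map"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lookup <- stats::setNames(seq_len(nrow(pairs)), key(pairs$ch_i, pairs$ch_j))
  rois <- names(map)
  A <- matrix(0, 10, 10, dimnames = list(rois, rois))
  npair <- matrix(0L, 10, 10, dimnames = list(rois, rois))
  for (a in 1:9) {
    for (b in (a + 1):10) {
      ra <- map[[rois[a]]]
      rb <- map[[rois[b]]]
      cand <- unique(key(
        rep(ra, each = length(rb)),
        rep(rb, times = length(ra))
      ))
      # drop degenerate (shared channel paired with itself) and within-ROI pairs
      keep <- vapply(strsplit(cand, " "), function(pq) {
        pq[1] != pq[2] &&
          !(all(pq %in% ra)) && !(all(pq %in% rb))
      }, logical(1))
      cand <- cand[keep]
      npair[a, b] <- npair[b, a] <- length(cand)
      if (!length(cand)) {
        A[a, b] <- A[b, a] <- NA_real_
        next
      }
      idx <- lookup[cand]
      if (anyNA(idx)) {
        stop("channel pair(s) missing from `pairs`: ",
          paste(cand[is.na(idx)], collapse = ", "),
          call. = FALSE
        )
      }
      w <- pairs$band_wpco[idx]
      v <- pairs$valid[idx]
      val <- if (mode == "zero") {
        mean(ifelse(v, w, 0))
      } else if (any(v)) mean(w[v]) else 0
      A[a, b] <- A[b, a] <- val
    }
  }
  structure(A,
    n_pairs = npair, mode = mode,
    subject_id = attr(pairs, "subject_id"),
    condition = attr(pairs, "condition"),
    band = attr(pairs, "band"),
    class = c("roi_network", "matrix", "array")
  )
}

#' Mean coherence within each region
#'
#' Intra-region coherence (mean band WPCO over within-ROI channel pairs,
#' invalid pairs as zero) is reported separately, not on the network
#' diagonal. Singleton regions have no within pairs and return `NA`.
#'
#' @inheritParams aggregate_network
#' @return named numeric vector, one value per ROI.
#' @export
intra_roi_coherence <- function(pairs, map) {
  stopifnot(inherits(map, "roi_map"))
  key <- paste(pmin(pairs$ch_i, pairs$ch_j), pmax(pairs$ch_i, pairs$ch_j))
  lookup <- stats::setNames(seq_len(nrow(pairs)), key)
  vapply(map, function(chs) {
    if (length(chs) < 2) {
      return(NA_real_)
    }
    idx <- utils::combn(sort(chs), 2)
    k <- paste(idx[1, ], idx[2, ])
    i <- lookup[k]
    mean(ifelse(pairs$valid[i], pairs$band_wpco[i], 0))
  }, numeric(1))
}

#' Edge list of a ROI network
#'
#' @param net a `roi_network`.
#' @param threshold keep edges with weight strictly above this (default 0).
#' @return tibble with columns `roi_a`, `roi_b`, `weight`; each unordered
#'   edge once.
#' @export
to_edgelist <- function(net, threshold = 0) {
  stopifnot(inherits(net, "roi_network"))
  rois <- rownames(net)
  idx <- which(upper.tri(net) & !is.na(net) & net > threshold, arr.ind = TRUE)
  tibble::tibble(
    roi_a = rois[idx[, 1]],
    roi_b = rois[idx[, 2]],
    weight = net[idx]
  )
}

#' Write a ROI network as labeled adjacency CSV plus manifest
#'
#' @param net a `roi_network`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  df <- data.frame(roi = rownames(net), as.data.frame(unclass(net)[, ]),
    check.names = FALSE
  )
  readr::write_csv(df, path, progress = FALSE)
  jsonlite::write_json(
    list(
      mode = attr(net, "mode"), subject_id = attr(net, "subject_id"),
      condition = attr(net, "condition"), band = attr(net, "band")
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
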