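map <- load_roi_map()

test_that("the shipped montage map matches the published channel assignment", {
  expect_s3_class(map, "roi_map")
  expect_length(map, 10)
  expect_equal(map$LDLPFC, c("CH01", "CH09", "CH17"))
  expect_equal(map$RDLPFC, c("CH07", "CH14", "CH21"))
  expect_equal(map$LFOA, c("CH02", "CH03", "CH04", "CH10", "CH11"))
  expect_equal(map$RFOA, c("CH04", "CH05", "CH06", "CH12", "CH13"))
  expect_equal(map$LOFA, c("CH18", "CH19"))
  expect_equal(map$ROFA, c("CH19", "CH20"))
  expect_equal(map$LPTBA, "CH08")
  expect_equal(map$RPTBA, "CH15")
  expect_equal(map$LIPFG, "CH16")
  expect_equal(map$RIPFG, "CH22")
  # midline channels sit on both hemispheric regions
  expect_true("CH04" %in% map$LFOA && "CH04" %in% map$RFOA)
  expect_true("CH19" %in% map$LOFA && "CH19" %in% map$ROFA)
})

test_that("malformed maps are rejected", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("roi,channel", "LFOA,CH23"), bad)
  expect_error(load_roi_map(bad), "CH23")
  writeLines(c("roi,channel", "LFOA,CH01"), bad)
  expect_error(load_roi_map(bad), "missing")
})

random_pairs <- function(seed, p_valid = 0.5) {
  set.seed(seed)
  p <- channel_pairs(22)
  p$band_wpco <- runif(nrow(p))
  p$valid <- runif(nrow(p)) < p_valid
  p
}

# independent brute-force oracle over the published mapping
oracle_edge <- function(pairs, map, a, b, mode) {
  vals <- c()
  seen <- character()
  for (p in map[[a]]) {
    for (q in map[[b]]) {
      if (p == q) next
      k <- paste(sort(c(p, q)), collapse = "-")
      if (k %in% seen) next
      seen <- c(seen, k)
      if (all(c(p, q) %in% map[[a]]) || all(c(p, q) %in% map[[b]])) next
      row <- which((pairs$ch_i == p & pairs$ch_j == q) |
        (pairs$ch_i == q & pairs$ch_j == p))
      w <- pairs$band_wpco[row]
      v <- pairs$valid[row]
      vals <- rbind(vals, c(w, v))
    }
  }
  if (mode == "zero") {
    return(mean(ifelse(vals[, 2] == 1, vals[, 1], 0)))
  }
  if (any(vals[, 2] == 1)) mean(vals[vals[, 2] == 1, 1]) else 0
}

test_that("aggregation matches a brute-force enumeration oracle in both modes", {
  for (seed in c(71, 72)) {
    pairs <- random_pairs(seed)
    for (mode in c("zero", "valid-only")) {
      net <- aggregate_network(pairs, map, mode = mode)
      expect_true(isSymmetric(unclass(net)[, ]))
      for (edge in list(
        c("LPTBA", "RPTBA"), c("LFOA", "RFOA"),
        c("LOFA", "ROFA"), c("LDLPFC", "RIPFG")
      )) {
        expect_equal(
          net[edge[1], edge[2]],
          oracle_edge(pairs, map, edge[1], edge[2], mode)
        )
      }
    }
  }
})

test_that("the zeroing rule forces the zero network when nothing is valid", {
  pairs <- random_pairs(73)
  pairs$valid <- FALSE
  net <- aggregate_network(pairs, map, mode = "zero")
  expect_true(all(net[!is.na(net)] == 0))
  expect_equal(nrow(to_edgelist(net)), 0)
})

test_that("constant valid coherence propagates to every edge", {
  pairs <- channel_pairs(22)
  pairs$band_wpco <- 0.42
  pairs$valid <- TRUE
  net <- aggregate_network(pairs, map)
  off <- net[upper.tri(net)]
  expect_equal(unname(off[!is.na(off)]), rep(0.42, sum(!is.na(off))))
  expect_equal(nrow(to_edgelist(net)), 45)
})

test_that("singleton-region edges equal their single channel pair", {
  pairs <- random_pairs(74)
  net <- aggregate_network(pairs, map)
  row <- which(pairs$ch_i == "CH08" & pairs$ch_j == "CH15")
  expected <- if (pairs$valid[row]) pairs$band_wpco[row] else 0
  expect_equal(net["LPTBA", "RPTBA"], expected)
})

test_that("aggregation is invariant to pair-row ordering", {
  pairs <- random_pairs(75)
  shuffled <- pairs[sample(nrow(pairs)), ]
  expect_equal(
    unclass(aggregate_network(pairs, map))[, ],
    unclass(aggregate_network(shuffled, map))[, ]
  )
})

test_that("missing pairs are reported by name", {
  pairs <- random_pairs(76)
  pairs <- pairs[-(which(pairs$ch_i == "CH08" & pairs$ch_j == "CH15")), ]
  expect_error(aggregate_network(pairs, map), "CH08 CH15")
})

test_that("edge list thresholding and intra-region coherence behave", {
  pairs <- channel_pairs(22)
  pairs$band_wpco <- 0
  pairs$valid <- TRUE
  pairs$band_wpco[pairs$ch_i == "CH08" & pairs$ch_j == "CH15"] <- 0.9
  net <- aggregate_network(pairs, map)
  el <- to_edgelist(net)
  expect_equal(nrow(el), 1)
  expect_equal(el$weight, 0.9)

  intra <- intra_roi_coherence(pairs, map)
  expect_true(is.na(intra["LPTBA"])) # singleton: no within pairs
  expect_equal(unname(intra["LDLPFC"]), 0)
})
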