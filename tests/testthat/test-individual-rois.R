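test_that("epicenter selection takes the top fraction with lexical ties", {
  ids <- sprintf("R%03d", 1:200)
  p <- setNames(runif(200), ids)
  set.seed(8); p[] <- runif(200)
  epi <- define_epicenter(p, 0.10)
  expect_length(epi, 20)
  # sorting oracle
  expect_setequal(epi, ids[order(-p, ids)][1:20])

  flat <- setNames(rep(0.5, 10), sprintf("R%02d", 10:1))
  expect_equal(define_epicenter(flat, 0.25), sprintf("R%02d", 1:3))
  expect_error(define_epicenter(p, 1.5), "fraction")
  expect_error(define_epicenter(setNames(2, "a"), 0.5), "\\[0, 1\\]")
})

test_that("connectivity distances follow inverse-weight shortest paths", {
  w <- matrix(c(1, 0.5, 0.1,
                0.5, 1, 0.5,
                0.1, 0.5, 1), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d <- connectivity_to_distance(connectivity_matrix(w))
  # hand Dijkstra: direct A-C edge is 1/0.1 = 10; via B it is 2 + 2 = 4
  expect_equal(d["A", "C"], 4)
  expect_equal(d["A", "B"], 2)
  expect_equal(unname(diag(d)), rep(0, 3))

  full <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dfull <- connectivity_to_distance(connectivity_matrix(full))
  expect_true(all(dfull[upper.tri(dfull)] == 1))

  # nonpositive weights carry no edge -> disconnection warns, distance Inf
  iso <- diag(4); dimnames(iso) <- dimnames(full)
  expect_warning(diso <- connectivity_to_distance(connectivity_matrix(iso)),
                 "disconnected")
  expect_true(all(is.infinite(diso[upper.tri(diso)])))
})

test_that("Q1 takes the closest quartile and partitions the rest", {
  ids <- c("E1", sprintf("N%d", 1:8))
  d <- matrix(10, 9, 9, dimnames = list(ids, ids))
  d["E1", paste0("N", 1:8)] <- d[paste0("N", 1:8), "E1"] <- 1:8
  diag(d) <- 0
  roi <- quartile_q1_roi(d, "E1", subject_id = "s")
  expect_setequal(roi$region_ids, c("N1", "N2"))
  q <- roi$provenance$quartile
  expect_equal(sort(names(q)), sort(paste0("N", 1:8)))
  expect_equal(as.integer(table(q)), rep(2L, 4))
  expect_false("E1" %in% roi$region_ids)
  with_epi <- quartile_q1_roi(d, "E1", include_epicenter = TRUE)
  expect_true("E1" %in% with_epi$region_ids)
})

test_that("Q1 quartiles are disjoint, exhaustive and near-equal in size", {
  set.seed(21)
  for (rep_i in 1:5) {
    n <- sample(10:40, 1)
    gen_ids <- sprintf("R%02d", seq_len(n))
    w <- matrix(runif(n * n, 0.05, 0.9), n)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    diag(w) <- 1
    dimnames(w) <- list(gen_ids, gen_ids)
    d <- connectivity_to_distance(connectivity_matrix(w))
    epi <- gen_ids[1:3]
    roi <- quartile_q1_roi(d, epi)
    q <- roi$provenance$quartile
    rest <- setdiff(gen_ids, epi)
    expect_setequal(names(q), rest)
    sizes <- as.integer(table(factor(q, levels = 1:4)))
    expect_lte(max(sizes) - min(sizes), 1)
    # stable sort-then-slice oracle
    score <- rowMeans(d[rest, epi, drop = FALSE])
    ord <- rest[order(score, rest)]
    expect_identical(roi$region_ids, ord[seq_len(sizes[1])])
  }
})

test_that("probability interval search enumerates 12 candidates and finds
           the accumulating band", {
  # 3 subjects, 8 regions; only regions with probability in [0.4, 0.9]
  # accumulate between scans, fastest at the upper end of the band so the
  # full band strictly beats any sub-interval
  ids <- sprintf("R%d", 1:8)
  probs <- c(0.1, 0.25, 0.45, 0.55, 0.7, 0.85, 0.95, 1.0)
  cat8 <- region_catalog(ids, volume = rep(1, 8))
  prob <- matrix(rep(probs, each = 3), 3, 8,
                 dimnames = list(c("s1", "s2", "s3"), ids))
  bl <- matrix(1.5, 3, 8, dimnames = dimnames(prob))
  fu <- bl
  accum <- probs >= 0.4 & probs <= 0.9
  gain <- c(0, 0, 0.05, 0.10, 0.10, 0.15, 0, 0)
  fu <- bl * rep(1 + gain, each = 3)
  subjects <- data.frame(subject_id = c("s1", "s2", "s3"), group = "CU",
                         abeta = "positive", interval_years = 1)
  cohort <- tau_cohort(subjects, bl, fu, cat8)
  res <- probability_interval_search(prob, cohort)
  expect_equal(nrow(res$search), 12)
  expect_equal(unname(res$interval), c(0.4, 0.9))
  # oracle equivalence: winner matches brute-force enumeration
  brute <- res$search[order(-res$search$mean_change,
                            res$search$hi - res$search$lo,
                            res$search$lo), ][1, ]
  expect_equal(unname(res$interval), c(brute$lo, brute$hi))
  expect_setequal(res$rois$s1$region_ids, ids[accum])

  single <- probability_interval_search(prob, cohort, lower_starts = 0.2,
                                        uppers = 1.0)
  expect_equal(unname(single$interval), c(0.2, 1.0))
})

test_that("overlap ROI is the suprathreshold intersection with its index", {
  mk <- function(v, tp) voxel_block("s1", tp, v, rep("r", length(v)))
  v <- rep(1.0, 10)
  bl <- v; bl[1:6] <- 2.0
  fu <- v; fu[4:9] <- 2.0
  roi <- overlap_index_roi(mk(bl, "baseline"), mk(fu, "followup"))
  expect_equal(which(roi$voxel_mask), 4:6)
  expect_equal(roi$provenance$overlap_index, 3 / 9)
  # symmetric under swapping timepoints; mask within each timepoint's mask
  swap <- overlap_index_roi(mk(fu, "baseline"), mk(bl, "followup"))
  expect_equal(swap$voxel_mask, roi$voxel_mask)
  expect_true(all(which(roi$voxel_mask) %in% which(bl > 1.4)))
  expect_true(all(which(roi$voxel_mask) %in% which(fu > 1.4)))

  same <- overlap_index_roi(mk(bl, "baseline"), mk(bl, "followup"))
  expect_equal(same$voxel_mask, bl > 1.4)
  expect_equal(same$provenance$overlap_index, 1)

  disj <- fu; disj[] <- 1.0; disj[7:10] <- 2.0
  bl2 <- v; bl2[1:3] <- 2.0
  expect_null(overlap_index_roi(mk(bl2, "baseline"), mk(disj, "followup")))

  # gray matter restriction applies to both masks
  gm <- rep(TRUE, 10); gm[5] <- FALSE
  roi_gm <- overlap_index_roi(
    voxel_block("s1", "baseline", bl, rep("r", 10), gm),
    voxel_block("s1", "followup", fu, rep("r", 10), gm))
  expect_equal(which(roi_gm$voxel_mask), c(4L, 6L))
})

test_that("highest positive stage rule takes the maximum index", {
  sets <- lapply(1:5, function(k)
    region_set(paste0("DDS_", k), sprintf("R%02d", k), stage_index = k))
  roi4 <- highest_positive_dds_roi(c(T, T, T, T, F), sets, "s")
  expect_equal(roi4$provenance$stage_index, 4L)
  expect_false(roi4$provenance$hierarchy_violation)
  expect_equal(highest_positive_dds_roi(rep(TRUE, 5),
                                        sets)$provenance$stage_index, 5L)
  skip3 <- highest_positive_dds_roi(c(T, F, T, F, F), sets)
  expect_equal(skip3$provenance$stage_index, 3L)
  expect_true(skip3$provenance$hierarchy_violation)

  none <- highest_positive_dds_roi(rep(FALSE, 5), sets)
  expect_equal(none$provenance$stage_index, 1L)
  expect_true(none$provenance$all_negative_fallback)
  expect_null(highest_positive_dds_roi(rep(FALSE, 5), sets,
                                       fallback = "exclude"))
})

test_that("adding a later positive stage never selects an earlier one", {
  sets <- lapply(1:5, function(k)
    region_set(paste0("DDS_", k), sprintf("R%02d", k), stage_index = k))
  set.seed(31)
  for (i in 1:20) {
    pos <- runif(5) < 0.4
    base_idx <- highest_positive_dds_roi(pos, sets)$provenance$stage_index
    j <- sample(which(!pos %in% NA), 1)
    pos2 <- pos; pos2[j] <- TRUE
    expect_gte(highest_positive_dds_roi(pos2, sets)$provenance$stage_index,
               if (any(pos)) base_idx else 1L)
  }
})

test_that("individual_roi enforces exactly one payload", {
  expect_error(individual_roi("s", "q1"), "exactly one")
  expect_error(individual_roi("s", "q1", region_ids = "a",
                              voxel_mask = TRUE), "exactly one")
})
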