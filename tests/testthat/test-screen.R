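layout2 <- function(wells, compounds, conc, vehicle = FALSE) {
  data.frame(well_id = wells, compound_id = compounds,
             concentration_uM = conc, is_vehicle = vehicle)
}

test_that("well aggregation is field means then well means", {
  pc <- data.frame(well_id = "W1",
                   field_id = rep(c("f1", "f2"), c(2, 4)),
                   score = c(0.9, 1.1, 0.7, 0.8, 0.8, 0.9))
  w <- aggregate_wells(pc, layout2("W1", "C1", 10))
  expect_equal(w$mean_score, mean(c(1.0, 0.8)))   # 0.9, not the pooled mean
  expect_identical(w$cell_count, 6L)
  expect_identical(w$n_fields, 2L)
  # a field whose cells all have undefined scores is excluded and counted
  pc2 <- rbind(pc, data.frame(well_id = "W1", field_id = "f3",
                              score = c(NA, NA)))
  w2 <- aggregate_wells(pc2, layout2("W1", "C1", 10))
  expect_equal(w2$mean_score, 0.9)
  expect_identical(w2$n_empty_fields, 1L)
  expect_identical(w2$n_unscored_cells, 2L)
  # unknown wells are an error
  expect_error(aggregate_wells(pc, layout2("W9", "C1", 10)), "absent from layout")
})

test_that("synthetic plate well means equal a pooled two-stage recomputation", {
  pl <- generate_plate(n_compounds = 20, n_hits_both = 2, n_hits_high_only = 2,
                       cells_per_well = 40, seed = 5)
  wells <- aggregate_wells(pl$per_cell, pl$layout)
  for (w in sample(wells$well_id, 5)) {
    pc <- pl$per_cell[pl$per_cell$well_id == w, ]
    oracle <- mean(tapply(pc$score, pc$field_id, mean))
    expect_equal(wells$mean_score[wells$well_id == w], oracle)
  }
})

test_that("vehicle statistics use the sample SD and demand replication", {
  v <- data.frame(mean_score = c(0.9, 1.0, 1.1), is_vehicle = TRUE)
  st <- vehicle_stats(v)
  expect_equal(st$mean, 1.0)
  expect_equal(st$sd, 0.1)
  expect_error(vehicle_stats(v[1, ]), ">= 2 vehicle wells")
  # identical vehicle wells: SD 0 -> hit calling refuses loudly
  st0 <- vehicle_stats(data.frame(mean_score = rep(1, 5), is_vehicle = TRUE))
  expect_error(call_hits(v, st0$mean, st0$sd), "> 0")
  # Monte-Carlo recovery of generator parameters
  set.seed(100)
  sim <- data.frame(mean_score = rnorm(1000, 1, 0.05), is_vehicle = TRUE)
  st2 <- vehicle_stats(sim)
  expect_lt(abs(st2$mean - 1), 3 * 0.05 / sqrt(1000))
  expect_lt(abs(st2$sd - 0.05), 3 * 0.05 / sqrt(2 * 999))
})

test_that("the k-SD rule calls hits one-sided below by default", {
  w <- data.frame(mean_score = c(0.85, 0.95, 1.12))
  calls <- call_hits(w, 1.0, 0.05)
  expect_identical(calls$is_hit, c(TRUE, FALSE, FALSE))  # -3, -1, +2.4 SD
  expect_equal(calls$z_dev, c(-3, -1, 2.4))
  calls2 <- call_hits(w, 1.0, 0.05, direction = "two_sided")
  expect_identical(calls2$is_hit, c(TRUE, FALSE, TRUE))
})

test_that("hit calling is calibrated to the normal tail on null compounds", {
  set.seed(202)
  null_wells <- data.frame(mean_score = rnorm(10000, 1, 0.05))
  calls <- call_hits(null_wells, 1, 0.05, k = 2)
  n_hit <- sum(calls$is_hit)
  bounds <- qbinom(c(0.005, 0.995), 10000, pnorm(-2))
  expect_gte(n_hit, bounds[1])
  expect_lte(n_hit, bounds[2])
})

test_that("hit calling is invariant under common affine rescaling", {
  set.seed(12)
  w <- data.frame(mean_score = rnorm(200, 1, 0.08))
  base <- call_hits(w, 1, 0.05)$is_hit
  a <- 3.2; b <- -0.7
  w2 <- data.frame(mean_score = a * w$mean_score + b)
  expect_identical(call_hits(w2, a * 1 + b, a * 0.05)$is_hit, base)
})

test_that("hit categories partition the compound set", {
  pl <- generate_plate(n_compounds = 150, n_hits_both = 12, n_hits_high_only = 10,
                       effect_size_sd = 6, cells_per_well = 40, seed = 9)
  res <- screen_plate(pl$per_cell, pl$layout)
  expect_identical(sum(table(res$categories$category)), 150L)
  expect_identical(nrow(res$categories), 150L)
})

test_that("strongly planted hits are recovered with few false positives", {
  # the 2-SD rule calibrates the per-well false-positive rate, so the FPR is
  # accounted per null well, pooled over seeds
  n_fp <- 0L; n_null_wells <- 0L
  for (s in c(1, 2, 3)) {
    pl <- generate_plate(n_compounds = 120, n_hits_both = 8, n_hits_high_only = 6,
                         effect_size_sd = 10, cells_per_well = 40, seed = s)
    res <- screen_plate(pl$per_cell, pl$layout)
    called <- res$categories[match(pl$truth$compound_id, res$categories$compound_id), ]
    planted_hit <- pl$truth$category != "none"
    expect_true(all(called$category[planted_hit] != "none"))           # recall 1
    expect_identical(as.character(called$category[pl$truth$category == "both"]),
                     rep("both", 8))
    null_ids <- pl$truth$compound_id[!planted_hit]
    null_wells <- res$calls[res$calls$compound_id %in% null_ids, ]
    n_fp <- n_fp + sum(null_wells$is_hit)
    n_null_wells <- n_null_wells + nrow(null_wells)
  }
  expect_lte(n_fp / n_null_wells, 0.05)
})

test_that("enrichment p-values equal exhaustive enumeration", {
  # library of 100, 10 in the class, 20 hits of which 6 in class
  ann <- data.frame(compound_id = sprintf("c%03d", 1:100),
                    target_class = rep(c("A", "other"), c(10, 90)))
  hits <- c(sprintf("c%03d", 1:6), sprintf("c%03d", 50:63))
  e <- target_enrichment(hits, ann)
  a <- e[e$target_class == "A", ]
  expect_equal(a$n_hits, 6L)
  expect_equal(a$fold_enrichment, (6 / 20) / (10 / 100))
  expect_equal(a$p_value, hyper_upper_oracle(6, 10, 100, 20), tolerance = 1e-12)
  # tiny instance: full subset enumeration
  ann2 <- data.frame(compound_id = sprintf("x%02d", 1:10),
                     target_class = rep(c("A", "B"), c(4, 6)))
  hits2 <- c("x01", "x02", "x05")   # 2 of 4 class-A members among 3 hits
  e2 <- target_enrichment(hits2, ann2)
  expect_equal(e2$p_value[e2$target_class == "A"],
               hyper_enum_oracle(2, 4, 10, 3), tolerance = 1e-12)
})

test_that("enrichment handles empty and saturated classes", {
  ann <- data.frame(compound_id = sprintf("c%02d", 1:30),
                    target_class = rep(c("A", "B"), c(3, 27)))
  # class absent from hits: fold 0, p near 1 for a small class share
  e <- target_enrichment(sprintf("c%02d", 10:14), ann)
  a <- e[e$target_class == "A", ]
  expect_equal(a$fold_enrichment, 0)
  expect_gt(a$p_value, 0.4)
  # all hits in a class that is the whole library: fold 1, p = 1
  ann1 <- data.frame(compound_id = sprintf("c%02d", 1:10), target_class = "A")
  e1 <- target_enrichment(sprintf("c%02d", 1:4), ann1)
  expect_equal(e1$fold_enrichment, 1)
  expect_equal(e1$p_value, 1)
  # a hit without annotation is an error
  expect_error(target_enrichment("zz99", ann), "missing annotation")
})
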