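test_that("compartment sums follow exact arithmetic on a uniform cell", {
  # 100 px nucleus of value 2 with a 10 px nucleolus
  nuc <- matrix(0L, 14, 14); nuc[3:12, 3:12] <- 1L
  no <- matrix(0L, 14, 14); no[3:12, 3] <- 1L
  f <- image_field(list(gc = matrix(2, 14, 14)))
  m <- measure_cells(f, label_mask(nuc), label_mask(no, parent = 1L))
  expect_equal(m$I_nucleus_gc, 200)
  expect_equal(m$I_nucleolar_gc, 20)
  expect_equal(m$I_nucleoplasm_gc, 180)
  expect_identical(m$n_nucleoli, 1L)
})

test_that("a cell with no nucleoli has zero nucleolar signal and no score", {
  nuc <- matrix(0L, 10, 10); nuc[2:9, 2:9] <- 1L
  no <- matrix(0L, 10, 10)
  f <- image_field(list(gc = matrix(3, 10, 10), fc = matrix(5, 10, 10)))
  m <- measure_cells(f, label_mask(nuc), label_mask(no))
  expect_equal(m$I_nucleolar_gc, 0)
  expect_equal(m$I_nucleoplasm_gc, m$I_nucleus_gc)
  expect_true(is.na(normality_score(m, "gc", "fc")))
})

test_that("compartment sums equal a brute-force per-pixel loop", {
  gf <- generate_field(phenotype_params("normal", seed = 13, n_nuclei = 2L,
                                        field_dim = c(160L, 160L)))
  m <- measure_cells(gf$field, gf$truth$nuclei, gf$truth$nucleoli)
  img <- gf$field$channels$ncl
  for (k in 1:2) {
    oracle <- loop_sums(img, gf$truth$nuclei$labels, gf$truth$nucleoli$labels,
                        gf$truth$nucleoli$parent, k)
    expect_equal(m$I_nucleus_ncl[k], oracle[["nucleus"]])
    expect_equal(m$I_nucleolar_ncl[k], oracle[["nucleolar"]])
    expect_equal(m$I_nucleoplasm_ncl[k], oracle[["nucleoplasm"]])
  }
})

test_that("the normality score is the ratio of compartment ratios", {
  tc <- toy_cell()
  np_px <- sum(tc$nuclei$labels > 0) - sum(tc$nucleoli$labels > 0)
  no_px <- sum(tc$nucleoli$labels > 0)
  # GC ratio 9, FC ratio 3 -> score 3
  gc <- matrix(0, tc$dim[1], tc$dim[2]); fc <- gc
  gc[tc$nuclei$labels > 0] <- 1; gc[tc$nucleoli$labels > 0] <- 9 * np_px / no_px
  fc[tc$nuclei$labels > 0] <- 1; fc[tc$nucleoli$labels > 0] <- 3 * np_px / no_px
  f <- image_field(list(gc = gc, fc = fc))
  m <- measure_cells(f, tc$nuclei, tc$nucleoli)
  expect_equal(normality_score(m, "gc", "fc"), 3)
  # proportional channels give exactly 1
  f2 <- image_field(list(gc = gc, fc = gc * 0.37))
  m2 <- measure_cells(f2, tc$nuclei, tc$nucleoli)
  expect_equal(normality_score(m2, "gc", "fc"), 1)
})

test_that("score and ratio are invariant to per-channel positive scaling", {
  gf <- generate_field(phenotype_params("canonical_stress", seed = 4,
                                        n_nuclei = 2L, field_dim = c(160L, 160L)))
  m <- measure_cells(gf$field, gf$truth$nuclei, gf$truth$nucleoli)
  s0 <- normality_score(m, "ncl", "ubf")
  r0 <- compartment_ratio(m, "ncl")
  f2 <- gf$field
  f2$channels$ncl <- f2$channels$ncl * 17.3
  f2$channels$ubf <- f2$channels$ubf * 0.02
  m2 <- measure_cells(f2, gf$truth$nuclei, gf$truth$nucleoli)
  expect_lt(max(abs(normality_score(m2, "ncl", "ubf") / s0 - 1)), 1e-12)
  expect_lt(max(abs(compartment_ratio(m2, "ncl") / r0 - 1)), 1e-12)
})

test_that("nucleolar + nucleoplasmic intensity equals the nucleus exactly", {
  gf <- generate_field(phenotype_params("dissolution", seed = 6))
  m <- measure_cells(gf$field, gf$truth$nuclei, gf$truth$nucleoli)
  for (ch in c("dapi", "ubf", "ncl"))
    expect_identical(m[[paste0("I_nucleolar_", ch)]] + m[[paste0("I_nucleoplasm_", ch)]],
                     m[[paste0("I_nucleus_", ch)]])
})

test_that("dispersing GC intensity from nucleoli strictly lowers the score", {
  tc <- toy_cell()
  in_no <- tc$nucleoli$labels > 0
  in_np <- tc$nuclei$labels > 0 & !in_no
  fc <- matrix(0, tc$dim[1], tc$dim[2])
  fc[in_np] <- 1; fc[in_no] <- 50
  scores <- sapply(c(0, 0.25, 0.5, 0.75, 0.95), function(f) {
    gc <- matrix(0, tc$dim[1], tc$dim[2])
    moved <- f * 40 * sum(in_no)
    gc[in_no] <- 1 + (1 - f) * 40
    gc[in_np] <- 1 + moved / sum(in_np)
    m <- measure_cells(image_field(list(gc = gc, fc = fc)), tc$nuclei, tc$nucleoli)
    normality_score(m, "gc", "fc")
  })
  expect_true(all(diff(scores) < 0))
})

test_that("canonical-stress construction scores below normal", {
  # GC partially dispersed AND FC condensed, nucleoplasmic FC unchanged
  g_n <- generate_field(phenotype_params("normal", seed = 2, poisson = FALSE,
                                         read_sd = 0))
  g_c <- generate_field(phenotype_params("canonical_stress", seed = 2,
                                         poisson = FALSE, read_sd = 0))
  expect_lt(mean(g_c$truth$cells$analytic_score),
            mean(g_n$truth$cells$analytic_score))
  # and the FC ratio indeed rises while the GC ratio falls
  rat <- function(g, ch) mean(g$truth$cells[[paste0("I_nucleolar_", ch)]] /
                              g$truth$cells[[paste0("I_nucleoplasm_", ch)]])
  expect_gt(rat(g_c, "ubf"), rat(g_n, "ubf"))
  expect_lt(rat(g_c, "ncl"), rat(g_n, "ncl"))
})

test_that("single-channel compartment ratios behave like the uniform-field oracle", {
  # uniform channel, nucleolus 10% of nucleus area -> ratio 1/9
  nuc <- matrix(0L, 14, 14); nuc[3:12, 3:12] <- 1L
  no <- matrix(0L, 14, 14); no[3:12, 3] <- 1L
  f <- image_field(list(pol = matrix(4, 14, 14)))
  m <- measure_cells(f, label_mask(nuc), label_mask(no, parent = 1L))
  expect_equal(compartment_ratio(m, "pol"), 1 / 9)
  # relocation series: 0%, 50%, 90% to the nucleoplasm -> strictly decreasing
  in_no <- no > 0; in_np <- nuc > 0 & !in_no
  ratios <- sapply(c(0, 0.5, 0.9), function(f_rel) {
    img <- matrix(0, 14, 14)
    img[in_no] <- (1 - f_rel) * 100
    img[in_np] <- f_rel * 100 * sum(in_no) / sum(in_np) + 1e-9
    mm <- measure_cells(image_field(list(pol = img)), label_mask(nuc),
                        label_mask(no, parent = 1L))
    compartment_ratio(mm, "pol")
  })
  expect_true(all(diff(ratios) < 0))
})

test_that("field summaries average per cell and normalize to vehicle", {
  mk <- function(field_id, vals) {
    d <- data.frame(field_id = field_id, I_nucleus_eu = vals)
    d
  }
  pc <- rbind(mk("v1", c(98, 102)), mk("v2", c(99, 101)),
              mk("t1", c(19, 21)), mk("t2", c(20, 20)))
  s <- field_intensity_summary(pc, "eu", region = "nucleus")
  expect_equal(s$mean, c(100, 100, 20, 20))
  sn <- normalize_to_vehicle(s, s$field_id %in% c("v1", "v2"))
  expect_equal(sn$norm_mean, c(1, 1, 0.2, 0.2))  # 80% reduction readout
  # identical fields: all 1, zero dispersion
  pc2 <- rbind(mk("a", c(50, 50)), mk("b", c(50, 50)))
  s2 <- normalize_to_vehicle(field_intensity_summary(pc2, "eu"), c(TRUE, TRUE))
  expect_equal(s2$norm_mean, c(1, 1))
  expect_equal(s2$sd, c(0, 0))
  # brute-force per-cell averaging oracle on generator-set means
  set.seed(7)
  vals <- lapply(1:3, function(i) rnorm(10, 100 * i, 5))
  pc3 <- do.call(rbind, lapply(1:3, function(i) mk(paste0("f", i), vals[[i]])))
  s3 <- field_intensity_summary(pc3, "eu")
  expect_equal(s3$mean, sapply(vals, mean))
  expect_equal(s3$sd, sapply(vals, sd))
})
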