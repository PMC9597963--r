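mk <- function(seqs, eff, reads = NULL) {
  d <- tibble::tibble(sequence30 = seqs, efficiency = eff)
  if (!is.null(reads)) d$reads <- reads
  d
}

test_that("read filter is inclusive at the threshold", {
  d <- mk(c("s1", "s2", "s3"), c(10, 20, 30), reads = c(199, 200, 201))
  expect_equal(nrow(quiet(filter_min_reads(d, 200))), 2)
  expect_equal(quiet(filter_min_reads(d, 0)), d)
  expect_equal(nrow(quiet(filter_min_reads(d[0, ], 200))), 0)
  expect_error(filter_min_reads(mk("s", 1), 200),
    class = "guideboost_schema_error")
})

test_that("replicate averaging intersects and means", {
  a <- mk(c("s1", "s2"), c(10, 50))
  b <- mk(c("s1", "s3"), c(20, 70))
  out <- average_replicates(a, b)
  expect_equal(out, mk("s1", 15))
  expect_equal(nrow(average_replicates(mk("s1", 1), mk("s2", 2))), 0)
  expect_equal(average_replicates(a, a), a)
})

test_that("normalization is ordinary least squares of reference on source", {
  m <- fit_normalization(data.frame(source = c(10, 20, 30),
    reference = c(20, 40, 60)))
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$n_overlap, 3L)

  ident <- fit_normalization(data.frame(source = c(1, 2, 3),
    reference = c(1, 2, 3)))
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_equal(ident$slope, 1, tolerance = 1e-12)

  expect_error(fit_normalization(data.frame(source = 1, reference = 1)),
    class = "guideboost_degenerate_fit_error")
  expect_error(
    fit_normalization(data.frame(source = c(5, 5, 5), reference = 1:3)),
    class = "guideboost_degenerate_fit_error")
})

test_that("normalization recovers a planted slope from noisy pairs", {
  withr::with_seed(77, {
    src <- runif(500, 0, 100)
    ref <- 5 + 0.8 * src + rnorm(500, 0, 2)
  })
  m <- fit_normalization(data.frame(source = src, reference = ref))
  expect_lt(abs(m$slope - 0.8), 0.05)
  td <- tidy(m)
  expect_equal(td$estimate, c(m$intercept, m$slope))
  expect_equal(glance(m)$n_overlap, 500L)
})

test_that("applying a normalization is an invertible affine map", {
  d <- mk(paste0("s", 1:5), c(1, 5, 10, 50, 90))
  ident <- fit_normalization(data.frame(source = c(1, 2, 3),
    reference = c(1, 2, 3)))
  expect_equal(apply_normalization(d, ident), d)
  dbl <- fit_normalization(data.frame(source = c(10, 20, 30),
    reference = c(20, 40, 60)))
  expect_equal(apply_normalization(d, dbl)$efficiency, d$efficiency * 2)
  inv <- fit_normalization(data.frame(source = c(20, 40, 60),
    reference = c(10, 20, 30)))
  expect_equal(
    apply_normalization(apply_normalization(d, dbl), inv)$efficiency,
    d$efficiency, tolerance = 1e-9)
})

test_that("duplicate-averaged merging is order-invariant", {
  a <- mk(c("s1", "s2"), c(30, 10))
  b <- mk(c("s2", "s3"), c(50, 5))
  c3 <- mk("s1", 60)
  out <- merge_average_duplicates(a, b, c3)
  expect_equal(out$efficiency[out$sequence30 == "s2"], 30)
  expect_equal(out$efficiency[out$sequence30 == "s1"], 45)
  perms <- list(list(a, b, c3), list(c3, a, b), list(b, c3, a))
  for (p in perms) expect_equal(merge_average_duplicates(p), out)
  expect_equal(merge_average_duplicates(a, a), a[order(a$sequence30), ])
  expect_equal(merge_average_duplicates(a), a[order(a$sequence30), ])
})

test_that("positive affine rescaling preserves Spearman correlation", {
  withr::with_seed(5, {
    eff <- runif(100, 0, 100)
    covariate <- eff + rnorm(100, 0, 20)
  })
  d <- mk(paste0("s", 1:100), eff)
  m <- fit_normalization(data.frame(source = c(0, 50), reference = c(7, 100)))
  rescaled <- apply_normalization(d, m)
  expect_equal(spearman_cor(rescaled$efficiency, covariate),
    spearman_cor(eff, covariate))
})

test_that("the full harmonization pipeline recovers planted structure", {
  scr <- simulate_paired_screens(generator_config(n_guides = 800, seed = 3))
  half <- 1:400
  ts <- quiet(build_training_set(
    scr$screen_a[half, c("sequence30", "efficiency")],
    scr$screen_a[-half, c("sequence30", "efficiency")],
    scr$day8, scr$day10,
    read_threshold = 200
  ))
  counts <- setNames(ts$counts$n, ts$counts$stage)
  expect_equal(unname(counts["study1_merged"]), 800)
  expect_lte(unname(counts["overlap"]), 49)
  expect_gte(unname(counts["overlap"]), 10) # read filter removes part of the overlap
  expect_equal(
    unname(counts["final_unique"]),
    unname(counts["study1_merged"] + counts["study2_unique"] - counts["overlap"])
  )
  expect_false(any(duplicated(ts$data$sequence30)))

  # disjoint inputs cannot support a normalization fit
  a1 <- mk(paste0(strrep("A", 27), "GG", c("A", "C")), c(10, 20))
  b1 <- mk(paste0(strrep("C", 25), "GGG", c("A", "T")), c(1, 2),
    reads = c(500, 500))
  expect_error(
    quiet(build_training_set(a1, a1, b1, b1, read_threshold = 0)),
    class = "guideboost_degenerate_fit_error"
  )
})

test_that("planted affine parameters fall inside the OLS confidence interval", {
  # low-noise paired screens: 100 seeded replicates, expect >= 90 to cover
  covered <- 0L
  for (s in 1:100) {
    # wide bounds keep the planted affine link exact (no clipping)
    cfg <- generator_config(n_guides = 300, noise_sd = 0.1,
      bounds = c(-100, 200), seed = 1000 + s)
    scr <- simulate_paired_screens(cfg)
    src <- (scr$day8$efficiency + scr$day10$efficiency) / 2
    overlap <- match(scr$shared, scr$day8$sequence30)
    pairs <- data.frame(
      source = src[overlap],
      reference = scr$screen_a$efficiency[match(scr$shared,
        scr$screen_a$sequence30)]
    )
    m <- fit_normalization(pairs)
    # Bonferroni 97.5% per coefficient: a joint 95% region for (int, slope)
    ci <- confint(m$fit, level = 0.975)
    # true mapping source -> reference: intercept -a/b, slope 1/b
    a <- cfg$affine[["intercept"]]
    b <- cfg$affine[["slope"]]
    if (ci["source", 1] <= 1 / b && 1 / b <= ci["source", 2] &&
        ci["(Intercept)", 1] <= -a / b && -a / b <= ci["(Intercept)", 2]) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered, 90L)
})
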