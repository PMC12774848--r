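test_that("informative and co-segregating follow the four-library genotype pattern", {
  cfg <- scan_config()
  v <- as_variants(tibble::tibble(
    scaffold = "s1", pos = c(10, 20, 30, 40, 50, 60, 70),
    ref = "A", alt = "G",
    pass_filter = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    gt_hom_parent = c(2L, 1L, 2L, 2L, NA, 2L, 2L),
    gt_het_parent = c(1L, 1L, 1L, 1L, 1L, NA, 1L),
    gt_hom_pool = c(2L, 2L, 1L, 2L, 2L, 2L, 2L),
    gt_het_pool = c(1L, 1L, 1L, 1L, 1L, 1L, NA)
  ))
  inf <- is_informative(v, NULL, cfg)
  # canonical informative site; het parent wrong; non-PASS; missing parents
  expect_equal(inf, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  cos <- is_cosegregating(v, cfg)
  expect_true(cos[1])
  expect_false(cos[3])   # recombinant signal in hom pool
  expect_false(cos[7])   # missing pool genotype is not evidence
})

test_that("repeat-masked variants and tier classes gate informativeness", {
  cfg <- scan_config()
  bed <- file.path(tempdir(), "scan.bed")
  writeLines("s1\t14\t25", bed)   # 0-based half-open: 1-based 15..25
  m <- read_bed_mask(bed)
  v <- as_variants(toy_variants(pos = c(10, 20), ref = "A", alt = "G"))
  expect_equal(is_informative(v, m, cfg), c(TRUE, FALSE))
  indel <- as_variants(toy_variants(pos = 100, ref = "AT", alt = "A"))
  expect_false(is_informative(indel, NULL, cfg, tier = "genome"))
  expect_true(is_informative(indel, NULL, cfg, tier = "fine"))
})

test_that("auto allele orientation accepts the mirrored reference-bias pattern", {
  v <- as_variants(tibble::tibble(
    scaffold = "s1", pos = 10, ref = "A", alt = "G", pass_filter = TRUE,
    gt_hom_parent = 0L, gt_het_parent = 1L,
    gt_hom_pool = 0L, gt_het_pool = 1L
  ))
  expect_false(is_informative(v, NULL, scan_config()))
  cfg <- scan_config(allele_orientation = "auto")
  expect_true(is_informative(v, NULL, cfg))
  expect_true(is_cosegregating(v, cfg))
  v$gt_hom_pool <- 2L
  expect_false(is_cosegregating(v, cfg))
})

test_that("window proportions are exact and undefined windows are flagged", {
  # one full window: 40 informative of which 34 co-segregate -> 0.85
  v <- toy_variants(pos = seq(1000, 40000, by = 1000),
                    coseg = rep(c(TRUE, FALSE), c(34, 6)))
  scf <- tibble::tibble(scaffold = "s1", length = 2.2e6)
  w <- window_scan(as_variants(v), scf, cfg = scan_config())
  expect_equal(w$proportion[1], 0.85)
  expect_equal(w$n_informative[1], 40L)
  # windows past the variants have no informative sites
  far <- w[w$start > 1e6, ]
  expect_true(all(!far$defined))
  expect_true(all(is.na(far$proportion)))
  expect_true(all(w$truncated == (w$end - w$start + 1 < 1e6)))
  expect_error(window_scan(v[c(2, 1), ], scf), "sort")
})

test_that("window counts equal a brute-force recount on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    n_scf <- sample(1:4, 1)
    scf <- tibble::tibble(scaffold = paste0("s", seq_len(n_scf)),
                          length = sample(seq(1.2e6, 4e6, by = 1e5), n_scf))
    v <- as_variants(random_variants(sample(100:1500, 1), scf$scaffold, 4e6))
    w <- tidy(window_scan(v, scf))
    bf <- brute_force_windows(v, scf)
    expect_equal(w$n_informative, bf$n_informative)
    expect_equal(w$n_coseg, bf$n_coseg)
    expect_equal(w[, c("scaffold", "start", "end")],
                 bf[, c("scaffold", "start", "end")])
  }
})

test_that("non-overlapping step-aligned tiles conserve total informative counts", {
  set.seed(5)
  scf <- tibble::tibble(scaffold = c("a", "b"), length = c(3e6, 2e6))
  v <- as_variants(random_variants(2000, scf$scaffold, 2e6))
  cfg <- scan_config(window_bp = 2e5, step_bp = 2e5)  # tiles
  w <- tidy(window_scan(v, scf, cfg = cfg))
  inf <- is_informative(v, NULL, cfg)
  for (s in scf$scaffold) {
    expect_equal(sum(w$n_informative[w$scaffold == s]),
                 sum(inf & v$scaffold == s & v$pos <= scf$length[scf$scaffold == s]))
  }
})

test_that("fine scan includes indels and agrees with the coarse scan on shared classes", {
  pos <- seq(5000, 195000, by = 5000)
  v <- toy_variants(pos = pos)
  v$ref[10] <- "AT"; v$alt[10] <- "A"   # an informative, co-segregating indel
  v <- as_variants(v)
  cfg <- scan_config(window_bp = 2e5, step_bp = 2e5, min_scaffold_bp = 1e5,
                     fine_window_bp = 5e4, fine_step_bp = 5e4)
  scf <- tibble::tibble(scaffold = "s1", length = 2e5)
  coarse <- window_scan(v, scf, cfg = cfg)
  fine <- fine_scan(v, "s1", c(1, 2e5), cfg = cfg)
  expect_equal(sum(fine$n_informative), sum(coarse$n_informative) + 1L)
  expect_equal(sum(fine$n_coseg), sum(coarse$n_coseg) + 1L)
  # same stream restricted to SNP/MNP gives identical pooled counts
  cfg2 <- scan_config(window_bp = 2e5, step_bp = 2e5, min_scaffold_bp = 1e5,
                      fine_window_bp = 5e4, fine_step_bp = 5e4,
                      fine_classes = c("SNP", "MNP"))
  fine2 <- fine_scan(v, "s1", c(1, 2e5), cfg = cfg2)
  expect_equal(sum(fine2$n_informative), sum(coarse$n_informative))
  expect_equal(nrow(fine_scan(v, "s1", c(5, 2), cfg = cfg)), 0)
})

test_that("peak calling merges adjacent high windows and recounts over the span", {
  # three overlapping windows above threshold
  w <- tibble::tibble(
    scaffold = "s1",
    start = c(1, 50001, 100001, 500001),
    end = c(100000, 150000, 200000, 600000),
    n_informative = c(100L, 100L, 100L, 100L),
    n_coseg = c(90L, 92L, 88L, 10L),
    proportion = c(0.90, 0.92, 0.88, 0.10),
    defined = TRUE, truncated = FALSE
  )
  class(w) <- c("coseg_windows", class(w))
  attr(w, "scaffolds") <- tibble::tibble(scaffold = "s1", length = 6e5)
  v <- as_variants(toy_variants(pos = seq(1000, 199000, by = 1000)))
  cfg <- scan_config(proportion_threshold = 0.85, min_interval_coseg = 10)
  p <- call_peaks(w, v, cfg = cfg)
  expect_equal(nrow(p), 1)
  expect_equal(p$start, 1)
  expect_equal(p$end, 200000)
  expect_equal(p$max_proportion, 0.92)
  # recounted over the span, not summed over overlapping windows
  expect_equal(p$n_coseg_total, 199L)
  expect_false(p$disregarded)
  expect_equal(p$rank, 1L)
})

test_that("peaks with too few co-segregating variants are flagged disregarded", {
  v <- as_variants(toy_variants(pos = seq(10000, 90000, by = 10000)))  # 9 coseg
  scf <- tibble::tibble(scaffold = "s1", length = 1.2e6)
  cfg <- scan_config(window_bp = 1e5, step_bp = 1e5, min_scaffold_bp = 1e6,
                     proportion_threshold = 0.5, min_interval_coseg = 100)
  w <- window_scan(v, scf, cfg = cfg)
  p <- call_peaks(w, v, cfg = cfg)
  expect_equal(p$n_coseg_total, 9L)
  expect_true(p$disregarded)
  expect_true(is.na(p$rank))
})

test_that("equal-proportion intervals are ranked by co-segregating count then position", {
  v1 <- toy_variants(scaffold = "s1", pos = seq(1000, 50000, by = 1000))
  v2 <- toy_variants(scaffold = "s2", pos = seq(1000, 30000, by = 1000))
  v <- as_variants(dplyr::bind_rows(v1, v2))
  scf <- tibble::tibble(scaffold = c("s1", "s2"), length = c(2e6, 1.5e6))
  cfg <- scan_config(window_bp = 1e5, step_bp = 1e5, min_scaffold_bp = 1e6,
                     proportion_threshold = 0.9, min_interval_coseg = 5)
  w <- window_scan(v, scf, cfg = cfg)
  p <- call_peaks(w, v, cfg = cfg)
  # both intervals at proportion 1; s1 has more co-segregating variants
  expect_equal(p$scaffold[p$rank == 1], "s1")
  expect_equal(p$scaffold[p$rank == 2], "s2")
  expect_true(all(p$max_proportion == 1))
})

test_that("interval metrics reproduce width and density arithmetic", {
  m <- interval_metrics(51.9e6, 56.7e6, 13906)
  expect_equal(m$width_mb, 4.8)
  expect_equal(m$density_per_mb, 2897)
  m2 <- interval_metrics(c(26.7e6, 31.7e6), c(28e6, 32.8e6), 6201)
  expect_equal(m2$width_mb, 2.4)
  expect_equal(m2$density_per_mb, 2584)
  expect_equal(interval_metrics(1.85e6, 3.85e6, 5967)$width_mb, 2)
  expect_error(interval_metrics(100, 50, 10), "width")
})

test_that("diagnostic markers pick co-segregating SNPs nearest each interval edge", {
  v <- toy_variants(pos = seq(1000, 100000, by = 1000))
  v$ref[5] <- "AT"; v$alt[5] <- "GC"     # MNP: not a diagnostic marker
  v <- as_variants(v)
  interval <- list(scaffold = "s1", start = 1, end = 100000)
  d <- diagnostic_markers(v, interval, k = 3)
  expect_equal(sum(d$edge == "start"), 3)
  expect_equal(sum(d$edge == "end"), 3)
  expect_equal(d$pos[d$edge == "start"], c(1000, 2000, 3000))
  expect_equal(d$pos[d$edge == "end"], c(100000, 99000, 98000))
  d1 <- diagnostic_markers(v, interval, k = 1)
  expect_equal(d1$pos, c(1000, 100000))
  empty <- diagnostic_markers(v, list(scaffold = "s9", start = 1, end = 10), k = 2)
  expect_equal(nrow(empty), 0)
})

test_that("scan results carry tidy, glance and autoplot methods", {
  sim <- simulate_cross(small_cross_cfg(seed = 3))
  w <- window_scan(sim$variants, sim$scaffolds, cfg = small_scan_cfg())
  expect_s3_class(tidy(w), "tbl_df")
  g <- glance(w)
  expect_equal(g$n_windows, nrow(w))
  p <- call_peaks(w, sim$variants, cfg = small_scan_cfg())
  expect_s3_class(glance(p), "tbl_df")
  expect_s3_class(autoplot(w), "ggplot")
  expect_s3_class(autoplot(p), "ggplot")
})
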