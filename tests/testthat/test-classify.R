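test_that("priority rules fire per the five contamination patterns", {
  cfg <- classifier_config()
  rec_mixed <- profile_record("m", c(30, 50, 70, 40, 60, 55),
                              rep(c("a", "b"), each = 3))
  expect_equal(assign_priority(rec_mixed, 0.03, cfg)$priority, 1L)
  expect_equal(assign_priority(rec_mixed, 0.07, cfg)$priority, 2L)
  expect_equal(assign_priority(rec_mixed, 0.6, cfg)$priority, 3L)

  rec_high <- profile_record("h", rep(85, 10), rep(c("a", "b"), each = 5))
  expect_equal(assign_priority(rec_high, 0.6, cfg)$priority, 4L)

  rec_low <- profile_record("l", c(rep(15, 9), 50), rep(c("a", "b"), each = 5))
  expect_equal(assign_priority(rec_low, 0.6, cfg)$priority, 5L)
})

test_that("priority boundaries follow the printed inequalities", {
  cfg <- classifier_config()
  rec <- profile_record("b", c(30, 50, 70, 40, 60, 55), rep(c("a", "b"), each = 3))
  # adjusted p exactly at the strong cutoff falls to priority 2
  expect_equal(assign_priority(rec, 0.05, cfg)$priority, 2L)
  expect_equal(assign_priority(rec, 0.1, cfg)$priority, 3L)
  # rank exactly 80 counts as high (>= cut) but exactly 80% of samples does not
  # (> fraction): 8 of 10 high-ranked samples is not enough
  rec80 <- profile_record("e", c(rep(80, 8), 50, 50), rep(c("a", "b"), each = 5))
  expect_equal(assign_priority(rec80, 0.6, cfg)$frac_high, 0.8)
  expect_equal(assign_priority(rec80, 0.6, cfg)$priority, 3L)
  rec9 <- profile_record("f", c(rep(80, 9), 50), rep(c("a", "b"), each = 5))
  expect_equal(assign_priority(rec9, 0.6, cfg)$priority, 4L)
  # NA adjusted p: uniform patterns still classifiable, mixed is NA
  expect_equal(assign_priority(rec9, NA_real_, cfg)$priority, 4L)
  expect_true(is.na(assign_priority(rec, NA_real_, cfg)$priority))
})

test_that("profile ANOVA delegates to the shared primitive", {
  rec <- profile_record("p", c(10, 20, 30, 70, 80, 90), rep(c("a", "b"), each = 3))
  res <- profile_anova(rec)
  expect_equal(res$statistic, 54)
  expect_equal(res$p_value, 0.00182626066826, tolerance = 1e-9)
  expect_true(is.na(profile_anova(profile_record("q", 1:4, rep("g", 4)))$p_value))
})

test_that("the five-pattern fixture classifies as 1, 2, 4, 5 and 3", {
  cls <- classify_profiles(priority_fixture())
  got <- setNames(cls$assignments$priority, cls$assignments$profile_id)
  expect_identical(got, c(A = 1L, B = 2L, C = 4L, D = 5L, E = 3L))
  expect_equal(cls$n_retained, 5L)
  expect_equal(sum(cls$summary$fraction), 1)
  expect_equal(cls$summary$fraction, rep(0.2, 5))
})

test_that("profiles are exhaustively and uniquely classified", {
  set.seed(99)
  recs <- lapply(1:40, function(i) {
    profile_record(paste0("r", i), runif(10, 0, 100),
                   rep(c("a", "b"), each = 5))
  })
  cls <- classify_profiles(recs)
  retained <- cls$assignments[!is.na(cls$assignments$anova_p), ]
  expect_true(all(retained$priority %in% 1:5))
  expect_equal(cls$n_retained, nrow(retained))
  expect_equal(sum(cls$summary$n), cls$n_retained)
})

test_that("NA-ANOVA profiles drop out of the family and the denominator", {
  recs <- c(priority_fixture(),
            list(single = profile_record("single", c(50, 60, 70), rep("g", 3))))
  cls <- classify_profiles(recs)
  expect_equal(cls$n_total, 6L)
  expect_equal(cls$n_retained, 5L)
  # same Bonferroni family as without the degenerate profile
  ref <- classify_profiles(priority_fixture())
  expect_equal(cls$assignments$adjusted_p[1:5], ref$assignments$adjusted_p)

  allna <- classify_profiles(list(profile_record("x", c(1, 2), c("g", "g"))))
  expect_equal(allna$n_retained, 0L)
  expect_equal(nrow(allna$summary), 0L)
  expect_error(classify_profiles(list()), "no profiles")
})

test_that("duplicating every profile doubles m but keeps summary fractions", {
  # fixture built so no adjusted p crosses a cutoff when the family doubles
  # (the moderate-band profile is excluded: its assignment is m-sensitive by
  # construction); A's adjusted p goes 3e-6 -> 6e-6, C/D/E sit at p = 1
  recs <- priority_fixture()[c("A", "C", "D", "E")]
  once <- classify_profiles(recs)
  twice <- classify_profiles(c(recs, setNames(recs, paste0(names(recs), "2"))))
  expect_equal(twice$summary$fraction, once$summary$fraction)
  expect_equal(twice$assignments$adjusted_p[1],
               min(1, 2 * once$assignments$adjusted_p[1]))
})

test_that("shrinking group separation never decreases the adjusted p", {
  low <- c(10, 20, 30)
  high0 <- c(70, 80, 90)
  adj_seq <- vapply(seq(1, 0, by = -0.1), function(t) {
    rec <- profile_record("m", c(low, low + t * (high0 - low)),
                          rep(c("a", "b"), each = 3))
    classify_profiles(list(rec))$assignments$adjusted_p
  }, numeric(1))
  expect_true(all(diff(adj_seq) >= -1e-12))
})

test_that("long-format profile tables round-trip", {
  recs <- priority_fixture()
  long <- do.call(rbind, lapply(recs, function(r) {
    data.frame(profile_id = r$profile_id, sample_id = r$sample_ids,
               group = r$group, rank = r$marker_rank, stringsAsFactors = FALSE)
  }))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(long, path)
  back <- read_profiles(path)
  expect_length(back, 5L)
  expect_equal(back[[1]]$marker_rank, recs$A$marker_rank)
  expect_equal(classify_profiles(back)$assignments$priority,
               classify_profiles(recs)$assignments$priority)
})
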