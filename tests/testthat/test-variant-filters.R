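base_record <- function(...) {
  rec <- tibble::tibble(depth = 40, read_quality = 35, mapping_quality = 40,
                        base_quality = 35, contig_end_distance = 1000)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

test_that("substitution filter thresholds are inclusive at stated values", {
  cases <- list(
    # field           at value  below  above  rule label
    list("depth", 10, 9, NA, "coverage"),
    list("depth", 150, 151, NA, "coverage"),
    list("read_quality", 30, 29, NA, "read_quality"),
    list("mapping_quality", 30, 29, NA, "mapping_quality"),
    list("base_quality", 30, 29, NA, "base_quality"),
    list("contig_end_distance", 500, 499, NA, "contig_end")
  )
  for (cs in cases) {
    field <- cs[[1]]
    rec_at <- base_record(); rec_at[[field]] <- cs[[2]]
    expect_true(filter_substitutions(rec_at)$pass,
                label = paste(field, "at threshold"))
    rec_off <- base_record(); rec_off[[field]] <- cs[[3]]
    out_off <- filter_substitutions(rec_off)
    expect_false(out_off$pass, label = paste(field, "just outside"))
    expect_equal(out_off$fail_rule, cs[[5]])
    rec_in <- base_record(); rec_in[[field]] <- cs[[2]] + ifelse(cs[[2]] %in% c(150), -1, 1)
    expect_true(filter_substitutions(rec_in)$pass,
                label = paste(field, "one inside"))
  }
})

test_that("rejections are attributed to the first failed rule in fixed order", {
  rec <- base_record(depth = 5, read_quality = 10, mapping_quality = 10)
  expect_equal(filter_substitutions(rec)$fail_rule, "coverage")
  rec2 <- base_record(read_quality = 10, base_quality = 10)
  expect_equal(filter_substitutions(rec2)$fail_rule, "read_quality")
})

test_that("substitution and indel filters are idempotent on passing sets", {
  set.seed(31)
  recs <- tibble::tibble(depth = sample(10:150, 50, TRUE),
                         read_quality = sample(30:60, 50, TRUE),
                         mapping_quality = sample(30:60, 50, TRUE),
                         base_quality = sample(30:60, 50, TRUE),
                         contig_end_distance = sample(500:5000, 50, TRUE))
  once <- filter_substitutions(recs) |> dplyr::filter(pass)
  twice <- filter_substitutions(once |> dplyr::select(-pass, -fail_rule)) |>
    dplyr::filter(pass)
  expect_equal(nrow(once), 50L)
  expect_equal(nrow(twice), nrow(once))
})

test_that("indel filter respects both quality thresholds inclusively", {
  expect_true(filter_indels(tibble::tibble(q_snp = 30, q_max_gtype = 5))$pass)
  expect_false(filter_indels(tibble::tibble(q_snp = 29, q_max_gtype = 100))$pass)
  expect_false(filter_indels(tibble::tibble(q_snp = 100, q_max_gtype = 4))$pass)
  expect_true(filter_indels(tibble::tibble(q_snp = 31, q_max_gtype = 6))$pass)
  empty <- filter_indels(tibble::tibble(q_snp = numeric(), q_max_gtype = numeric()))
  expect_equal(nrow(empty), 0L)
})

test_that("discordant-pair clusters require seven qualifying reads", {
  lens <- c(c1 = 1e5, c2 = 1e5)
  mk_pairs <- function(n, mq) {
    tibble::tibble(contig1 = "c1", pos1 = 50000 + seq_len(n),
                   strand1 = "+", contig2 = "c2",
                   pos2 = 30000 + seq_len(n), strand2 = "-", mq = mq)
  }
  expect_equal(nrow(cluster_discordant_pairs(mk_pairs(7, 30), lens)), 1L)
  expect_equal(nrow(cluster_discordant_pairs(mk_pairs(6, 30), lens)), 0L)
  # 10 pairs but only 5 qualifying by mapping quality
  mixed <- mk_pairs(10, c(rep(30, 5), rep(29, 5)))
  expect_equal(nrow(cluster_discordant_pairs(mixed, lens)), 0L)
  # boundary: MQ exactly 30 counts
  expect_equal(cluster_discordant_pairs(mk_pairs(7, 30), lens)$n_support, 7L)
})

test_that("contig-end pairs are excluded before clustering", {
  lens <- c(c1 = 10000, c2 = 10000)
  good <- tibble::tibble(contig1 = "c1", pos1 = 5000 + 1:7, strand1 = "+",
                         contig2 = "c2", pos2 = 5000 + 1:7, strand2 = "-",
                         mq = 60)
  near <- good |> dplyr::mutate(pos1 = 100 + 1:7)    # within 500 of start
  expect_equal(nrow(cluster_discordant_pairs(good, lens)), 1L)
  expect_equal(nrow(cluster_discordant_pairs(near, lens)), 0L)
  expect_error(cluster_discordant_pairs(good, c(c1 = 10000)), "missing contig")
})

test_that("clustering is invariant to input row order", {
  set.seed(17)
  lens <- c(c1 = 1e5, c2 = 1e5, c3 = 1e5)
  pairs <- dplyr::bind_rows(
    tibble::tibble(contig1 = "c1", pos1 = 40000 + sample(-100:100, 9, TRUE),
                   strand1 = "+", contig2 = "c2",
                   pos2 = 20000 + sample(-100:100, 9, TRUE), strand2 = "-",
                   mq = 60),
    tibble::tibble(contig1 = "c3", pos1 = 70000 + sample(-100:100, 8, TRUE),
                   strand1 = "+", contig2 = "c3",
                   pos2 = 80000 + sample(-100:100, 8, TRUE), strand2 = "+",
                   mq = 60))
  a <- cluster_discordant_pairs(pairs, lens)
  b <- cluster_discordant_pairs(pairs[sample(nrow(pairs)), ], lens)
  expect_equal(a, b)
  expect_setequal(a$orientation, c("inter_contig", "inverted"))
})

test_that("microhomology equals a brute-force overlap search", {
  expect_equal(breakpoint_microhomology("AAAACCC", "GGGTTTT", 6), 0L)
  expect_equal(breakpoint_microhomology("TTTACGT", "ACGTGGG", 6), 4L)
  # identical sequences cap at max_len
  expect_equal(breakpoint_microhomology("ACGTACGTAC", "ACGTACGTAC", 6), 6L)
  expect_error(breakpoint_microhomology("", "ACGTAA", 4), "at least|empty")

  set.seed(19)
  brute <- function(l, r, mx) {
    best <- 0L
    for (n in seq_len(mx)) {
      if (substring(l, nchar(l) - n + 1) == substring(r, 1, n)) best <- n
    }
    best
  }
  for (i in 1:200) {
    mh <- sample(0:6, 1)
    left <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    if (mh > 0) {
      right <- paste0(substring(left, 12 - mh + 1), substring(right, mh + 1))
    }
    expect_identical(breakpoint_microhomology(left, right, 6),
                     brute(left, right, 6))
  }
})

test_that("copy-number windows honour the null, sentinels and antisymmetry", {
  # exactly proportional counts: all log2 zero, nothing flagged
  grid <- tibble::tibble(contig = "c1", start = seq(0, by = 2000,
                                                    length.out = 50))
  t0 <- grid |> dplyr::mutate(count = 100)
  n0 <- grid |> dplyr::mutate(count = 200)
  cn0 <- copy_number_windows(t0, n0)
  expect_true(all(cn0$log2_ratio == 0))
  expect_false(any(cn0$flag))

  # zero-tumour windows take the -4 sentinel and are testable
  t1 <- t0; t1$count[1] <- 0
  cn1 <- copy_number_windows(t1, n0)
  expect_equal(cn1$log2_ratio[1], -4)
  expect_true(cn1$flag[1])

  # swapping tumour and normal flips the sign (sentinels aside)
  set.seed(3)
  ta <- grid |> dplyr::mutate(count = rpois(50, 80) + 1)
  nb <- grid |> dplyr::mutate(count = rpois(50, 80) + 1)
  expect_equal(copy_number_windows(ta, nb)$log2_ratio,
               -copy_number_windows(nb, ta)$log2_ratio)

  expect_error(copy_number_windows(t0, n0[-1, ]), "grid")
})

test_that("a planted hemizygous deletion is visible in the log2 track", {
  set.seed(101)
  n_win <- 2000
  grid <- tibble::tibble(contig = "c1",
                         start = seq(0, by = 2000, length.out = n_win))
  seg <- 1001:1100
  lam_t <- rep(200, n_win); lam_t[seg] <- 100
  tum <- grid |> dplyr::mutate(count = rpois(n_win, lam_t))
  nor <- grid |> dplyr::mutate(count = rpois(n_win, 200))
  cn <- copy_number_windows(tum, nor)
  expect_gte(mean(cn$log2_ratio[seg] < -0.7), 0.9)
  expect_lt(mean(cn$log2_ratio[-seg] < -0.7), 0.01)
})

test_that("exon coverage screen uses a strict mean-depth threshold", {
  depth <- tibble::tibble(contig = "c1", pos = 1:100, depth = 10)
  exons <- tibble::tibble(exon_id = "e1", contig = "c1", start = 0, end = 100)
  expect_false(low_coverage_exon_screen(depth, exons)$flagged)

  depth2 <- depth |> dplyr::mutate(depth = 9.5)
  expect_true(low_coverage_exon_screen(depth2, exons)$flagged)

  # half uncovered, half deep: the mean decides
  depth3 <- tibble::tibble(contig = "c1", pos = 51:100, depth = 18)
  out3 <- low_coverage_exon_screen(depth3, exons)
  expect_equal(out3$mean_depth, 9)
  expect_true(out3$flagged)

  expect_error(low_coverage_exon_screen(
    depth, tibble::tibble(exon_id = "z", contig = "c1", start = 5, end = 5)),
    "length")
})
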