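test_that("a fixed seed reproduces the generator byte for byte", {
  p <- small_params(seed = 5)
  r1 <- simulate_reference(p)
  r2 <- simulate_reference(p)
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(r1$contigs, r2$contigs)
  c1 <- simulate_cohort(p, r1)
  c2 <- simulate_cohort(p, r2)
  expect_identical(c1$variants, c2$variants)
  g1 <- simulate_genotype_cohort(p)
  g2 <- simulate_genotype_cohort(p)
  expect_identical(g1$matrix, g2$matrix)
  # a different seed changes the output
  expect_false(identical(simulate_reference(small_params(seed = 6))$sequences,
                         r1$sequences))
})

test_that("reference simulation conserves total length and honours chimera settings", {
  p <- cohort_params(genome_length = 100000, n_contigs = 10, seed = 3)
  ref <- simulate_reference(p)
  expect_equal(sum(nchar(ref$sequences)), 100000)
  expect_equal(sum(ref$contigs$length), 100000)

  clean <- simulate_reference(cohort_params(genome_length = 5e4,
                                            n_contigs = 10,
                                            chimera_fraction = 0, seed = 3))
  expect_false(any(clean$contigs$chimeric))
  expect_true(all(is.na(clean$contigs$junction)))

  expect_error(cohort_params(genome_length = 0), "genome_length")
})

test_that("tumour variant sets reflect the lineage structure", {
  # no branch divergence: the two tumour sets coincide
  p0 <- small_params(seed = 7, somatic_rate_per_branch = 0,
                     cnv_loss_fraction = 0)
  co0 <- simulate_cohort(p0)
  key <- function(x) sort(variant_key(x$contig, x$pos, x$alt))
  expect_identical(key(co0$variants$tumor_a), key(co0$variants$tumor_b))

  # no germline input at all: tumours carry only somatic variants
  pg <- small_params(seed = 7, germline_het_rate = 0,
                     founder_private_rate = 0, cnv_loss_fraction = 0)
  cog <- simulate_cohort(pg)
  somatic_keys <- c(cog$truth$trunk, cog$truth$branch_a)
  expect_setequal(key(cog$variants$tumor_a), sort(somatic_keys))
  expect_equal(nrow(cog$variants$normal_female), 0L)

  # conservation: |A-unique| + |B-unique| + |common| = |A union B|
  p <- small_params(seed = 19)
  co <- simulate_cohort(p)
  ka <- key(co$variants$tumor_a); kb <- key(co$variants$tumor_b)
  expect_equal(length(setdiff(ka, kb)) + length(setdiff(kb, ka)) +
                 length(intersect(ka, kb)), length(union(ka, kb)))
})

test_that("branch mutation counts follow the configured Poisson mean", {
  counts <- vapply(1:60, function(s) {
    co <- simulate_cohort(cohort_params(genome_length = 4e4, n_contigs = 4,
                                        germline_het_rate = 0,
                                        founder_private_rate = 0,
                                        somatic_rate_trunk = 0,
                                        somatic_rate_per_branch = 500,
                                        cnv_loss_fraction = 0, seed = s))
    length(co$truth$branch_a)
  }, numeric(1))
  # mean of 60 Poisson(500) draws: sd of the mean = sqrt(500/60)
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(500 / 60))
})

test_that("library profiles respect purity settings and chimeric structure", {
  # zero contamination, no chimeras: every contig is single-library
  p0 <- small_params(seed = 23, library_contamination = 0,
                     chimera_fraction = 0)
  sim0 <- simulate_chromosome_libraries(p0)
  per <- sim0$profiles |> dplyr::count(contig, library) |>
    dplyr::count(contig)
  expect_true(all(per$n == 1))

  # chimeric contig: two coordinate-contiguous runs of source libraries
  p1 <- cohort_params(genome_length = 4e4, n_contigs = 4,
                      chimera_fraction = 0.25, library_contamination = 0,
                      seed = 31)
  ref1 <- simulate_reference(p1)
  sim1 <- simulate_chromosome_libraries(p1, ref1)
  chim <- ref1$contigs |> dplyr::filter(chimeric)
  reads <- sim1$profiles |> dplyr::filter(contig == chim$contig[1]) |>
    dplyr::arrange(position)
  runs <- rle(reads$library)
  expect_equal(length(runs$values), 2L)
  expect_lte(max(reads$position[cumsum(runs$lengths)[1]]), chim$junction[1])

  # contamination rate is recovered within binomial noise
  p2 <- small_params(seed = 37, library_contamination = 0.1,
                     chimera_fraction = 0)
  sim2 <- simulate_chromosome_libraries(p2)
  off <- mean(sim2$truth$contaminated)
  n <- nrow(sim2$truth)
  expect_lt(abs(off - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  expect_error(cohort_params(library_contamination = 0.6),
               "library_contamination")
})

test_that("fixture bundles round-trip and checksum deterministically", {
  p <- small_params(seed = 13)
  ref <- simulate_reference(p)
  co <- simulate_cohort(p, ref)
  libs <- simulate_chromosome_libraries(p, ref)
  gcx <- simulate_genotype_cohort(p)
  d1 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(list(reference = ref, cohort = co,
                                  libraries = libs, genotypes = gcx), d1)
  expect_true(all(file.exists(m1$path)))

  # VCF round trip reproduces the in-memory variant tables
  back <- read_minimal_vcf(file.path(d1, "tumor_b.vcf"))
  orig <- co$variants$tumor_b |> dplyr::arrange(contig, pos)
  expect_equal(back |> dplyr::select(contig, pos, ref, alt, genotype),
               orig |> dplyr::select(contig, pos, ref, alt, genotype))
  # TSV round trip of the genotype matrix
  gm_back <- readr::read_tsv(file.path(d1, "genotype_matrix.tsv"),
                             show_col_types = FALSE)
  expect_equal(as.data.frame(gm_back), as.data.frame(gcx$matrix))

  # identical seed, fresh directory: identical checksums
  d2 <- withr::local_tempdir()
  m2 <- write_fixture_bundle(list(reference = simulate_reference(p),
                                  cohort = simulate_cohort(p),
                                  libraries = simulate_chromosome_libraries(p),
                                  genotypes = simulate_genotype_cohort(p)), d2)
  expect_equal(m1$md5, m2$md5)

  # no components: only a (valid) truth record is emitted
  d3 <- withr::local_tempdir()
  m3 <- write_fixture_bundle(list(), d3)
  expect_equal(nrow(m3), 1L)
  expect_true(jsonlite::validate(readr::read_file(m3$path[1])))
})

test_that("FASTA output is readable with standard tooling", {
  p <- cohort_params(genome_length = 2e4, n_contigs = 4, seed = 43)
  ref <- simulate_reference(p)
  d <- withr::local_tempdir()
  write_fixture_bundle(list(reference = ref), d)
  seqs <- Biostrings::readDNAStringSet(file.path(d, "reference.fasta"))
  expect_equal(length(seqs), 4L)
  expect_equal(unname(as.character(seqs)), unname(ref$sequences))
})
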