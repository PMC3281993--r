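vset <- function(keys, genotype = "het") {
  parts <- stringr::str_split_fixed(keys, ":", 3)
  tibble::tibble(contig = parts[, 1], pos = as.integer(parts[, 2]),
                 alt = parts[, 3], genotype = genotype)
}

test_that("four-genome partition obeys the set identities", {
  a <- vset(c("c1:1:A", "c1:2:T", "c1:3:G"))
  # identical genomes leave nothing private or unique
  pid <- partition_variants(a, a, a, a)
  expect_equal(pid$counts$n[pid$counts$category == "tumor_private"], 0L)
  expect_equal(nrow(pid$a_unique), 0L)
  expect_equal(nrow(pid$b_unique), 0L)

  # disjoint tumours share nothing
  b <- vset(c("c2:5:C", "c2:9:A"))
  pdis <- partition_variants(a[0, ], a[0, ], a, b)
  expect_equal(nrow(pdis$tumor_common), 0L)
  expect_equal(nrow(pdis$a_unique), 3L)
  expect_equal(nrow(pdis$b_unique), 2L)

  expect_error(partition_variants(a, a, dplyr::bind_rows(a, a[1, ]), b),
               "duplicate")
})

test_that("partition categories are disjoint and cover the tumour union", {
  p <- small_params(seed = 47)
  co <- simulate_cohort(p)
  pa <- partition_variants(co$variants$normal_female, co$variants$normal_male,
                           co$variants$tumor_a, co$variants$tumor_b)
  key <- function(x) variant_key(x$contig, x$pos, x$alt)
  ka <- key(co$variants$tumor_a); kb <- key(co$variants$tumor_b)
  expect_equal(length(key(pa$a_unique)) + length(key(pa$b_unique)) +
                 length(key(pa$tumor_common)),
               length(union(ka, kb)))
  expect_length(intersect(key(pa$tumor_private), key(pa$shared_with_normal)), 0)
  expect_setequal(c(key(pa$tumor_private), key(pa$shared_with_normal)),
                  key(pa$tumor_common))
  # swapping the tumour labels swaps the unique sets and fixes the rest
  pb <- partition_variants(co$variants$normal_female, co$variants$normal_male,
                           co$variants$tumor_b, co$variants$tumor_a)
  expect_equal(pb$a_unique, pa$b_unique)
  expect_equal(pb$tumor_common |> dplyr::arrange(contig, pos),
               pa$tumor_common |> dplyr::arrange(contig, pos))
})

test_that("planted branch-somatic variants are recovered as tumour-unique", {
  p <- small_params(seed = 53)
  co <- simulate_cohort(p)
  pa <- partition_variants(co$variants$normal_female, co$variants$normal_male,
                           co$variants$tumor_a, co$variants$tumor_b)
  au <- variant_key(pa$a_unique$contig, pa$a_unique$pos, pa$a_unique$alt)
  bu <- variant_key(pa$b_unique$contig, pa$b_unique$pos, pa$b_unique$alt)
  expect_gte(mean(co$truth$branch_a %in% au), 0.95)
  expect_gte(mean(co$truth$branch_b %in% bu), 0.95)
})

test_that("founder sex inference follows the SRY and X-dosage rules", {
  x <- c(normal_female = 1000, normal_male = 500,
         tumor_a = 980, tumor_b = 1015)
  sry_no <- c(tumor_a = FALSE, tumor_b = FALSE)
  expect_equal(infer_founder_sex(x, sry_no)$call, "female")
  expect_equal(infer_founder_sex(x, c(tumor_a = TRUE, tumor_b = FALSE))$call,
               "male")
  # X dosage resembling the male normal: not called female
  x_low <- c(normal_female = 1000, normal_male = 500,
             tumor_a = 600, tumor_b = 620)
  expect_equal(infer_founder_sex(x_low, sry_no)$call, "indeterminate")
  expect_error(infer_founder_sex(x[-2], sry_no), "normal_male")
})

test_that("heterozygous fraction is a plain proportion with guarded input", {
  expect_equal(heterozygous_fraction(tibble::tibble(genotype = rep("het", 4))),
               1)
  expect_equal(heterozygous_fraction(
    tibble::tibble(genotype = c("het", "het", "het", "hom"))), 0.75)
  expect_error(heterozygous_fraction(tibble::tibble(genotype = character())),
               "empty")
  p <- small_params(seed = 59, cnv_loss_fraction = 0)
  co <- simulate_cohort(p)
  somatic <- co$truth$origins |>
    dplyr::filter(origin == "branch_a_somatic") |>
    dplyr::mutate(genotype = "het")
  expect_equal(heterozygous_fraction(somatic), 1)
})

test_that("mutation spectrum collapses strands into six classes", {
  expect_equal(substitution_class("C", "T"), "G:C>A:T")
  expect_equal(substitution_class("A", "C"), substitution_class("T", "G"))
  sp <- mutation_spectrum(tibble::tibble(ref = rep("C", 10),
                                         alt = rep("T", 10)))
  expect_equal(sp$proportion[sp$class == "G:C>A:T"], 1)
  expect_equal(sum(sp$proportion), 1)
  expect_error(mutation_spectrum(tibble::tibble(ref = "A", alt = "A")),
               "not a substitution")
})

test_that("simulated somatic spectra match the generator weights", {
  p <- small_params(seed = 61, genome_length = 2e5, n_contigs = 10,
                    somatic_rate_per_branch = 2000)
  co <- simulate_cohort(p)
  somatic <- co$truth$origins |>
    dplyr::filter(origin %in% c("branch_a_somatic", "branch_b_somatic"))
  sp <- mutation_spectrum(somatic)
  gof <- suppressWarnings(
    chisq.test(sp$n, p = p$spectrum_weights[sp$class]))
  expect_gt(gof$p.value, 0.01)
})

test_that("codon classification matches direct genetic-code lookups", {
  # one gene, plus strand: ATG TTA TAA
  ref <- c(c1 = "ATGTTATAA")
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", strand = "+",
                          start = 0, end = 9)
  # third-position change in a four-fold codon family is synonymous
  res_s <- ns_s_ratio(tibble::tibble(contig = "c1", pos = 6, ref = "A",
                                     alt = "G"), genes, ref)
  expect_equal(res_s$classified$consequence, "S")  # TTA -> TTG (Leu)
  res_ns <- ns_s_ratio(tibble::tibble(contig = "c1", pos = 1, ref = "A",
                                      alt = "C"), genes, ref)
  expect_equal(res_ns$classified$consequence, "NS") # ATG -> CTG

  # all nine single-base changes of codon 2 (TTA), against a direct oracle
  gc_tab <- Biostrings::GENETIC_CODE
  muts <- tidyr::expand_grid(offset = 1:3, alt = c("A", "C", "G", "T")) |>
    dplyr::mutate(ref = substring("TTA", offset, offset)) |>
    dplyr::filter(alt != ref)
  expected <- vapply(seq_len(nrow(muts)), function(i) {
    codon <- "TTA"
    substr(codon, muts$offset[i], muts$offset[i]) <- muts$alt[i]
    if (gc_tab[[codon]] == gc_tab[["TTA"]]) "S" else "NS"
  }, character(1))
  res_all <- ns_s_ratio(muts |>
                          dplyr::transmute(contig = "c1", pos = offset + 3,
                                           ref = ref, alt = alt),
                        genes, ref)
  got <- res_all$classified |>
    dplyr::arrange(pos, alt)
  want <- muts |> dplyr::mutate(consequence = expected) |>
    dplyr::arrange(offset + 3, alt)
  expect_equal(got$consequence, want$consequence)

  # a mismatching reference allele is an error naming the offender
  expect_error(ns_s_ratio(tibble::tibble(contig = "c1", pos = 1, ref = "G",
                                         alt = "C"), genes, ref),
               "c1:1:C")
})

test_that("minus-strand genes are classified on the coding strand", {
  # reverse complement of ATG TTA TAA laid on the minus strand
  ref <- c(c1 = "TTATAACAT")
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", strand = "-",
                          start = 0, end = 9)
  # genomic T>C at pos 9 is CDS A>G at codon 1 position 1: ATG -> GTG, NS
  res <- ns_s_ratio(tibble::tibble(contig = "c1", pos = 9, ref = "T",
                                   alt = "C"), genes, ref)
  expect_equal(res$classified$consequence, "NS")
  expect_equal(res$classified$codon, "ATG")
  # genomic T>C at pos 4 is CDS A>G third position of TTA -> TTG, S
  res2 <- ns_s_ratio(tibble::tibble(contig = "c1", pos = 4, ref = "T",
                                    alt = "C"), genes, ref)
  expect_equal(res2$classified$consequence, "S")
})
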