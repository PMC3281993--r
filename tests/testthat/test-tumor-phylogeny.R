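test_that("genotype collapsing merges identical vectors and applies the wildcard rule", {
  rows <- list(c(1, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 0), c(1, 1, 0))
  col <- collapse_genotypes(gm_from_rows(rows))
  expect_equal(nrow(col), 2L)
  expect_equal(sort(col$n_tumors), c(2L, 3L))

  # missing call with a unique completion folds in
  rows2 <- list(c(1, 0, 0), c(1, 1, 0), c(1, NA, 0))
  col2 <- collapse_genotypes(gm_from_rows(rows2))
  expect_equal(nrow(col2), 3L)   # ambiguous: compatible with both -> kept
  rows3 <- list(c(1, 1, 0), c(0, 0, 1), c(1, NA, 0))
  col3 <- collapse_genotypes(gm_from_rows(rows3))
  expect_equal(nrow(col3), 2L)   # unique completion -> folded
  folded <- col3[vapply(col3$tumor_ids, function(x) "T03" %in% x,
                        logical(1)), ]
  expect_true("T01" %in% folded$tumor_ids[[1]])

  expect_error(collapse_genotypes(gm_from_rows(list(c(NA, NA, NA)))),
               "non-missing")
})

test_that("nested and disjoint marker sets give the expected topologies", {
  # chain: marker sets m1 > m2 > m3
  chain <- gm_from_rows(list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(0, 0, 0)))
  tr <- build_clone_tree(chain)
  expect_equal(glance(tr)$n_edges, 3L)
  expect_true(all(tidy(tr)$weight == 1))
  expect_equal(glance(tr)$n_conflicts, 0L)
  # depth of the chain tip is 3 markers
  deepest <- tr$nodes[lengths(tr$nodes$markers) == 3, ]
  expect_equal(nrow(deepest), 1L)

  # two disjoint marker groups branch at the root
  split2 <- gm_from_rows(list(c(1, 1, 0), c(0, 0, 1), c(0, 0, 0)))
  tr2 <- build_clone_tree(split2)
  root_children <- tidy(tr2) |> dplyr::filter(parent == "root")
  expect_equal(nrow(root_children), 2L)
  expect_setequal(root_children$weight, c(2L, 1L))
})

test_that("conflicting markers are reported and repaired by duplication", {
  confl <- gm_from_rows(list(c(1, 1, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)))
  tr <- build_clone_tree(confl)
  expect_equal(nrow(tr$conflicts), 1L)
  expect_gte(tr$homoplasy, 1L)
  # every observed genotype still lands on a node
  expect_equal(sum(tr$nodes$n_tumors), 4L)
})

test_that("clone tree equals an exhaustive laminar-family oracle on small panels", {
  # oracle: a conflict-free rooted perfect phylogeny is the Hasse diagram of
  # the marker carrier sets; build it by exhaustive pairwise subset tests
  oracle_edges <- function(mat) {
    carriers <- lapply(seq_len(ncol(mat)), function(j) which(mat[, j] == 1))
    names(carriers) <- colnames(mat)
    genotype_sets <- unique(lapply(seq_len(nrow(mat)), function(i) {
      sort(colnames(mat)[mat[i, ] == 1])
    }))
    # parent set of a genotype: largest strict subset among genotype sets
    parent_of <- function(s) {
      subs <- Filter(function(t) length(t) < length(s) && all(t %in% s),
                     genotype_sets)
      if (length(subs) == 0) return(character(0))
      sizes <- vapply(subs, length, integer(1))
      subs[[which.max(sizes)]]
    }
    lapply(genotype_sets, function(s) {
      list(set = s, parent = parent_of(s))
    })
  }
  set.seed(71)
  for (rep in 1:25) {
    # random conflict-free matrix: grow nested/disjoint marker sets on a tree
    k <- sample(3:8, 1)
    n_geno <- sample(3:6, 1)
    pat <- matrix(0L, n_geno, k,
                  dimnames = list(NULL, paste0("m", 1:k)))
    assigned <- sample(rep_len(seq_len(n_geno - 1), k))
    parent <- c(0, vapply(2:n_geno, function(i) sample(i - 1, 1), integer(1)))
    for (i in 2:n_geno) {
      pat[i, ] <- pat[parent[i], ]
      pat[i, which(assigned == (i - 1))] <- 1L
    }
    gm <- tibble::as_tibble(pat) |>
      dplyr::mutate(tumor_id = sprintf("T%02d", seq_len(n_geno)))
    tr <- build_clone_tree(gm)
    expect_equal(glance(tr)$n_conflicts, 0L)
    expect_equal(glance(tr)$total_weight, sum(colSums(pat) > 0))
    # every oracle parent/child pair appears as an ancestor edge in the tree
    node_sets <- lapply(tr$nodes$markers, sort)
    for (e in oracle_edges(pat)) {
      expect_true(any(vapply(node_sets, identical, logical(1),
                             y = sort(e$set))))
    }
  }
})

test_that("tree topology is invariant to tumour relabeling", {
  p <- small_params(seed = 83)
  gcx <- simulate_genotype_cohort(p)
  m1 <- gcx$matrix
  m2 <- m1[sample(nrow(m1)), ]
  m2$tumor_id <- sprintf("X%03d", seq_len(nrow(m2)))
  t1 <- build_clone_tree(m1)
  t2 <- build_clone_tree(m2)
  expect_setequal(
    vapply(t1$nodes$markers, paste, character(1), collapse = "|"),
    vapply(t2$nodes$markers, paste, character(1), collapse = "|"))
  expect_equal(glance(t1)$total_weight, glance(t2)$total_weight)
})

test_that("simulated clone topologies are reconstructed exactly", {
  p <- small_params(seed = 89)
  gcx <- simulate_genotype_cohort(p)
  col <- collapse_genotypes(gcx$matrix)
  expect_equal(nrow(col), length(gcx$truth$patterns))
  tr <- build_clone_tree(col)
  expect_equal(glance(tr)$n_conflicts, 0L)
  # node marker-sets must coincide with the truth patterns
  truth_sets <- lapply(gcx$truth$patterns, function(p) sort(names(p)[p == 1]))
  node_sets <- lapply(tr$nodes$markers, sort)
  for (s in truth_sets) {
    expect_true(any(vapply(node_sets, identical, logical(1), y = s)))
  }
  expect_equal(glance(tr)$total_weight,
               length(unique(unlist(lapply(gcx$truth$tree$markers, c)))))
})

test_that("frequency trajectories flag monotone rises and nothing else", {
  # three years, frequencies 0.2 -> 0.5 -> 0.8 for genotype B
  rows <- c(rep(list(c(0, 0)), 8), rep(list(c(1, 0)), 2),   # 2007: 0.2
            rep(list(c(0, 0)), 5), rep(list(c(1, 0)), 5),   # 2008: 0.5
            rep(list(c(0, 0)), 2), rep(list(c(1, 0)), 8))   # 2009: 0.8
  gm <- gm_from_rows(rows, location = "pen",
                     year = rep(c(2007, 2008, 2009), each = 10))
  tr <- frequency_trajectories(gm)
  rising <- tr$sweeps |> dplyr::filter(first_freq == 0.2)
  expect_true(rising$sweep)
  # frequencies per region-year sum to one
  sums <- tr$frequencies |> dplyr::group_by(location, year) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))

  # oscillation is not a sweep
  rows_o <- c(rep(list(c(0, 0)), 6), rep(list(c(1, 0)), 4),
              rep(list(c(0, 0)), 4), rep(list(c(1, 0)), 6),
              rep(list(c(0, 0)), 7), rep(list(c(1, 0)), 3))
  gm_o <- gm_from_rows(rows_o, location = "pen",
                       year = rep(2007:2009, each = 10))
  tr_o <- frequency_trajectories(gm_o)
  expect_false(any(tr_o$sweeps$sweep))

  # a genotype fixed from the start is suppressed
  gm_fix <- gm_from_rows(rep(list(c(1, 0)), 9), location = "pen",
                         year = rep(2007:2009, each = 3))
  expect_false(any(frequency_trajectories(gm_fix)$sweeps$sweep))

  # single sampled year: sweep undefined
  gm_one <- gm_from_rows(list(c(1, 0), c(0, 0)), location = "pen",
                         year = c(2008, 2008))
  expect_true(all(is.na(frequency_trajectories(gm_one)$sweeps$sweep)))
})

test_that("multi-tumour hosts are classified by the planted rules", {
  rows <- list(
    c(1, 0, 0, 0), c(1, 0, 0, 0),        # D1: metastasis-consistent
    c(1, 0, 0, 0), c(0, 1, 0, 0),        # D2: both genotypes seen elsewhere
    c(1, 0, 0, 0), c(1, 0, 1, 0),        # D3: private genotype, Hamming 1
    c(1, 0, 0, 0), c(0, 1, 1, 1),        # D4: private genotype, Hamming 3
    c(1, 0, 0, 0), c(0, 1, 0, 0)         # D5, D6: singles covering genotypes
  )
  gm <- gm_from_rows(rows,
                     devil = c("D1", "D1", "D2", "D2", "D3", "D3",
                               "D4", "D4", "D5", "D6"))
  cls <- classify_host_tumors(gm)
  got <- setNames(cls$classification, cls$devil_id)
  expect_equal(got[["D1"]], "metastasis_consistent")
  expect_equal(got[["D2"]], "reinfection")
  expect_equal(got[["D3"]], "possible_de_novo")
  expect_equal(got[["D4"]], "unresolved")
  expect_false("D5" %in% names(got))
})

test_that("planted host classes in the synthetic cohort are reproduced exactly", {
  p <- small_params(seed = 97)
  gcx <- simulate_genotype_cohort(p)
  cls <- classify_host_tumors(gcx$matrix)
  cmp <- dplyr::inner_join(cls, gcx$truth$host_classes, by = "devil_id")
  expect_equal(nrow(cmp), nrow(gcx$truth$host_classes))
  expect_equal(cmp$classification, cmp$class)
})
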