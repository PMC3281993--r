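#' Simulate the genotyped multi-tumour cohort
#'
#' Builds a random conflict-free clone tree over the nuclear +
#' mitochondrial somatic marker panel, then samples a cohort of tumours
#' from its genotypes with the epidemiological structure the downstream
#' analyses look for:
#'
#' * one isolated region (`"forestier"`) seeded by a single lineage in
#'   which a genotype rises monotonically in frequency over four sampled
#'   years (a planted selective sweep);
#' * hosts carrying multiple tumours, planted as metastasis-consistent
#'   (identical genotypes), reinfection (two genotypes both circulating in
#'   other hosts) and possible-de-novo cases (a second genotype private to
#'   the host, one reserved marker away from a circulating genotype);
#' * the remaining hosts with one tumour each, spread over mainland
#'   regions and years.
#'
#' A few nuclear markers are reserved for the de novo events and do not
#' label tree edges; the truth record reports the full tree (including the
#' de novo genotypes), every tumour's genotype, host classes, and the
#' planted sweep.
#'
#' @param params A [cohort_params()] object. Requires `n_hosts` large
#'   enough for the planted design (>= 44 with the default multi-host
#'   counts) and `n_tumors >=` the planted baseline.
#' @param n_metastasis_hosts,n_reinfection_hosts,n_denovo_hosts Planted
#'   multi-tumour host counts.
#' @return A list of class `genotype_cohort`: `matrix` (genotype-matrix
#'   tibble: metadata plus 0/1 marker columns) and `truth` (list with
#'   `tree` -- tibble `parent`, `child`, list-column `markers` --
#'   `patterns` (named list of 0/1 vectors per genotype), `tumor_genotypes`,
#'   `host_classes`, `sweep`, `markers`).
#' @export
simulate_genotype_cohort <- function(params,
                                     n_metastasis_hosts = 14,
                                     n_reinfection_hosts = 3,
                                     n_denovo_hosts = 3) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed + 3L)
  nuclear <- sprintf("N%02d", seq_len(params$n_nuclear_markers))
  mito <- sprintf("M%02d", seq_len(params$n_mito_markers))
  n_reserved <- min(n_denovo_hosts, max(0, params$n_nuclear_markers - 4))
  n_denovo_hosts <- n_reserved
  reserved <- if (n_reserved > 0) tail(nuclear, n_reserved) else character(0)
  tree_markers <- c(setdiff(nuclear, reserved), mito)
  all_markers <- c(nuclear, mito)

  k <- max(2L, min(params$n_clone_genotypes, length(tree_markers) + 1L))
  # partition tree markers over the K-1 edges, each edge gaining >= 1
  shuffled <- sample(tree_markers)
  sizes <- tabulate(sample.int(k - 1L, length(shuffled) - (k - 1L),
                               replace = TRUE), k - 1L) + 1L
  edge_markers <- split(shuffled, rep(seq_len(k - 1L), sizes))
  genotype_ids <- sprintf("g%02d", seq_len(k))
  parent <- c(NA_integer_, vapply(2:k, function(i) {
    sample.int(i - 1L, 1)
  }, integer(1)))
  patterns <- vector("list", k)
  patterns[[1]] <- setNames(rep(0L, length(all_markers)), all_markers)
  for (i in 2:k) {
    p <- patterns[[parent[i]]]
    p[edge_markers[[i - 1L]]] <- 1L
    patterns[[i]] <- p
  }
  names(patterns) <- genotype_ids
  tree <- tibble(
    parent = c("root", genotype_ids[parent[-1]]),
    child = genotype_ids,
    markers = c(list(character(0)), unname(edge_markers))
  )
  tree$parent[1] <- NA_character_

  is_leaf <- !(genotype_ids %in% tree$child[match(genotype_ids,
                                                  tree$parent)]) # placeholder
  children_of <- table(factor(genotype_ids[parent[-1]],
                              levels = genotype_ids))
  leaves <- genotype_ids[children_of == 0]
  sweep_g <- tail(leaves, 1)
  sweep_parent <- genotype_ids[parent[match(sweep_g, genotype_ids)]]

  # --- forestier sweep block: 4 years x 5 single-tumour hosts -------------
  sweep_years <- 2007:2010
  sweep_counts <- c(1, 2, 3, 4)      # of 5 tumours/year -> 0.2 .. 0.8
  forestier <- purrr::map2(sweep_years, sweep_counts, function(yr, ns) {
    tibble(genotype = c(rep(sweep_g, ns), rep(sweep_parent, 5 - ns)),
           location = "forestier", year = yr)
  }) |> bind_rows()
  n_forestier_hosts <- nrow(forestier)

  # --- multi-tumour hosts -------------------------------------------------
  # genotypes guaranteed to circulate among single-tumour hosts
  common_pool <- genotype_ids[order(-vapply(patterns, sum, numeric(1)))][1:2]
  common_pool <- unique(c(common_pool, genotype_ids[1]))[1:2]
  mainland_years <- 2004:2010
  mainland_locs <- c("east_coast", "north", "northwest", "northeast")

  host_rows <- list()
  add_host <- function(devil, genotypes, class, n_each = 1) {
    host_rows[[length(host_rows) + 1L]] <<-
      tibble(devil = devil, genotype = rep(genotypes, n_each),
             class = class,
             location = sample(mainland_locs, 1),
             year = sample(mainland_years, 1))
  }
  devil_counter <- 0L
  next_devil <- function() {
    devil_counter <<- devil_counter + 1L
    sprintf("D%03d", devil_counter)
  }
  # forestier hosts first (one tumour each)
  forestier$devil <- vapply(seq_len(nrow(forestier)), function(i) next_devil(),
                            character(1))
  # metastasis hosts double as genotype coverage: cycle through every tree
  # genotype so that each one is observed somewhere in the cohort
  meta_genotypes <- rep_len(sample(genotype_ids), n_metastasis_hosts)
  for (i in seq_len(n_metastasis_hosts)) {
    add_host(next_devil(), meta_genotypes[i], "metastasis_consistent",
             n_each = 2)
  }
  for (i in seq_len(n_reinfection_hosts)) {
    add_host(next_devil(), common_pool, "reinfection")
  }
  denovo_patterns <- list()
  for (i in seq_len(n_denovo_hosts)) {
    base <- common_pool[(i %% 2) + 1L]
    dn_id <- sprintf("dn%02d", i)
    p <- patterns[[base]]
    p[reserved[i]] <- 1L
    denovo_patterns[[dn_id]] <- p
    add_host(next_devil(), c(base, dn_id), "possible_de_novo")
  }
  multi <- bind_rows(host_rows)

  n_planted_hosts <- n_forestier_hosts + n_metastasis_hosts +
    n_reinfection_hosts + n_denovo_hosts
  n_singles <- params$n_hosts - n_planted_hosts
  if (n_singles < 4) {
    abort("`n_hosts` too small for the planted multi-host design")
  }
  single_genotypes <- c(rep(common_pool, 2),
                        sample(genotype_ids, n_singles - 4, replace = TRUE))
  singles <- tibble(
    devil = vapply(seq_len(n_singles), function(i) next_devil(),
                   character(1)),
    genotype = single_genotypes,
    class = "single",
    location = sample(mainland_locs, n_singles, replace = TRUE),
    year = sample(mainland_years, n_singles, replace = TRUE)
  )

  n_baseline <- nrow(forestier) + nrow(multi) + nrow(singles)
  n_extra <- params$n_tumors - n_baseline
  if (n_extra < 0) {
    abort(sprintf("`n_tumors` must be >= %d for this host design",
                  n_baseline))
  }
  extra <- if (n_extra > 0) {
    meta_hosts <- multi |> filter(.data$class == "metastasis_consistent") |>
      distinct(.data$devil, .data$genotype, .data$location, .data$year)
    idx <- rep_len(seq_len(nrow(meta_hosts)), n_extra)
    meta_hosts[idx, ] |> mutate(class = "metastasis_consistent")
  } else NULL

  tumors <- bind_rows(
    forestier |> mutate(class = "single"),
    multi, singles, extra
  ) |>
    mutate(tumor_id = sprintf("T%03d", dplyr::row_number()),
           tissue = ifelse(duplicated(.data$devil), "metastasis", "facial"))

  all_patterns <- c(patterns, denovo_patterns)
  gmat <- do.call(rbind, all_patterns[tumors$genotype])
  matrix_tbl <- bind_cols(
    tumors |> transmute(.data$tumor_id, devil_id = .data$devil,
                        .data$location, .data$year, .data$tissue),
    as_tibble(gmat)
  )

  dn_tree <- if (length(denovo_patterns)) {
    tibble(parent = vapply(seq_along(denovo_patterns), function(i) {
      common_pool[(i %% 2) + 1L]
    }, character(1)),
      child = names(denovo_patterns),
      markers = lapply(seq_along(denovo_patterns),
                       function(i) reserved[i]))
  } else NULL
  host_classes <- tumors |>
    group_by(devil_id = .data$devil) |>
    summarise(n_tumors = dplyr::n(), class = .data$class[1],
              .groups = "drop") |>
    filter(.data$n_tumors >= 2)
  out <- list(
    matrix = matrix_tbl,
    truth = list(
      tree = bind_rows(tree, dn_tree),
      patterns = all_patterns,
      tumor_genotypes = tumors |>
        select("tumor_id", devil_id = "devil", "genotype", "location",
               "year"),
      host_classes = host_classes,
      sweep = list(location = "forestier", genotype = sweep_g,
                   years = sweep_years,
                   frequencies = sweep_counts / 5),
      markers = list(nuclear = nuclear, mito = mito, reserved = reserved)
    ),
    params = params
  )
  class(out) <- "genotype_cohort"
  out
}

#' @export
print.genotype_cohort <- function(x, ...) {
  cat(sprintf("<genotype_cohort> %d tumours x %d markers, %d hosts, %d genotypes\n",
              nrow(x$matrix), length(marker_columns(x$matrix)),
              length(unique(x$matrix$devil_id)),
              length(x$truth$patterns)))
  invisible(x)
}

#' Simulate a host + tumour mitochondrial cohort
#'
#' Generates several host mitochondrial haplotypes on a random parsimony
#' tree, samples hosts from them, and derives every tumour's mitochondrial
#' genome from a single founder host haplotype (identical or with a few
#' extra tumour-private variants), the clonal-descent structure the
#' horizontal-transfer test should recover. Some samples also carry
#' variants inside the control region, which grouping must mask.
#'
#' @param params A [cohort_params()] object (mitochondrial length, control
#'   region, seed).
#' @param n_host_haplotypes Distinct haplotypes among normal hosts.
#' @param n_hosts,n_tumors Sample counts.
#' @return A list of class `mito_cohort`: `variants` (tibble: `sample`,
#'   `pos`, `ref`, `alt`), `samples` (tibble: `sample`, `class`),
#'   `control_region`, and `truth` (list: per-sample haplotype, founder
#'   haplotype id, haplotype variant sets).
#' @export
simulate_mito_cohort <- function(params, n_host_haplotypes = 6,
                                 n_hosts = 30, n_tumors = 20) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed + 4L)
  cr <- params$mito_control_region
  coding_pos <- setdiff(seq_len(params$mito_length),
                        (cr[1] + 1):cr[2])
  mito_seq <- strsplit(random_dna(params$mito_length), "")[[1]]
  pool <- sample(coding_pos)
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  new_variants <- function(n) {
    pos <- sort(take(n))
    ref <- mito_seq[pos]
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                  character(1))
    paste(pos, unname(alt), sep = ":")
  }
  # host haplotype tree: haplotype 1 is the reference-like root
  hap_sets <- list(H1 = character(0))
  for (i in 2:n_host_haplotypes) {
    parent <- sample(names(hap_sets), 1)
    hap_sets[[paste0("H", i)]] <-
      c(hap_sets[[parent]], new_variants(sample(2:4, 1)))
  }
  founder_hap <- sample(names(hap_sets), 1)
  # two tumour-derived haplotypes hang off the founder haplotype
  tumor_sets <- list(
    TH1 = hap_sets[[founder_hap]],
    TH2 = c(hap_sets[[founder_hap]], new_variants(1)),
    TH3 = c(hap_sets[[founder_hap]], new_variants(2))
  )
  host_assign <- sample(names(hap_sets), n_hosts, replace = TRUE)
  host_assign[seq_len(n_host_haplotypes)] <- names(hap_sets) # all observed
  tumor_assign <- sample(names(tumor_sets), n_tumors, replace = TRUE,
                         prob = c(0.6, 0.25, 0.15))
  tumor_assign[1:3] <- names(tumor_sets)

  samples <- tibble(
    sample = c(sprintf("host%02d", seq_len(n_hosts)),
               sprintf("tumor%02d", seq_len(n_tumors))),
    class = rep(c("host", "tumor"), c(n_hosts, n_tumors))
  )
  hap_of <- c(setNames(host_assign, samples$sample[seq_len(n_hosts)]),
              setNames(tumor_assign, samples$sample[n_hosts + seq_len(n_tumors)]))
  sets <- c(hap_sets, tumor_sets)
  variants <- purrr::imap(hap_of, function(hap, smp) {
    keys <- sets[[hap]]
    if (length(keys) == 0) return(NULL)
    parts <- stringr::str_split_fixed(keys, stringr::fixed(":"), 2)
    tibble(sample = smp, pos = as.integer(parts[, 1]),
           ref = mito_seq[as.integer(parts[, 1])], alt = parts[, 2])
  }) |> bind_rows()
  # control-region decoys on a few samples (must be masked away)
  decoy_samples <- sample(samples$sample, 4)
  cr_pos <- sample((cr[1] + 1):cr[2], 4)
  decoys <- tibble(
    sample = decoy_samples, pos = cr_pos, ref = mito_seq[cr_pos],
    alt = vapply(mito_seq[cr_pos],
                 function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
  )
  out <- list(
    variants = bind_rows(variants, decoys) |> arrange(.data$sample, .data$pos),
    samples = samples,
    control_region = cr,
    truth = list(haplotype_of = hap_of, founder_haplotype = founder_hap,
                 host_sets = hap_sets, tumor_sets = tumor_sets)
  )
  class(out) <- "mito_cohort"
  out
}
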