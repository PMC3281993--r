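#' Simulate the four-genome variant cohort
#'
#' Generates the variant content of the study design: a founder genome
#' carrying population germline variation plus founder-private variants,
#' two independent normal genomes drawn from the same population variation,
#' and two tumour lineages that inherit the founder's germline, share a
#' trunk of early somatic mutations, and then diverge with independent
#' Poisson-distributed somatic branch mutations drawn from the configured
#' mutation spectrum. Somatic variants are heterozygous unless a simulated
#' hemizygous copy-number loss drops or homozygoses them. Sites follow the
#' infinite-sites assumption: no position mutates twice anywhere in the
#' cohort.
#'
#' Somatic substitution classes are drawn exactly from `spectrum_weights`
#' by first drawing the class and then placing the variant at an unused
#' site whose reference base matches the class (A/T sites for the A:T
#' classes, G/C sites for the G:C classes).
#'
#' @param params A [cohort_params()] object.
#' @param reference A [simulate_reference()] result (generated from
#'   `params` when omitted).
#' @return An object of class `synthetic_cohort`: list with `variants`
#'   (named list of tibbles `normal_female`, `normal_male`, `tumor_a`,
#'   `tumor_b`, columns `contig`, `pos`, `ref`, `alt`, `genotype`),
#'   `truth` (list: `origins` tibble with per-variant origin labels,
#'   `founder_variants` keys, `trunk`, `branch_a`, `branch_b` key vectors,
#'   `cn_segments`), plus `reference` and `params`.
#' @export
simulate_cohort <- function(params, reference = simulate_reference(params)) {
  stopifnot(inherits(params, "cohort_params"),
            inherits(reference, "cohort_reference"))
  set.seed(params$seed + 1L)
  bases <- unlist(strsplit(reference$sequences, ""), use.names = FALSE)
  site_contig <- rep(reference$contigs$contig, reference$contigs$length)
  site_pos <- unlist(lapply(reference$contigs$length, seq_len),
                     use.names = FALSE)
  is_at <- bases %in% c("A", "T")
  used <- rep(FALSE, length(bases))

  # draw `n` substitutions with classes ~ weights at unused matching sites
  draw <- function(n, weights) {
    if (n == 0) {
      return(tibble(contig = character(), pos = integer(), ref = character(),
                    alt = character(), class = character()))
    }
    cls <- sample(SUBSTITUTION_CLASSES, n, replace = TRUE, prob = weights)
    at_need <- startsWith(cls, "A")
    pick_sites <- function(pool_mask, k) {
      pool <- which(pool_mask & !used)
      if (length(pool) < k) abort("genome too small for requested variant load")
      sample(pool, k)
    }
    idx <- integer(n)
    idx[at_need] <- pick_sites(is_at, sum(at_need))
    idx[!at_need] <- pick_sites(!is_at, sum(!at_need))
    used[idx] <<- TRUE
    ref <- bases[idx]
    target <- substr(cls, 5, 5)
    alt <- ifelse(ref %in% c("A", "G"), target, complement_base(target))
    tibble(contig = site_contig[idx], pos = site_pos[idx],
           ref = ref, alt = alt, class = cls)
  }

  n_pop <- rpois(1, params$germline_het_rate * params$genome_length)
  pop <- draw(n_pop, params$germline_spectrum_weights)
  if (nrow(pop) > 0) {
    carriers <- matrix(runif(3 * nrow(pop)) < 0.5, ncol = 3,
                       dimnames = list(NULL, c("founder", "normal_female",
                                               "normal_male")))
    while (any(none <- rowSums(carriers) == 0)) {
      carriers[none, ] <- runif(3 * sum(none)) < 0.5
    }
    gt <- matrix(ifelse(runif(3 * nrow(pop)) < 0.3, "hom", "het"), ncol = 3)
    pop <- pop |>
      mutate(founder = carriers[, 1], nf = carriers[, 2], nm = carriers[, 3],
             gt_founder = gt[, 1], gt_nf = gt[, 2], gt_nm = gt[, 3])
  } else {
    pop <- pop |> mutate(founder = logical(), nf = logical(), nm = logical(),
                         gt_founder = character(), gt_nf = character(),
                         gt_nm = character())
  }
  n_priv <- rpois(1, params$founder_private_rate * params$genome_length)
  founder_private <- draw(n_priv, params$germline_spectrum_weights) |>
    mutate(genotype = as.character(ifelse(runif(dplyr::n()) < 0.9,
                                          "het", "hom")))
  trunk <- draw(rpois(1, params$somatic_rate_trunk),
                params$spectrum_weights) |>
    mutate(genotype = "het")
  branch_a <- draw(rpois(1, params$somatic_rate_per_branch),
                   params$spectrum_weights) |>
    mutate(genotype = "het")
  branch_b <- draw(rpois(1, params$somatic_rate_per_branch),
                   params$spectrum_weights) |>
    mutate(genotype = "het")

  # one hemizygous-loss segment per tumour lineage
  cn_segment <- function(tumor) {
    seg_len <- round(params$cnv_loss_fraction * params$genome_length)
    if (seg_len == 0) return(NULL)
    ctg <- reference$contigs[sample.int(nrow(reference$contigs), 1), ]
    seg_len <- min(seg_len, ctg$length)
    start <- sample.int(ctg$length - seg_len + 1L, 1) - 1L
    tibble(tumor = tumor, contig = ctg$contig, start = start,
           end = start + seg_len)
  }
  cn_segments <- bind_rows(cn_segment("tumor_a"), cn_segment("tumor_b"))

  apply_loss <- function(vars, which_tumor) {
    if (is.null(cn_segments) || nrow(cn_segments) == 0 || nrow(vars) == 0) {
      return(vars)
    }
    seg <- cn_segments[cn_segments$tumor == which_tumor, , drop = FALSE]
    if (nrow(seg) == 0) return(vars)
    hit <- vars$contig == seg$contig & vars$pos - 1 >= seg$start &
      vars$pos - 1 < seg$end & vars$genotype == "het"
    drop <- hit & runif(nrow(vars)) < 0.5
    vars$genotype[hit & !drop] <- "hom"
    vars[!drop, , drop = FALSE]
  }

  founder_germline <- bind_rows(
    pop |> filter(.data$founder) |>
      transmute(.data$contig, .data$pos, .data$ref, .data$alt, .data$class,
                genotype = .data$gt_founder),
    founder_private |> select("contig", "pos", "ref", "alt", "class",
                              "genotype")
  )
  tumor_core <- bind_rows(
    founder_germline,
    trunk |> select("contig", "pos", "ref", "alt", "class", "genotype")
  )
  tumor_a <- apply_loss(bind_rows(tumor_core, branch_a |>
                                    select("contig", "pos", "ref", "alt",
                                           "class", "genotype")), "tumor_a")
  tumor_b <- apply_loss(bind_rows(tumor_core, branch_b |>
                                    select("contig", "pos", "ref", "alt",
                                           "class", "genotype")), "tumor_b")
  strip <- function(x) x |> select("contig", "pos", "ref", "alt", "genotype")

  variants <- list(
    normal_female = pop |> filter(.data$nf) |>
      transmute(.data$contig, .data$pos, .data$ref, .data$alt,
                genotype = .data$gt_nf),
    normal_male = pop |> filter(.data$nm) |>
      transmute(.data$contig, .data$pos, .data$ref, .data$alt,
                genotype = .data$gt_nm),
    tumor_a = strip(tumor_a),
    tumor_b = strip(tumor_b)
  )
  origins <- bind_rows(
    pop |> transmute(.data$contig, .data$pos, .data$ref, .data$alt,
                     .data$class, origin = "population_germline"),
    founder_private |> transmute(.data$contig, .data$pos, .data$ref,
                                 .data$alt, .data$class,
                                 origin = "founder_private"),
    trunk |> transmute(.data$contig, .data$pos, .data$ref, .data$alt,
                       .data$class, origin = "trunk_somatic"),
    branch_a |> transmute(.data$contig, .data$pos, .data$ref, .data$alt,
                          .data$class, origin = "branch_a_somatic"),
    branch_b |> transmute(.data$contig, .data$pos, .data$ref, .data$alt,
                          .data$class, origin = "branch_b_somatic")
  )
  out <- list(
    variants = variants,
    truth = list(
      origins = origins,
      founder_variants = variant_key(founder_germline$contig,
                                     founder_germline$pos,
                                     founder_germline$alt),
      trunk = variant_key(trunk$contig, trunk$pos, trunk$alt),
      branch_a = variant_key(branch_a$contig, branch_a$pos, branch_a$alt),
      branch_b = variant_key(branch_b$contig, branch_b$pos, branch_b$alt),
      cn_segments = cn_segments
    ),
    reference = reference,
    params = params
  )
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- vapply(x$variants, nrow, integer(1))
  cat("<synthetic_cohort> variant counts:\n")
  for (s in names(n)) cat(sprintf("  %-14s %d\n", s, n[[s]]))
  invisible(x)
}
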