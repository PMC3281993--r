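#' Mitochondrial haplotype grouping and horizontal-transfer testing
#'
#' Mitochondria pass clonally down the cancer lineage unless the tumour
#' captures host mitochondria by horizontal transfer. Grouping the
#' mitochondrial variant sets of hosts and tumours into haplotypes (after
#' masking the repetitive, unsequenceable control region) and placing them
#' on a parsimony tree reveals how many independent host attachment points
#' the tumour haplotypes require: one attachment point is consistent with
#' strict clonal descent from the founder animal, more than one implies
#' transfer.
#'
#' @name mito_haplotypes
NULL

#' Group mitochondrial variant sets into haplotypes
#'
#' @param variants Data frame of mitochondrial variant calls with columns
#'   `sample`, `pos` (1-based), `alt` (and optionally `ref`). Samples with
#'   no rows carry the reference haplotype; list such samples in `samples`.
#' @param samples Data frame with columns `sample` and `class`
#'   (`"host"`/`"tumor"`) enumerating every sequenced sample.
#' @param control_region Length-2 numeric: the control-region interval,
#'   0-based half-open; variants inside it are masked before grouping.
#' @return A tibble of class `mito_haplotypes`: `haplotype_id`,
#'   `n_variants`, `n_host`, `n_tumor`, list-columns `variants` (masked
#'   variant keys) and `carriers`. Samples whose only variants lay inside
#'   the control region collapse to the reference haplotype.
#' @export
group_haplotypes <- function(variants, samples, control_region) {
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  stopifnot(all(c("sample", "pos", "alt") %in% names(variants)),
            all(c("sample", "class") %in% names(samples)),
            length(control_region) == 2)
  if (!all(samples$class %in% c("host", "tumor"))) {
    abort("sample class must be \"host\" or \"tumor\"")
  }
  if (!all(variants$sample %in% samples$sample)) {
    abort("variants refer to samples missing from the roster")
  }
  masked <- variants |>
    filter(!(.data$pos - 1 >= control_region[1] &
               .data$pos - 1 < control_region[2]))
  key_by_sample <- lapply(split(masked, masked$sample), function(v) {
    sort(paste(v$pos, v$alt, sep = ":"))
  })
  sets <- vapply(samples$sample, function(s) {
    paste(key_by_sample[[s]] %||% character(0), collapse = ";")
  }, character(1))
  groups <- split(seq_len(nrow(samples)), sets)
  groups <- groups[order(nchar(names(groups)), names(groups))]
  out <- tibble(
    haplotype_id = paste0("H", seq_along(groups)),
    n_variants = vapply(names(groups), function(s) {
      if (nzchar(s)) length(strsplit(s, ";", fixed = TRUE)[[1]]) else 0L
    }, integer(1)),
    variants = lapply(names(groups), function(s) {
      if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]] else character(0)
    }),
    carriers = lapply(groups, function(i) samples$sample[i]),
    n_host = vapply(groups, function(i) sum(samples$class[i] == "host"),
                    integer(1)),
    n_tumor = vapply(groups, function(i) sum(samples$class[i] == "tumor"),
                     integer(1))
  )
  structure(out, class = c("mito_haplotypes", class(out)))
}

# haplotype table -> binary genotype matrix consumable by build_clone_tree
haplotype_matrix <- function(haplotypes) {
  all_vars <- sort(unique(unlist(haplotypes$variants, use.names = FALSE)))
  if (length(all_vars) == 0) {
    abort("no segregating mitochondrial variants")
  }
  m <- vapply(all_vars, function(v) {
    as.integer(vapply(haplotypes$variants, function(s) v %in% s, logical(1)))
  }, integer(nrow(haplotypes)))
  m <- matrix(m, nrow = nrow(haplotypes),
              dimnames = list(NULL, paste0("m", seq_along(all_vars))))
  out <- as_tibble(m)
  out$tumor_id <- haplotypes$haplotype_id
  out
}

#' Parsimony tree over mitochondrial haplotypes
#'
#' Builds the haplotype genealogy with the same perfect-phylogeny core used
#' for the tumour clone tree, rooted at the reference (variant-free)
#' haplotype.
#'
#' @param haplotypes A [group_haplotypes()] table.
#' @return A `clone_tree` whose member "tumours" are haplotype ids.
#' @export
build_haplotype_tree <- function(haplotypes) {
  stopifnot(inherits(haplotypes, "mito_haplotypes"))
  build_clone_tree(haplotype_matrix(haplotypes))
}

#' Count host attachment points of tumour mitochondrial haplotypes
#'
#' Walks each tumour-carrying haplotype up the tree to its nearest
#' ancestor-or-self carrying host samples; the number of distinct such host
#' haplotypes is the minimal number of host-to-tumour mitochondrial
#' acquisition events. One attachment point means the tumour mitochondria
#' are clonal (identical to or derived from a single host haplotype).
#'
#' @param haplotypes A [group_haplotypes()] table.
#' @param tree Optional [build_haplotype_tree()] result (built when
#'   omitted).
#' @return A list with `n_attachments`, `verdict`
#'   (`"clonal (no transfer detected)"` or `"transfer inferred"`), and
#'   `attachments` (tibble: tumour haplotype, its host attachment point).
#' @export
horizontal_transfer_test <- function(haplotypes,
                                     tree = build_haplotype_tree(haplotypes)) {
  stopifnot(inherits(haplotypes, "mito_haplotypes"))
  if (sum(haplotypes$n_tumor) == 0) {
    abort("no tumour haplotypes to test")
  }
  nodes <- tree$nodes
  parent <- setNames(nodes$parent, nodes$node)
  hap_class <- haplotypes |>
    mutate(is_host = .data$n_host > 0, is_tumor = .data$n_tumor > 0)
  node_of <- vapply(hap_class$haplotype_id, function(h) {
    hit <- which(vapply(nodes$tumor_ids, function(tt) h %in% (tt %||%
                                                                character(0)),
                        logical(1)))
    nodes$node[hit[1]]
  }, character(1))
  host_nodes <- node_of[hap_class$haplotype_id[hap_class$is_host]]
  attach_point <- function(node) {
    cur <- node
    while (!is.na(cur)) {
      if (cur %in% host_nodes) return(cur)
      cur <- parent[[cur]]
    }
    NA_character_
  }
  tumour_haps <- hap_class$haplotype_id[hap_class$is_tumor]
  attachments <- tibble(
    tumor_haplotype = tumour_haps,
    attachment_node = vapply(node_of[tumour_haps], attach_point,
                             character(1))
  ) |>
    mutate(attachment_haplotype = vapply(.data$attachment_node, function(nd) {
      if (is.na(nd)) return(NA_character_)
      hosts <- intersect(unlist(nodes$tumor_ids[nodes$node == nd]),
                         hap_class$haplotype_id[hap_class$is_host])
      hosts[1] %||% NA_character_
    }, character(1)))
  pts <- unique(attachments$attachment_node)
  n <- length(pts)
  list(
    n_attachments = n,
    verdict = if (n == 1 && !anyNA(pts)) "clonal (no transfer detected)"
              else "transfer inferred",
    attachments = attachments
  )
}
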