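#' Nonsynonymous/synonymous classification of coding substitutions
#'
#' Somatic passenger mutations accumulate roughly at random across codon
#' positions, giving an NS/S ratio near the value implied by the structure
#' of the genetic code (about 2-3 for typical coding sequence); germline
#' polymorphism is shaped by purifying selection and sits near or below 1.
#' Each substitution falling inside an annotated CDS is placed in its
#' strand-corrected codon, the codon is mutated, and both codons are
#' translated with the standard genetic code. A variant hitting several
#' overlapping gene models takes the worst consequence (NS beats S).
#'
#' @param variants Data frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` (single bases).
#' @param genes Gene models: one row per CDS exon with columns `gene_id`,
#'   `contig`, `strand` (`"+"`/`"-"`), `start`, `end` (0-based half-open),
#'   rows ordered 5' to 3' within each gene; each gene's total CDS length
#'   must be divisible by 3.
#' @param reference Named character vector of contig sequences.
#' @return A list of class `ns_s_result`: `ratio` (NS/S, `NA` when S = 0),
#'   `ns`, `s`, `n_noncoding`, and `classified` (a tibble with one row per
#'   coding variant: key columns plus `gene_id`, `codon`, `codon_mut`,
#'   `aa_ref`, `aa_alt`, `consequence`).
#' @export
ns_s_ratio <- function(variants, genes, reference) {
  variants <- as_tibble(variants)
  genes <- as_tibble(genes)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(variants)),
            all(c("gene_id", "contig", "strand", "start", "end") %in%
                  names(genes)))
  maps <- build_cds_maps(genes, reference)

  rows <- list()
  mismatches <- character(0)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    key <- variant_key(v$contig, v$pos, v$alt)
    for (m in maps) {
      if (m$contig != v$contig) next
      j <- match(v$pos, m$genomic_pos)
      if (is.na(j)) next
      genomic_ref <- substr(reference[[m$contig]], v$pos, v$pos)
      if (genomic_ref != v$ref) {
        mismatches <- c(mismatches, key)
        next
      }
      cds_ref <- if (m$strand == "+") v$ref else complement_base(v$ref)
      cds_alt <- if (m$strand == "+") v$alt else complement_base(v$alt)
      codon_idx <- (j - 1L) %/% 3L + 1L
      offset <- (j - 1L) %% 3L + 1L
      codon <- substr(m$cds, 3L * (codon_idx - 1L) + 1L, 3L * codon_idx)
      stopifnot(substr(codon, offset, offset) == cds_ref)
      codon_mut <- codon
      substr(codon_mut, offset, offset) <- cds_alt
      aa_ref <- Biostrings::GENETIC_CODE[[codon]]
      aa_alt <- Biostrings::GENETIC_CODE[[codon_mut]]
      rows[[length(rows) + 1L]] <- tibble(
        contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
        gene_id = m$gene_id, codon = codon, codon_mut = codon_mut,
        aa_ref = aa_ref, aa_alt = aa_alt,
        consequence = if (aa_ref == aa_alt) "S" else "NS"
      )
    }
  }
  if (length(mismatches)) {
    abort(paste0("variant ref allele disagrees with reference at: ",
                 paste(unique(mismatches), collapse = ", ")))
  }
  classified <- bind_rows(rows)
  if (nrow(classified) > 0) {
    # worst consequence across overlapping gene models
    classified <- classified |>
      group_by(.data$contig, .data$pos, .data$ref, .data$alt) |>
      arrange(desc(.data$consequence == "NS"), .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  } else {
    classified <- tibble(contig = character(), pos = integer(),
                         ref = character(), alt = character(),
                         gene_id = character(), codon = character(),
                         codon_mut = character(), aa_ref = character(),
                         aa_alt = character(), consequence = character())
  }
  ns <- sum(classified$consequence == "NS")
  s <- sum(classified$consequence == "S")
  out <- list(
    ratio = if (s > 0) ns / s else NA_real_,
    ns = ns, s = s,
    n_noncoding = nrow(variants) - nrow(classified),
    classified = classified
  )
  class(out) <- "ns_s_result"
  out
}

#' @export
print.ns_s_result <- function(x, ...) {
  cat(sprintf("<ns_s_result> NS = %d, S = %d, NS/S = %s (%d non-coding)\n",
              x$ns, x$s,
              if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio),
              x$n_noncoding))
  invisible(x)
}

#' @rdname ns_s_ratio
#' @param x An `ns_s_result`.
#' @param ... Unused.
#' @export
tidy.ns_s_result <- function(x, ...) x$classified

#' @rdname ns_s_ratio
#' @export
glance.ns_s_result <- function(x, ...) {
  tibble(ns = x$ns, s = x$s, ratio = x$ratio, n_noncoding = x$n_noncoding)
}

# Per-gene CDS sequence and genomic-position map (positions 1-based, in CDS
# order; minus-strand genes run genomically backwards with complemented
# bases).
build_cds_maps <- function(genes, reference) {
  lapply(split(genes, genes$gene_id), function(g) {
    contig <- unique(g$contig)
    strand <- unique(g$strand)
    stopifnot(length(contig) == 1L, length(strand) == 1L,
              strand %in% c("+", "-"))
    if (!contig %in% names(reference)) {
      abort(paste0("no reference sequence for contig ", contig))
    }
    pos_list <- lapply(seq_len(nrow(g)), function(i) {
      p <- (g$start[i] + 1L):g$end[i]
      if (strand == "-") rev(p) else p
    })
    genomic_pos <- unlist(pos_list, use.names = FALSE)
    if (length(genomic_pos) %% 3L != 0L) {
      abort(paste0("CDS length of ", g$gene_id[1], " is not divisible by 3"))
    }
    bases <- vapply(genomic_pos, function(p) {
      substr(reference[[contig]], p, p)
    }, character(1))
    if (strand == "-") bases <- complement_base(bases)
    list(gene_id = g$gene_id[1], contig = contig, strand = strand,
         genomic_pos = genomic_pos, cds = paste(bases, collapse = ""))
  })
}

#' Enumerate every possible coding substitution of a gene set
#'
#' For each CDS position of each gene, lists the three possible single-base
#' changes with their NS/S consequence. Useful for computing the
#' code-determined NS/S expectation of uniform random coding mutation, and
#' for drawing random coding variants in simulations.
#'
#' @inheritParams ns_s_ratio
#' @return A tibble with columns `gene_id`, `contig`, `pos`, `ref`, `alt`,
#'   `consequence` (reference-strand alleles).
#' @export
enumerate_coding_changes <- function(genes, reference) {
  maps <- build_cds_maps(as_tibble(genes), reference)
  bind_rows(lapply(maps, function(m) {
    n <- nchar(m$cds)
    cds_ref <- strsplit(m$cds, "")[[1]]
    rows <- lapply(seq_len(n), function(j) {
      codon_idx <- (j - 1L) %/% 3L + 1L
      offset <- (j - 1L) %% 3L + 1L
      codon <- substr(m$cds, 3L * (codon_idx - 1L) + 1L, 3L * codon_idx)
      alts <- setdiff(DNA_BASES, cds_ref[j])
      cons <- vapply(alts, function(a) {
        mut <- codon
        substr(mut, offset, offset) <- a
        if (Biostrings::GENETIC_CODE[[mut]] ==
              Biostrings::GENETIC_CODE[[codon]]) "S" else "NS"
      }, character(1))
      genomic_ref <- if (m$strand == "+") cds_ref[j] else
        complement_base(cds_ref[j])
      genomic_alt <- if (m$strand == "+") alts else complement_base(alts)
      tibble(gene_id = m$gene_id, contig = m$contig,
             pos = m$genomic_pos[j], ref = genomic_ref,
             alt = genomic_alt, consequence = unname(cons))
    })
    bind_rows(rows)
  }))
}
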