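#' Simulate protein-coding gene models on a reference
#'
#' Lays non-overlapping multi-exon CDS models along the reference contigs,
#' on either strand, with total CDS lengths divisible by three. The models
#' carry no biological signal (the underlying sequence is random); they
#' exist so that coding-consequence statistics can be exercised against an
#' exhaustively enumerable ground truth.
#'
#' @param reference A [simulate_reference()] result, or any named character
#'   vector of contig sequences.
#' @param n_genes Number of gene models.
#' @param codon_range Range of CDS lengths in codons, `c(min, max)`.
#' @param max_exons Maximum CDS exons per gene.
#' @return A tibble of CDS exons: `gene_id`, `contig`, `strand`, `start`,
#'   `end` (0-based half-open), rows ordered 5' to 3' within gene.
#' @export
simulate_gene_models <- function(reference, n_genes = 5,
                                 codon_range = c(40, 120), max_exons = 3) {
  seqs <- if (inherits(reference, "cohort_reference")) {
    reference$sequences
  } else reference
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  cursors <- setNames(rep(1L, length(seqs)), names(seqs))
  rows <- list()
  contig_cycle <- rep_len(names(seqs), n_genes)
  for (g in seq_len(n_genes)) {
    ctg <- contig_cycle[g]
    n_codons <- sample(seq(codon_range[1], codon_range[2]), 1)
    cds_len <- 3L * n_codons
    n_ex <- sample.int(max_exons, 1)
    # split the CDS into n_ex chunks of >= 3 bp
    cuts <- sort(sample(seq(3L, cds_len - 3L, by = 3L),
                        min(n_ex - 1L, cds_len %/% 3L - 1L)))
    ex_lens <- diff(c(0L, cuts, cds_len))
    pos <- cursors[[ctg]] + sample(20:80, 1)
    ex <- list()
    for (le in ex_lens) {
      ex[[length(ex) + 1L]] <- c(start = pos - 1L, end = pos - 1L + le)
      pos <- pos + le + sample(20:100, 1)
    }
    if (pos > nchar(seqs[[ctg]])) {
      abort("contigs too short for the requested gene models")
    }
    cursors[[ctg]] <- pos
    strand <- sample(c("+", "-"), 1)
    exons <- bind_rows(lapply(ex, function(e) {
      tibble(start = unname(e["start"]), end = unname(e["end"]))
    }))
    if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), ]
    rows[[g]] <- exons |>
      mutate(gene_id = sprintf("gene%02d", g), contig = ctg,
             strand = strand) |>
      select("gene_id", "contig", "strand", "start", "end")
  }
  bind_rows(rows)
}
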