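#' Simulate a reference genome split into contigs
#'
#' Generates uniform-random contig sequences totalling exactly
#' `genome_length` bp, assigns each contig to a chromosome, and makes a
#' fraction of contigs chimeric: a chimeric contig is "assembled" from two
#' different chromosomes with a junction at a recorded interior coordinate,
#' the ground truth against which misassembly detection is scored. A
#' circular mitochondrial sequence is generated alongside.
#'
#' @param params A [cohort_params()] object.
#' @return An object of class `cohort_reference`: list with `sequences`
#'   (named character vector of contig sequences), `contigs` (tibble:
#'   `contig`, `length`, `chromosome`, `chimeric`, `junction` -- bp from the
#'   contig start, 0-based, `NA` for clean contigs -- `chr_left`,
#'   `chr_right`), `chromosomes` (tibble: `chromosome`, `size`), and `mito`
#'   (the mitochondrial sequence).
#' @export
simulate_reference <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_contigs
  base_len <- params$genome_length %/% n
  lengths <- rep(base_len, n)
  lengths[1] <- lengths[1] + params$genome_length %% n
  contig_ids <- sprintf("contig%03d", seq_len(n))
  chroms <- paste0("chr", seq_len(params$n_chromosomes))
  chr_left <- sample(rep_len(chroms, n))

  n_chimeric <- floor(params$chimera_fraction * n)
  chimeric <- rep(FALSE, n)
  junction <- rep(NA_real_, n)
  chr_right <- chr_left
  if (n_chimeric > 0) {
    picks <- sample.int(n, n_chimeric)
    chimeric[picks] <- TRUE
    for (i in picks) {
      chr_right[i] <- sample(setdiff(chroms, chr_left[i]), 1)
      junction[i] <- floor(runif(1, 0.3, 0.7) * lengths[i])
    }
  }
  sequences <- setNames(random_dna(lengths), contig_ids)
  contigs <- tibble(
    contig = contig_ids, length = lengths,
    chromosome = chr_left, chimeric = chimeric, junction = junction,
    chr_left = chr_left, chr_right = chr_right
  )
  # chromosome sizes from the bases truly belonging to each chromosome
  left_bp <- ifelse(chimeric, junction, lengths)
  right_bp <- ifelse(chimeric, lengths - junction, 0)
  sizes <- tibble(chromosome = c(chr_left, chr_right),
                  bp = c(left_bp, right_bp)) |>
    group_by(.data$chromosome) |>
    summarise(size = sum(.data$bp), .groups = "drop") |>
    filter(.data$size > 0)
  out <- list(
    sequences = sequences,
    contigs = contigs,
    chromosomes = sizes,
    mito = random_dna(params$mito_length),
    params = params
  )
  class(out) <- "cohort_reference"
  out
}

#' @export
print.cohort_reference <- function(x, ...) {
  cat(sprintf("<cohort_reference> %d contigs, %s bp (%d chimeric), %d chromosomes\n",
              nrow(x$contigs), format(sum(x$contigs$length), big.mark = ","),
              sum(x$contigs$chimeric), nrow(x$chromosomes)))
  invisible(x)
}

#' Simulate error-free reads from a sequence
#'
#' Supports two layouts: `"random"` draws read start positions uniformly
#' and strands at random (shotgun-like), `"tiled"` places reads forward at a
#' fixed stride chosen to hit the requested coverage, which yields exactly
#' uniform interior coverage -- convenient when a clean kmer coverage peak
#' is wanted.
#'
#' @param sequence A single sequence string.
#' @param coverage Target mean per-base coverage.
#' @param read_length Read length, bp.
#' @param layout `"random"` or `"tiled"`.
#' @return Character vector of read sequences.
#' @export
simulate_reads <- function(sequence, coverage = 20, read_length = 100,
                           layout = c("random", "tiled")) {
  layout <- match.arg(layout)
  len <- nchar(sequence)
  if (len < read_length) abort("sequence shorter than the read length")
  if (layout == "tiled") {
    stride <- max(1L, round(read_length / coverage))
    starts <- seq.int(1L, len - read_length + 1L, by = stride)
    return(substring(sequence, starts, starts + read_length - 1L))
  }
  n_reads <- ceiling(len * coverage / read_length)
  starts <- sample.int(len - read_length + 1L, n_reads, replace = TRUE)
  reads <- substring(sequence, starts, starts + read_length - 1L)
  flip <- runif(n_reads) < 0.5
  reads[flip] <- revcomp(reads[flip])
  reads
}
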