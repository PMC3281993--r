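#' Kmer occurrence spectra and genome-size estimation
#'
#' A kmer spectrum is the histogram of kmer multiplicities in a read set: for
#' each occurrence count `d >= 1`, the number of distinct kmers seen exactly
#' `d` times. Under roughly uniform sequencing coverage the spectrum shows a
#' large error peak at depth 1-2 (kmers created by sequencing errors or low
#' coverage) and a coverage peak near the per-kmer sequencing depth. The
#' genome size follows from dividing the effective number of kmer words by the
#' coverage-peak depth.
#'
#' @param histogram A data frame with columns `depth` (integer occurrence
#'   count, >= 1) and `n_kmers` (number of distinct kmers with that count).
#' @param k The kmer length used to build the histogram.
#' @return A tibble of class `kmer_spectrum` with columns `depth` and
#'   `n_kmers`, sorted by depth, carrying `k` as an attribute.
#' @examples
#' sp <- kmer_spectrum(data.frame(depth = c(1, 25), n_kmers = c(10, 100)), k = 21)
#' kmer_totals(sp)
#' @export
kmer_spectrum <- function(histogram, k) {
  check_scalar_number(k, "k", min = 1)
  histogram <- as_tibble(histogram)
  if (!all(c("depth", "n_kmers") %in% names(histogram))) {
    abort("`histogram` needs columns `depth` and `n_kmers`")
  }
  if (any(histogram$depth < 1) || any(histogram$n_kmers < 0)) {
    abort("depths must be >= 1 and counts >= 0")
  }
  if (anyDuplicated(histogram$depth)) {
    abort("duplicated depth rows in histogram")
  }
  out <- histogram |>
    select("depth", "n_kmers") |>
    arrange(.data$depth)
  structure(out, k = as.integer(k),
            class = c("kmer_spectrum", class(out)))
}

#' Totals of a kmer spectrum
#'
#' `Kn` is the total number of kmer occurrences (words), `Sum(d * n_d)`;
#' `Ks` is the number of occurrences of singleton kmers, `n_1`. Singleton
#' words are treated as noise and excluded from the effective word count.
#'
#' @param spectrum A [kmer_spectrum()].
#' @return A one-row tibble with columns `k`, `kn`, `ks`, `n_distinct`.
#' @export
kmer_totals <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  tibble(
    k = attr(spectrum, "k"),
    kn = sum(spectrum$depth * spectrum$n_kmers),
    ks = sum(spectrum$n_kmers[spectrum$depth == 1]),
    n_distinct = sum(spectrum$n_kmers)
  )
}

#' Count the kmer spectrum of a read collection
#'
#' Slides a window of length `k` over every read and tabulates occurrence
#' counts. Kmers containing non-ACGT characters are skipped, as are reads
#' shorter than `k`; both are tallied in the attributes. By default kmers are
#' counted canonically (the lexicographic minimum of the kmer and its reverse
#' complement), appropriate for double-stranded sequencing data; set
#' `canonical = FALSE` for stranded counting.
#'
#' This is an in-memory counter intended for spectra of up to a few million
#' windows; it is not a streaming counter for multi-gigabase datasets.
#'
#' @param reads A character vector of read sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param k Kmer length (>= 1).
#' @param canonical Collapse each kmer with its reverse complement?
#' @return A [kmer_spectrum()]; attributes `n_reads_skipped` and
#'   `n_kmers_skipped` record how many short reads and ambiguous kmers were
#'   dropped.
#' @examples
#' count_kmer_spectrum("AAAA", k = 2)   # "AA" occurs 3 times
#' @export
count_kmer_spectrum <- function(reads, k, canonical = TRUE) {
  check_scalar_number(k, "k", min = 1)
  k <- as.integer(k)
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  short <- nchar(reads) < k
  n_short <- sum(short)
  reads <- reads[!short]
  if (length(reads) == 0L) {
    abort("no reads of length >= k")
  }
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    substring(r, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  ok <- !grepl("[^ACGT]", kmers)
  n_bad <- sum(!ok)
  kmers <- kmers[ok]
  if (length(kmers) == 0L) {
    abort("no unambiguous kmers to count")
  }
  if (canonical) {
    rc <- revcomp(kmers)
    kmers <- pmin(kmers, rc)
  }
  occ <- table(kmers)
  hist <- table(as.integer(occ))
  out <- kmer_spectrum(
    tibble(depth = as.integer(names(hist)), n_kmers = as.numeric(hist)),
    k = k
  )
  attr(out, "n_reads_skipped") <- n_short
  attr(out, "n_kmers_skipped") <- n_bad
  out
}

#' Locate the coverage-peak depth of a kmer spectrum
#'
#' The spectrum's low-depth error peak is excluded by scanning from
#' `min_depth` for the first local minimum; the peak depth `Dp` is the depth
#' with the maximum kmer count at or beyond that valley, ties broken toward
#' the smaller depth. A histogram that only decreases (no coverage peak)
#' raises an error.
#'
#' @param spectrum A [kmer_spectrum()].
#' @param min_depth Smallest depth eligible for the valley/peak search.
#' @return The integer peak depth `Dp`.
#' @export
peak_depth <- function(spectrum, min_depth = 2L) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  check_scalar_number(min_depth, "min_depth", min = 1)
  dmax <- max(spectrum$depth)
  if (dmax < min_depth) {
    abort("histogram empty at or beyond `min_depth`")
  }
  # dense counts over the full depth grid; absent depths have zero kmers
  counts <- numeric(dmax)
  counts[spectrum$depth] <- spectrum$n_kmers
  d <- seq.int(min_depth, dmax)
  n <- counts[d]
  if (length(n) == 1L || all(diff(n) <= 0)) {
    abort("no coverage peak: histogram is non-increasing beyond `min_depth`")
  }
  # first local minimum: first depth whose count does not exceed the next
  valley <- which(n[-length(n)] <= n[-1])[1]
  peak <- valley - 1L + which.max(n[valley:length(n)])
  as.integer(d[peak])
}

#' Estimate genome size from a kmer spectrum
#'
#' Implements the effective-word estimator `Gs = (Kn - Ks) / Dp`, where `Kn`
#' is the total number of kmer words, `Ks` the number of singleton words
#' (noise), and `Dp` the kmer depth at the coverage peak.
#'
#' @param spectrum A [kmer_spectrum()].
#' @param dp Peak kmer depth; computed with [peak_depth()] when omitted.
#' @return Estimated genome size in base pairs (a real number).
#' @examples
#' # spectrum with 1e4 singleton words and 4e4 words at depth 20
#' sp <- kmer_spectrum(data.frame(depth = c(1, 20), n_kmers = c(1e4, 2e3)), 21)
#' estimate_genome_size(sp, dp = 20)
#' @export
estimate_genome_size <- function(spectrum, dp = peak_depth(spectrum)) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  check_scalar_number(dp, "dp", min = 1)
  tot <- kmer_totals(spectrum)
  if (tot$kn <= tot$ks) {
    abort("Kn <= Ks: no effective kmer words")
  }
  (tot$kn - tot$ks) / dp
}

#' Plot a kmer spectrum
#'
#' @param object A [kmer_spectrum()].
#' @param mark_peak Draw a vertical line at the detected coverage peak?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kmer_spectrum <- function(object, mark_peak = TRUE, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$depth, y = .data$n_kmers)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::labs(x = "kmer depth", y = "distinct kmers",
                  title = sprintf("k = %d kmer spectrum", attr(object, "k")))
  if (mark_peak) {
    dp <- tryCatch(peak_depth(object), error = function(e) NA_integer_)
    if (!is.na(dp)) {
      p <- p + ggplot2::geom_vline(xintercept = dp, linetype = 2,
                                   colour = "firebrick")
    }
  }
  p
}
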