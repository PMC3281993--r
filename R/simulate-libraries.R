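#' Simulate flow-sorted chromosome-library read profiles
#'
#' Each chromosome gets one sequencing library. Every contig receives
#' Poisson-distributed mapped reads at `library_read_density` reads/bp with
#' uniformly random coordinates; each read's *source* chromosome is the
#' contig's true chromosome (left or right of the junction for chimeric
#' contigs, so the source switches along the coordinate axis), and a
#' fraction `library_contamination` of reads is reassigned to a uniformly
#' chosen other library, emulating impure chromosome sorts.
#'
#' @param params A [cohort_params()] object.
#' @param reference A [simulate_reference()] result carrying the true
#'   contig-to-chromosome map.
#' @return A list of class `library_profiles`: `profiles` (tibble: `contig`,
#'   `library`, `position`), `libraries` (tibble: `library`, `chromosome`,
#'   `size`, `total_reads` -- the genome-wide raw reads per library used for
#'   effective-count scaling), and `truth` (tibble of per-read source
#'   chromosomes).
#' @export
simulate_chromosome_libraries <- function(params,
                                          reference = simulate_reference(params)) {
  stopifnot(inherits(params, "cohort_params"),
            inherits(reference, "cohort_reference"))
  check_scalar_number(params$library_contamination, "library_contamination",
                      min = 0, max = 0.5)
  set.seed(params$seed + 2L)
  chroms <- reference$chromosomes$chromosome
  libs <- setNames(paste0("L", seq_along(chroms)), chroms)

  reads <- purrr::pmap(reference$contigs, function(contig, length, chromosome,
                                                   chimeric, junction,
                                                   chr_left, chr_right, ...) {
    n <- rpois(1, params$library_read_density * length)
    if (n == 0) return(NULL)
    position <- sort(sample.int(length, n, replace = TRUE))
    source_chr <- if (chimeric) {
      ifelse(position <= junction, chr_left, chr_right)
    } else rep(chromosome, n)
    tibble(contig = contig, position = position, source = source_chr)
  }) |> bind_rows()

  contaminated <- runif(nrow(reads)) < params$library_contamination
  observed <- reads$source
  if (any(contaminated)) {
    observed[contaminated] <- vapply(observed[contaminated], function(ch) {
      sample(setdiff(chroms, ch), 1)
    }, character(1))
  }
  profiles <- tibble(
    contig = reads$contig,
    library = unname(libs[observed]),
    position = reads$position
  )
  # genome-wide raw library yield, proportional to chromosome size with
  # +-10% depth wobble between sorts
  libraries <- reference$chromosomes |>
    mutate(
      library = unname(libs[.data$chromosome]),
      total_reads = pmax(1, round(.data$size * params$library_read_density *
                                    runif(dplyr::n(), 0.9, 1.1)))
    ) |>
    select("library", "chromosome", "size", "total_reads")
  out <- list(
    profiles = profiles,
    libraries = libraries,
    truth = reads |> mutate(contaminated = contaminated)
  )
  class(out) <- "library_profiles"
  out
}

#' @export
print.library_profiles <- function(x, ...) {
  cat(sprintf("<library_profiles> %d reads over %d contigs, %d libraries\n",
              nrow(x$profiles), length(unique(x$profiles$contig)),
              nrow(x$libraries)))
  invisible(x)
}
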