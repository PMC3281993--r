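#' @importFrom rlang %||% abort .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats binom.test chisq.test coef lm predict rbinom rmultinom
#'   rpois runif setNames dpois
#' @importFrom utils head tail
NULL

# Strand-collapsed substitution classes, in fixed reporting order.
SUBSTITUTION_CLASSES <- c(
  "A:T>C:G", "A:T>G:C", "A:T>T:A",
  "G:C>A:T", "G:C>C:G", "G:C>T:A"
)

DNA_BASES <- c("A", "C", "G", "T")

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Map a ref/alt substitution to its strand-collapsed class
#'
#' Substitutions are reported on the reference strand but counted in the six
#' strand-collapsed classes (e.g. both T>A and A>T belong to A:T>T:A).
#'
#' @param ref,alt Character vectors of single reference and alternate bases.
#' @return A character vector of class labels (one of
#'   `"A:T>C:G"`, `"A:T>G:C"`, `"A:T>T:A"`, `"G:C>A:T"`, `"G:C>C:G"`,
#'   `"G:C>T:A"`).
#' @export
substitution_class <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  ref <- toupper(ref)
  alt <- toupper(alt)
  bad <- !(ref %in% DNA_BASES) | !(alt %in% DNA_BASES)
  if (any(bad)) {
    abort(paste0("non-ACGT allele in substitution at index ",
                 paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", ")))
  }
  if (any(ref == alt)) {
    abort("ref == alt: not a substitution")
  }
  # collapse pyrimidine-reference calls onto the purine strand
  flip <- ref %in% c("T", "C")
  ref[flip] <- complement_base(ref[flip])
  alt[flip] <- complement_base(alt[flip])
  pair <- ifelse(ref == "A", "A:T", "G:C")
  to <- ifelse(ref == "A",
    c(C = "C:G", G = "G:C", T = "T:A")[alt],
    c(A = "A:T", C = "C:G", T = "T:A")[alt]
  )
  paste0(pair, ">", to)
}

# (contig, position, alt) identity used throughout for variant set algebra
variant_key <- function(contig, pos, alt) {
  paste(contig, pos, alt, sep = ":")
}

# uniform random DNA string(s)
random_dna <- function(n) {
  vapply(n, function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# round to a number of significant figures (plain signif, named for intent)
signif3 <- function(x) signif(x, 3)

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}
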