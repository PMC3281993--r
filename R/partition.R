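#' Four-genome variant set algebra
#'
#' The founder animal of a transmissible cancer is long dead, but its
#' germline survives inside every tumour. Variants shared by two divergent
#' tumour subclones are, at minimum, as old as the subclones' most recent
#' common ancestor: those also seen in a sequenced normal genome are almost
#' certainly population germline variation, while the remaining shared
#' "private" variants mix founder-private germline with early (trunk)
#' somatic mutations. Variants present in only one tumour are strongly
#' enriched for somatic mutations acquired after the lineages diverged.
#'
#' Variant identity throughout is the key `(contig, position, alt)`: two
#' samples share a variant only when the alternate allele matches.
#'
#' @param normal_female,normal_male,tumor_a,tumor_b Variant tables, one row
#'   per called variant, with columns `contig`, `pos`, `alt` and optionally
#'   `genotype` (`"het"`/`"hom"`). Duplicate keys within a table are an
#'   error.
#' @return An object of class `variant_partition`: list with `counts` (one
#'   row per category), and the five underlying key sets as tibbles --
#'   `tumor_common`, `shared_with_normal`, `tumor_private`, `a_unique`,
#'   `b_unique`.
#' @export
partition_variants <- function(normal_female, normal_male, tumor_a, tumor_b) {
  keyset <- function(x, label) {
    x <- as_tibble(x)
    stopifnot(all(c("contig", "pos", "alt") %in% names(x)))
    k <- variant_key(x$contig, x$pos, x$alt)
    if (anyDuplicated(k)) {
      abort(paste0("duplicate variant keys in ", label))
    }
    k
  }
  kf <- keyset(normal_female, "normal_female")
  km <- keyset(normal_male, "normal_male")
  ka <- keyset(tumor_a, "tumor_a")
  kb <- keyset(tumor_b, "tumor_b")

  common <- intersect(ka, kb)
  normals <- union(kf, km)
  shared <- intersect(common, normals)
  private <- setdiff(common, normals)
  a_unique <- setdiff(ka, kb)
  b_unique <- setdiff(kb, ka)

  as_key_tbl <- function(keys) {
    if (length(keys) == 0) {
      return(tibble(contig = character(), pos = integer(), alt = character()))
    }
    parts <- stringr::str_split_fixed(keys, stringr::fixed(":"), 3)
    tibble(contig = parts[, 1], pos = as.integer(parts[, 2]), alt = parts[, 3])
  }

  out <- list(
    counts = tibble(
      category = c("tumor_common", "shared_with_normal", "tumor_private",
                   "a_unique", "b_unique"),
      n = c(length(common), length(shared), length(private),
            length(a_unique), length(b_unique))
    ),
    tumor_common = as_key_tbl(common),
    shared_with_normal = as_key_tbl(shared),
    tumor_private = as_key_tbl(private),
    a_unique = as_key_tbl(a_unique),
    b_unique = as_key_tbl(b_unique)
  )
  class(out) <- "variant_partition"
  out
}

#' @export
print.variant_partition <- function(x, ...) {
  cat("<variant_partition>\n")
  print(x$counts)
  invisible(x)
}

#' @rdname partition_variants
#' @param x A `variant_partition`.
#' @param ... Unused.
#' @export
tidy.variant_partition <- function(x, ...) x$counts

#' @rdname partition_variants
#' @export
glance.variant_partition <- function(x, ...) {
  x$counts |> tidyr::pivot_wider(names_from = "category", values_from = "n")
}

#' Infer the sex of the cancer's founder animal
#'
#' A male founder would leave a Y chromosome behind: detection of the
#' male-determining gene (SRY) in the tumour implies a male founder. A
#' female founder leaves two X chromosomes, so the tumour's X-linked variant
#' count should resemble the female normal's and be roughly double the male
#' normal's. The numeric windows operationalise "approximately double" and
#' "comparable" and are exposed as arguments.
#'
#' @param x_counts Named numeric vector of X-linked variant counts with
#'   entries `normal_female`, `normal_male`, `tumor_a`, `tumor_b` (counts
#'   should already exclude any masked, poorly assembled X intervals).
#' @param sry_detected Named logical vector with entries `tumor_a`,
#'   `tumor_b`.
#' @param min_male_ratio Each tumour count must be at least this multiple of
#'   the male normal count to call female.
#' @param female_window Two-sided multiplicative window around the female
#'   normal count.
#' @return A list with `call` (`"female"`, `"male"`, or `"indeterminate"`)
#'   and `evidence` (a tibble of the ratios examined).
#' @export
infer_founder_sex <- function(x_counts, sry_detected,
                              min_male_ratio = 1.5,
                              female_window = c(0.75, 1.25)) {
  needed <- c("normal_female", "normal_male", "tumor_a", "tumor_b")
  if (!all(needed %in% names(x_counts))) {
    abort("`x_counts` needs entries normal_female, normal_male, tumor_a, tumor_b")
  }
  if (!all(c("tumor_a", "tumor_b") %in% names(sry_detected))) {
    abort("`sry_detected` needs entries tumor_a and tumor_b")
  }
  tum <- x_counts[c("tumor_a", "tumor_b")]
  male_ratio <- tum / x_counts[["normal_male"]]
  female_ratio <- tum / x_counts[["normal_female"]]
  evidence <- tibble(
    sample = c("tumor_a", "tumor_b"),
    x_count = unname(tum),
    vs_male = unname(male_ratio),
    vs_female = unname(female_ratio),
    sry = unname(sry_detected[c("tumor_a", "tumor_b")])
  )
  call <- if (any(evidence$sry)) {
    "male"
  } else if (all(evidence$vs_male >= min_male_ratio) &&
             all(evidence$vs_female >= female_window[1] &
                   evidence$vs_female <= female_window[2])) {
    "female"
  } else {
    "indeterminate"
  }
  list(call = call, evidence = evidence)
}

#' Heterozygous fraction of a variant set
#'
#' Somatic point mutations arise on one chromosome copy, so a variant set
#' strongly enriched for somatic mutations should be almost entirely
#' heterozygous (copy-number losses can homozygose or remove them).
#'
#' @param variants Data frame with a `genotype` column (`"het"`/`"hom"`).
#' @return The fraction of records with genotype `"het"`.
#' @export
heterozygous_fraction <- function(variants) {
  variants <- as_tibble(variants)
  stopifnot("genotype" %in% names(variants))
  if (nrow(variants) == 0L) {
    abort("heterozygous fraction of an empty variant set is undefined")
  }
  bad <- setdiff(unique(variants$genotype), c("het", "hom"))
  if (length(bad)) {
    abort(paste0("unknown genotype labels: ", paste(bad, collapse = ", ")))
  }
  mean(variants$genotype == "het")
}

#' Strand-collapsed mutation spectrum of a substitution set
#'
#' @param variants Data frame with single-base `ref` and `alt` columns
#'   (indels must be excluded beforehand).
#' @return A tibble of class `spectrum_profile` with one row per
#'   substitution class: `class`, `n`, `proportion` (all six classes always
#'   present, proportions summing to 1).
#' @export
mutation_spectrum <- function(variants) {
  variants <- as_tibble(variants)
  stopifnot(all(c("ref", "alt") %in% names(variants)))
  if (nrow(variants) == 0L) {
    abort("mutation spectrum of an empty variant set is undefined")
  }
  cls <- substitution_class(variants$ref, variants$alt)
  counts <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
  out <- tibble(
    class = SUBSTITUTION_CLASSES,
    n = as.integer(counts),
    proportion = as.integer(counts) / nrow(variants)
  )
  structure(out, class = c("spectrum_profile", class(out)))
}

#' Plot a mutation spectrum
#'
#' @param object A [mutation_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of class proportions.
#' @export
autoplot.spectrum_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$class, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proportion of substitutions") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
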