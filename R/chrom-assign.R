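#' Assigning contigs to chromosomes from flow-sorted libraries
#'
#' Reads sequenced from flow-sorted chromosome libraries are aligned to the
#' assembly contigs; a contig's per-library mapped-read counts then indicate
#' which chromosome it belongs to. Because chromosomes differ in size and the
#' libraries in total yield, raw counts are rescaled to *effective* counts
#' before comparison: `N_e[i] = C_s[i] * N[i] / N_c[i]`, where `C_s[i]` is the
#' size of chromosome `i`, `N_c[i]` the total reads of library `i` aligning to
#' its chromosome, and `N[i]` the library-`i` reads mapped to the contig.
#'
#' @name chrom_assign
NULL

#' Effective per-library read counts for one contig
#'
#' @param profile A data frame of mapped reads for one or more contigs with
#'   columns `contig`, `library`, and optionally `position`.
#' @param libraries A data frame with one row per flow-sorted library:
#'   columns `library`, `chromosome`, `size` (chromosome size in bp) and
#'   `total_reads` (raw library reads aligning to that chromosome).
#' @return A tibble with columns `contig`, `library`, `n_reads`,
#'   `effective`, one row per contig x library present in `libraries`
#'   (libraries with no reads on a contig get zero), preserving the library
#'   order of `libraries`.
#' @examples
#' libs <- tibble::tibble(library = c("L1", "L2"), chromosome = c("chr1", "chr2"),
#'                        size = c(100, 200), total_reads = c(1000, 1000))
#' prof <- tibble::tibble(contig = "c1",
#'                        library = rep(c("L1", "L2"), c(50, 20)))
#' effective_counts(prof, libs)
#' @export
effective_counts <- function(profile, libraries) {
  profile <- as_tibble(profile)
  libraries <- as_tibble(libraries)
  stopifnot(all(c("contig", "library") %in% names(profile)),
            all(c("library", "chromosome", "size", "total_reads") %in%
                  names(libraries)))
  if (any(libraries$size <= 0) || any(libraries$total_reads <= 0)) {
    abort("library `size` and `total_reads` must be positive")
  }
  unknown <- setdiff(unique(profile$library), libraries$library)
  if (length(unknown) > 0) {
    abort(paste0("profile refers to unknown libraries: ",
                 paste(unknown, collapse = ", ")))
  }
  counts <- profile |>
    count(.data$contig, .data$library, name = "n_reads")
  tidyr::expand_grid(contig = unique(profile$contig),
                     library = libraries$library) |>
    left_join(counts, by = c("contig", "library")) |>
    mutate(n_reads = tidyr::replace_na(.data$n_reads, 0L)) |>
    left_join(libraries |> select("library", "chromosome", "size",
                                  "total_reads"),
              by = "library") |>
    mutate(effective = .data$size * .data$n_reads / .data$total_reads) |>
    select("contig", "library", "chromosome", "n_reads", "effective")
}

block_majority <- function(labels, previous = NULL) {
  tab <- sort(table(labels), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  # tie: prefer continuity with the previous block, else smallest label
  if (!is.null(previous) && previous %in% top) return(previous)
  sort(top)[1]
}

#' Scan a contig's mapped reads for library transitions
#'
#' Coordinate-sorted reads are chunked into consecutive blocks of
#' `block_size` reads; each block is labelled by the majority source library
#' (ties broken toward the previous block's label). Maximal runs of equal
#' labels form segments; a label change between adjacent runs is strong
#' evidence of a chimeric (misassembled) contig and emits a junction at the
#' midpoint between the flanking reads.
#'
#' @param profile A data frame of reads for a single contig with columns
#'   `library` and `position` (1-based).
#' @param block_size Reads per block.
#' @return A list with `segments` (tibble: `segment`, `library`, `start_read`,
#'   `end_read`, `start_pos`, `end_pos`) and `junctions` (numeric positions).
#'   A trailing partial block is kept as its own block; contigs with fewer
#'   than `block_size` reads form a single block and cannot show a junction.
#' @export
scan_blocks <- function(profile, block_size = 20L) {
  profile <- as_tibble(profile)
  stopifnot(all(c("library", "position") %in% names(profile)))
  check_scalar_number(block_size, "block_size", min = 1)
  if (nrow(profile) == 0L) abort("no mapped reads to scan")
  reads <- profile |> arrange(.data$position)
  n <- nrow(reads)
  block_id <- ceiling(seq_len(n) / block_size)
  labels <- character(max(block_id))
  for (b in seq_along(labels)) {
    prev <- if (b > 1) labels[b - 1] else NULL
    labels[b] <- block_majority(reads$library[block_id == b], prev)
  }
  runs <- rle(labels)
  run_end_block <- cumsum(runs$lengths)
  run_start_block <- c(1L, head(run_end_block, -1) + 1L)
  start_read <- (run_start_block - 1L) * block_size + 1L
  end_read <- pmin(run_end_block * block_size, n)
  segments <- tibble(
    segment = seq_along(runs$values),
    library = runs$values,
    start_read = start_read,
    end_read = end_read,
    start_pos = reads$position[start_read],
    end_pos = reads$position[end_read]
  )
  junctions <- if (nrow(segments) > 1) {
    # midpoint between the last read of one run and the first of the next
    floor((segments$end_pos[-nrow(segments)] +
             segments$start_pos[-1]) / 2)
  } else numeric(0)
  list(segments = segments, junctions = junctions)
}

#' Assign one contig to a chromosome (or split it)
#'
#' Computes effective counts, and if the second-largest to largest effective
#' ratio is below `ratio_threshold` assigns the contig to the chromosome of
#' the maximal library. Otherwise the block scan decides: two or more
#' segments with distinct libraries mean the contig is chimeric and is split
#' at the detected junctions; a contig that fails the ratio test but shows no
#' transition is assigned to the maximal chromosome. A ratio exactly equal to
#' the threshold is routed to the block scan (conservative).
#'
#' @param profile Reads of a single contig: columns `library`, `position`.
#' @param libraries See [effective_counts()].
#' @param ratio_threshold Second-max/max effective-count ratio below which a
#'   contig is assigned outright.
#' @param block_size Reads per block for the chimera scan.
#' @return A one-row tibble: `contig`, `status` (`"assigned"`, `"split"`,
#'   `"unassigned"`), `chromosome`, `ratio`, `n_reads`, plus list-columns
#'   `segments` and `junctions` for split contigs.
#' @export
assign_contig <- function(profile, libraries, ratio_threshold = 0.4,
                          block_size = 20L) {
  profile <- as_tibble(profile)
  if (!"contig" %in% names(profile)) profile$contig <- "contig"
  ctg <- unique(profile$contig)
  stopifnot(length(ctg) <= 1)
  if (length(ctg) == 0L) ctg <- NA_character_
  if (nrow(profile) == 0L) {
    return(tibble(contig = ctg, status = "unassigned",
                  chromosome = NA_character_, ratio = NA_real_, n_reads = 0L,
                  segments = list(NULL), junctions = list(numeric(0)),
                  reason = "no data"))
  }
  eff <- effective_counts(profile, libraries) |>
    arrange(desc(.data$effective), .data$library)
  top <- eff$effective[1]
  second <- if (nrow(eff) >= 2) eff$effective[2] else 0
  ratio <- if (top > 0) second / top else NA_real_
  res <- tibble(contig = ctg, status = NA_character_,
                chromosome = eff$chromosome[1], ratio = ratio,
                n_reads = nrow(profile),
                segments = list(NULL), junctions = list(numeric(0)),
                reason = NA_character_)
  if (is.na(ratio)) {
    res$status <- "unassigned"
    res$chromosome <- NA_character_
    res$reason <- "no data"
    return(res)
  }
  if (ratio < ratio_threshold) {
    res$status <- "assigned"
    return(res)
  }
  scan <- scan_blocks(profile, block_size = block_size)
  lib2chr <- setNames(libraries$chromosome, libraries$library)
  seg_chr <- unname(lib2chr[scan$segments$library])
  if (length(unique(seg_chr)) >= 2) {
    res$status <- "split"
    res$chromosome <- NA_character_
    res$segments <- list(scan$segments |> mutate(chromosome = seg_chr))
    res$junctions <- list(scan$junctions)
  } else {
    # ambiguous ratio but no spatial transition: keep the argmax assignment
    res$status <- "assigned"
  }
  res
}

#' Assign every contig in a profile table
#'
#' @param profiles Data frame of mapped reads with columns `contig`,
#'   `library`, `position` (multiple contigs).
#' @param libraries See [effective_counts()].
#' @inheritParams assign_contig
#' @return An object of class `chrom_assignment`: a list with
#'   `assignments` (one row per contig; unassigned contigs carry chromosome
#'   `"ChrU"`), `segments` (split-contig segments, BED-style 0-based
#'   half-open intervals derived from junctions), and the call parameters.
#' @export
assign_all <- function(profiles, libraries, ratio_threshold = 0.4,
                       block_size = 20L) {
  profiles <- as_tibble(profiles)
  if (nrow(profiles) == 0L) {
    out <- list(assignments = tibble(contig = character(), status = character(),
                                     chromosome = character(), ratio = numeric(),
                                     n_reads = integer()),
                segments = tibble(),
                ratio_threshold = ratio_threshold, block_size = block_size)
    class(out) <- "chrom_assignment"
    return(out)
  }
  rows <- profiles |>
    group_by(.data$contig) |>
    group_map(~ assign_contig(mutate(.x, contig = .y$contig), libraries,
                              ratio_threshold, block_size)) |>
    bind_rows()
  assignments <- rows |>
    mutate(chromosome = ifelse(.data$status == "assigned",
                               .data$chromosome, "ChrU")) |>
    select("contig", "status", "chromosome", "ratio", "n_reads")
  segments <- rows |>
    filter(.data$status == "split") |>
    select("contig", "segments") |>
    tidyr::unnest("segments")
  out <- list(assignments = assignments, segments = segments,
              junctions = rows |> select("contig", "junctions") |>
                tidyr::unnest("junctions"),
              ratio_threshold = ratio_threshold, block_size = block_size)
  class(out) <- "chrom_assignment"
  out
}

#' @export
print.chrom_assignment <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<chrom_assignment> %d contigs: %d assigned (%.1f%%), %d split, %d unassigned\n",
    g$n_contigs, g$n_assigned, 100 * g$fraction_assigned, g$n_split,
    g$n_unassigned))
  invisible(x)
}

#' @rdname assign_all
#' @param x A `chrom_assignment` object.
#' @param ... Unused.
#' @export
tidy.chrom_assignment <- function(x, ...) x$assignments

#' @rdname assign_all
#' @export
glance.chrom_assignment <- function(x, ...) {
  a <- x$assignments
  tibble(
    n_contigs = nrow(a),
    n_assigned = sum(a$status == "assigned"),
    n_split = sum(a$status == "split"),
    n_unassigned = sum(a$status == "unassigned"),
    fraction_assigned = if (nrow(a)) mean(a$status == "assigned") else 0
  )
}
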