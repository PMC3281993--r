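#' Cluster discordant read pairs into structural-variant candidates
#'
#' Read pairs mapping with an unexpected insert size or orientation, or to
#' two different contigs, are symptoms of a structural rearrangement. Pairs
#' with either read within `end_exclusion` bp of a contig end are discarded
#' (contig ends harbour assembly artifacts). The remaining pairs are grouped
#' into clusters when both breakpoint loci lie within `cluster_window` bp of
#' an existing cluster member and the orientation class matches; a cluster is
#' retained only when it has at least `min_support` pairs of mapping quality
#' `>= min_mq`.
#'
#' Orientation classes: `"inter_contig"` when the two reads map to different
#' contigs; `"inverted"` when both map to the same contig on the same strand;
#' `"same_contig"` for opposite-strand same-contig pairs with an unexpected
#' insert.
#'
#' @param pairs Data frame with columns `contig1`, `pos1`, `strand1`,
#'   `contig2`, `pos2`, `strand2`, `mq` (pair mapping quality).
#' @param contig_lengths Named numeric vector of contig lengths, used for
#'   end-distance computation; an error is raised for pairs on contigs with
#'   no recorded length.
#' @param min_support Minimum qualifying pairs per retained cluster.
#' @param min_mq Mapping quality a pair must reach to count as support.
#' @param end_exclusion Contig-end exclusion zone, bp.
#' @param cluster_window Maximum per-locus distance for joining a cluster
#'   (about one insert size), bp.
#' @return A tibble of retained clusters: `cluster`, `contig1`, `pos1`,
#'   `contig2`, `pos2` (median breakpoint loci), `orientation`, `n_pairs`,
#'   `n_support`.
#' @export
cluster_discordant_pairs <- function(pairs, contig_lengths,
                                     min_support = 7, min_mq = 30,
                                     end_exclusion = 500,
                                     cluster_window = 500) {
  pairs <- as_tibble(pairs)
  needed <- c("contig1", "pos1", "strand1", "contig2", "pos2", "strand2", "mq")
  stopifnot(all(needed %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    return(tibble(cluster = integer(), contig1 = character(), pos1 = numeric(),
                  contig2 = character(), pos2 = numeric(),
                  orientation = character(), n_pairs = integer(),
                  n_support = integer()))
  }
  used <- unique(c(pairs$contig1, pairs$contig2))
  if (!all(used %in% names(contig_lengths))) {
    abort(paste0("missing contig lengths for: ",
                 paste(setdiff(used, names(contig_lengths)), collapse = ", ")))
  }
  len1 <- unname(contig_lengths[pairs$contig1])
  len2 <- unname(contig_lengths[pairs$contig2])
  near_end <- pairs$pos1 <= end_exclusion | (len1 - pairs$pos1) < end_exclusion |
    pairs$pos2 <= end_exclusion | (len2 - pairs$pos2) < end_exclusion
  pairs <- pairs[!near_end, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(cluster_discordant_pairs(pairs, contig_lengths, min_support,
                                    min_mq, end_exclusion, cluster_window))
  }
  # canonical locus order so that (A,B) and (B,A) pairs co-cluster
  swap <- pairs$contig2 < pairs$contig1 |
    (pairs$contig1 == pairs$contig2 & pairs$pos2 < pairs$pos1)
  pairs <- pairs |>
    mutate(
      c1 = ifelse(swap, .data$contig2, .data$contig1),
      p1 = ifelse(swap, .data$pos2, .data$pos1),
      s1 = ifelse(swap, .data$strand2, .data$strand1),
      c2 = ifelse(swap, .data$contig1, .data$contig2),
      p2 = ifelse(swap, .data$pos1, .data$pos2),
      s2 = ifelse(swap, .data$strand1, .data$strand2),
      orientation = case_when(
        .data$c1 != .data$c2 ~ "inter_contig",
        .data$s1 == .data$s2 ~ "inverted",
        TRUE ~ "same_contig"
      )
    ) |>
    arrange(.data$orientation, .data$c1, .data$c2, .data$p1, .data$p2)
  # single-linkage within (orientation, contig pair), greedy along sorted p1
  grp <- paste(pairs$orientation, pairs$c1, pairs$c2, sep = "\r")
  cluster_id <- integer(nrow(pairs))
  next_id <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    anchors1 <- numeric(0)
    anchors2 <- numeric(0)
    ids <- integer(0)
    for (i in idx) {
      hit <- which(abs(anchors1 - pairs$p1[i]) <= cluster_window &
                     abs(anchors2 - pairs$p2[i]) <= cluster_window)
      if (length(hit)) {
        j <- hit[1]
        cluster_id[i] <- ids[j]
        anchors1[j] <- pairs$p1[i]   # chain along the sorted axis
        anchors2[j] <- pairs$p2[i]
      } else {
        next_id <- next_id + 1L
        cluster_id[i] <- next_id
        anchors1 <- c(anchors1, pairs$p1[i])
        anchors2 <- c(anchors2, pairs$p2[i])
        ids <- c(ids, next_id)
      }
    }
  }
  pairs$cluster <- cluster_id
  pairs |>
    group_by(.data$cluster) |>
    summarise(
      contig1 = .data$c1[1],
      pos1 = stats::median(.data$p1),
      contig2 = .data$c2[1],
      pos2 = stats::median(.data$p2),
      orientation = .data$orientation[1],
      n_pairs = dplyr::n(),
      n_support = sum(.data$mq >= min_mq),
      .groups = "drop"
    ) |>
    filter(.data$n_support >= min_support) |>
    arrange(.data$contig1, .data$pos1) |>
    mutate(cluster = dplyr::row_number())
}

#' Microhomology length at a rearrangement junction
#'
#' Microhomology-mediated end joining leaves a short identical sequence at
#' the two joined ends. Given the sequence ending at the junction on the left
#' fragment and the sequence continuing from the junction on the right
#' fragment, the microhomology is the longest suffix of the left sequence
#' that equals a prefix of the right sequence, capped at `max_len`.
#'
#' @param seq_left Sequence(s) ending at the junction (left fragment).
#' @param seq_right Sequence(s) starting at the junction (right fragment's
#'   continuation). Recycled against `seq_left`.
#' @param max_len Longest overlap considered; both sequences must be at
#'   least this long.
#' @return Integer vector of microhomology lengths.
#' @examples
#' breakpoint_microhomology("TTTACGT", "ACGTGGG", max_len = 6)  # 4
#' @export
breakpoint_microhomology <- function(seq_left, seq_right, max_len = 6) {
  check_scalar_number(max_len, "max_len", min = 1)
  n <- max(length(seq_left), length(seq_right))
  seq_left <- rep_len(toupper(seq_left), n)
  seq_right <- rep_len(toupper(seq_right), n)
  if (any(!nzchar(seq_left)) || any(!nzchar(seq_right))) {
    abort("empty junction sequence")
  }
  if (any(nchar(seq_left) < max_len) || any(nchar(seq_right) < max_len)) {
    abort("junction-flanking sequences must be at least `max_len` long")
  }
  vapply(seq_len(n), function(i) {
    left <- seq_left[i]
    right <- seq_right[i]
    nl <- nchar(left)
    best <- 0L
    for (len in seq_len(max_len)) {
      if (substr(left, nl - len + 1L, nl) == substr(right, 1L, len)) {
        best <- len
      }
    }
    best
  }, integer(1))
}
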