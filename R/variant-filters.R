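#' Quality filters for candidate variant calls
#'
#' Candidate substitution calls are filtered on coverage (minimum 10,
#' maximum 150 reads), read quality (>= 30), mapping quality (>= 30), base
#' quality (>= 30) and distance to the nearest contig end (>= 500 bp). All
#' thresholds are inclusive at their stated values: a record at exactly the
#' minimum (or maximum) passes. Each failing record is attributed to the
#' first rule it breaks, in the fixed order coverage, read quality, mapping
#' quality, base quality, contig end.
#'
#' @param records A data frame with columns `depth`, `read_quality`,
#'   `mapping_quality`, `base_quality`, `contig_end_distance` (other columns
#'   are carried through).
#' @param min_depth,max_depth Inclusive coverage window.
#' @param min_read_quality,min_mapping_quality,min_base_quality Inclusive
#'   Phred-like minima.
#' @param min_end_distance Minimum distance to a contig end, bp.
#' @return The input tibble with logical `pass` and character `fail_rule`
#'   (`NA` for passing records) appended. Use
#'   `dplyr::filter(out, pass)` for the passing set and
#'   `dplyr::count(out, fail_rule)` for the rejection tally.
#' @export
filter_substitutions <- function(records,
                                 min_depth = 10, max_depth = 150,
                                 min_read_quality = 30,
                                 min_mapping_quality = 30,
                                 min_base_quality = 30,
                                 min_end_distance = 500) {
  records <- as_tibble(records)
  needed <- c("depth", "read_quality", "mapping_quality", "base_quality",
              "contig_end_distance")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort(paste0("records lack columns: ", paste(missing, collapse = ", ")))
  }
  records |>
    mutate(
      fail_rule = case_when(
        .data$depth < min_depth | .data$depth > max_depth ~ "coverage",
        .data$read_quality < min_read_quality ~ "read_quality",
        .data$mapping_quality < min_mapping_quality ~ "mapping_quality",
        .data$base_quality < min_base_quality ~ "base_quality",
        .data$contig_end_distance < min_end_distance ~ "contig_end",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$fail_rule)
    )
}

#' Quality filter for candidate indel calls
#'
#' An indel call passes when its SNP quality `q_snp >= 30` and its
#' most-likely-genotype quality `q_max_gtype >= 5`, both inclusive.
#'
#' @param records Data frame with columns `q_snp` and `q_max_gtype`.
#' @param min_q_snp,min_q_max_gtype Inclusive minima.
#' @return The input tibble with `pass` and `fail_rule` appended.
#' @export
filter_indels <- function(records, min_q_snp = 30, min_q_max_gtype = 5) {
  records <- as_tibble(records)
  missing <- setdiff(c("q_snp", "q_max_gtype"), names(records))
  if (length(missing)) {
    abort(paste0("records lack columns: ", paste(missing, collapse = ", ")))
  }
  records |>
    mutate(
      fail_rule = case_when(
        .data$q_snp < min_q_snp ~ "q_snp",
        .data$q_max_gtype < min_q_max_gtype ~ "q_max_gtype",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$fail_rule)
    )
}

#' Screen exons for inadequate sequencing coverage
#'
#' An exon is flagged when its mean per-base depth is strictly below
#' `min_mean`; positions absent from the depth track count as depth zero.
#'
#' @param depth_track Data frame with columns `contig`, `pos` (1-based) and
#'   `depth`.
#' @param exons Data frame with columns `exon_id`, `contig`, `start`, `end`
#'   (0-based half-open intervals).
#' @param min_mean Mean-depth threshold (strict `<`).
#' @return The exon tibble with `mean_depth` and `flagged` appended.
#' @export
low_coverage_exon_screen <- function(depth_track, exons, min_mean = 10) {
  depth_track <- as_tibble(depth_track)
  exons <- as_tibble(exons)
  stopifnot(all(c("contig", "pos", "depth") %in% names(depth_track)),
            all(c("exon_id", "contig", "start", "end") %in% names(exons)))
  if (any(exons$end <= exons$start)) {
    abort("zero- or negative-length exon interval")
  }
  mean_depth <- purrr::pmap_dbl(
    exons |> select("contig", "start", "end"),
    function(contig, start, end) {
      width <- end - start
      d <- depth_track$depth[depth_track$contig == contig &
                               depth_track$pos > start &
                               depth_track$pos <= end]
      sum(d) / width   # uncovered positions contribute zero depth
    }
  )
  exons |>
    mutate(mean_depth = mean_depth, flagged = mean_depth < min_mean)
}
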