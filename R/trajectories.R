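#' Regional genotype-frequency trajectories and sweep flagging
#'
#' For each sampling region, computes the relative frequency of each tumour
#' genotype among the tumours sampled per year. A genotype is flagged as
#' sweep-like in a region when its frequency is monotonically non-decreasing
#' across at least `sweep_min_years` sampled years, finishes above
#' `sweep_final_freq`, and did not already start at fixation (a genotype at
#' frequency 1 throughout carries no sweep information). Regions with a
#' single sampled year yield trajectories but no sweep call.
#'
#' @param matrix A genotype matrix (see [genotype_matrix]) with `location`
#'   and `year` metadata.
#' @param sweep_min_years Minimum number of sampled years for a sweep call.
#' @param sweep_final_freq Frequency the genotype must exceed in the final
#'   sampled year.
#' @return An object of class `genotype_trajectories`: list with
#'   `frequencies` (tibble: `location`, `year`, `genotype_id`, `n`, `freq`)
#'   and `sweeps` (tibble: `location`, `genotype_id`, `n_years`,
#'   `first_freq`, `final_freq`, `monotone`, `sweep`).
#' @export
frequency_trajectories <- function(matrix, sweep_min_years = 3,
                                   sweep_final_freq = 0.5) {
  matrix <- validate_genotype_matrix(matrix)
  if (!all(c("location", "year") %in% names(matrix))) {
    abort("`location` and `year` metadata are required")
  }
  collapsed <- collapse_genotypes(matrix)
  assignment <- genotype_assignment(collapsed)
  samples <- matrix |>
    select("tumor_id", "location", "year") |>
    left_join(assignment, by = "tumor_id")
  frequencies <- samples |>
    count(.data$location, .data$year, .data$genotype_id) |>
    group_by(.data$location, .data$year) |>
    mutate(freq = .data$n / sum(.data$n)) |>
    ungroup()
  # per region, the trajectory of every genotype over every sampled year
  # (frequency zero in years where the genotype was not observed)
  sweeps <- frequencies |>
    group_by(.data$location) |>
    group_map(function(fr, grp) {
      years <- sort(unique(fr$year))
      if (length(years) < 2) {
        return(tibble(location = grp$location,
                      genotype_id = unique(fr$genotype_id),
                      n_years = length(years),
                      first_freq = NA_real_, final_freq = NA_real_,
                      monotone = NA, sweep = NA))
      }
      full <- tidyr::expand_grid(year = years,
                                 genotype_id = unique(fr$genotype_id)) |>
        left_join(fr |> select("year", "genotype_id", "freq"),
                  by = c("year", "genotype_id")) |>
        mutate(freq = tidyr::replace_na(.data$freq, 0)) |>
        arrange(.data$genotype_id, .data$year)
      full |>
        group_by(.data$genotype_id) |>
        summarise(
          n_years = length(years),
          first_freq = dplyr::first(.data$freq),
          final_freq = dplyr::last(.data$freq),
          monotone = all(diff(.data$freq) >= 0),
          .groups = "drop"
        ) |>
        mutate(
          location = grp$location,
          sweep = .data$n_years >= sweep_min_years & .data$monotone &
            .data$final_freq > sweep_final_freq & .data$first_freq < 1
        ) |>
        select("location", dplyr::everything())
    }) |>
    bind_rows()
  out <- list(frequencies = frequencies, sweeps = sweeps)
  class(out) <- "genotype_trajectories"
  out
}

#' @export
print.genotype_trajectories <- function(x, ...) {
  n_sw <- sum(x$sweeps$sweep, na.rm = TRUE)
  cat(sprintf("<genotype_trajectories> %d region-years, %d sweep-flagged genotype(s)\n",
              nrow(dplyr::distinct(x$frequencies, .data$location, .data$year)),
              n_sw))
  invisible(x)
}

#' @rdname frequency_trajectories
#' @param x A `genotype_trajectories` object.
#' @param ... Unused.
#' @export
tidy.genotype_trajectories <- function(x, ...) x$frequencies

#' Plot genotype-frequency trajectories
#'
#' @param object A [frequency_trajectories()] result.
#' @param ... Unused.
#' @return A ggplot object, one panel per region.
#' @export
autoplot.genotype_trajectories <- function(object, ...) {
  ggplot2::ggplot(object$frequencies,
                  ggplot2::aes(x = .data$year, y = .data$freq,
                               colour = .data$genotype_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~location) +
    ggplot2::labs(x = "year", y = "genotype frequency", colour = "genotype")
}

#' Classify hosts carrying multiple tumours
#'
#' A host with several tumours of identical genotype is consistent with
#' metastatic spread of a single inoculation. Distinct genotypes that are
#' each also observed in other hosts indicate independent reinfection.
#' A genotype unique to the host that differs from some genotype observed
#' elsewhere in the cohort by exactly one marker is most simply explained by
#' a de novo variant arising within that host. Everything else is reported
#' unresolved.
#'
#' @param matrix A genotype matrix with `devil_id` metadata.
#' @return A tibble with one row per host carrying >= 2 tumours:
#'   `devil_id`, `n_tumors`, `n_genotypes`, `classification` (one of
#'   `"metastasis_consistent"`, `"reinfection"`, `"possible_de_novo"`,
#'   `"unresolved"`), list-column `genotype_ids`.
#' @export
classify_host_tumors <- function(matrix) {
  matrix <- validate_genotype_matrix(matrix)
  if (!"devil_id" %in% names(matrix)) {
    abort("`devil_id` metadata is required")
  }
  collapsed <- collapse_genotypes(matrix)
  assignment <- genotype_assignment(collapsed) |>
    left_join(matrix |> select("tumor_id", "devil_id"), by = "tumor_id")
  # hosts in which each genotype occurs
  carriers <- assignment |>
    distinct(.data$genotype_id, .data$devil_id)
  pattern0 <- lapply(collapsed$pattern, function(p) {
    p[is.na(p)] <- 0L
    p
  })
  names(pattern0) <- collapsed$genotype_id
  hamming <- function(a, b) sum(pattern0[[a]] != pattern0[[b]])

  multi <- assignment |>
    group_by(.data$devil_id) |>
    filter(dplyr::n() >= 2) |>
    group_map(function(d, grp) {
      gts <- unique(d$genotype_id)
      seen_elsewhere <- vapply(gts, function(g) {
        any(carriers$devil_id[carriers$genotype_id == g] != grp$devil_id)
      }, logical(1))
      cohort_gts <- unique(carriers$genotype_id[
        carriers$devil_id != grp$devil_id])
      classification <- if (length(gts) == 1L) {
        "metastasis_consistent"
      } else if (all(seen_elsewhere)) {
        "reinfection"
      } else {
        private <- gts[!seen_elsewhere]
        near_hit <- any(vapply(private, function(g) {
          length(cohort_gts) > 0 &&
            any(vapply(cohort_gts, function(h) hamming(g, h) == 1L,
                       logical(1)))
        }, logical(1)))
        if (near_hit) "possible_de_novo" else "unresolved"
      }
      tibble(devil_id = grp$devil_id, n_tumors = nrow(d),
             n_genotypes = length(gts), classification = classification,
             genotype_ids = list(gts))
    }) |>
    bind_rows()
  multi
}
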